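small_libs <- list(library_def("L1", c("r1", "r2")),
                   library_def("L2", c("r3", "r4")))

test_that("import_counts sums replicates per library and zero-fills", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"),
                              c("r1", "r2", "r3", "r4")))
  cn <- import_counts(m, small_libs)
  expect_equal(dim(cn$counts), c(3L, 4L))
  expect_equal(cn$lib_counts["s1", "L1"], 1 + 4)
  expect_equal(cn$lib_counts["s3", "L2"], 9 + 12)
  expect_equal(unname(cn$lib_totals["L1"]), sum(m[, 1:2]))

  expect_warning(cn2 <- import_counts(m, small_libs,
                                      seq_ids = c("s1", "s2", "s3", "s4")),
                 "absent from counts")
  expect_equal(unname(cn2$lib_counts["s4", ]), c(0, 0))
})

test_that("import_counts rejects duplicate and unmapped columns", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tr1\tr1", "s1\t1\t2"), tf)
  expect_error(import_counts(tf, list(library_def("L1", "r1"))),
               "named twice")
  writeLines(c("seq_id\tr1\tzz", "s1\t1\t2"), tf)
  expect_error(import_counts(tf, list(library_def("L1", "r1"))),
               "not mapped")
  writeLines(c("seq_id\tr1", "s1\t-3"), tf)
  expect_error(import_counts(tf, list(library_def("L1", "r1"))),
               "negative count.*line 2")
})

test_that("per-library count files and the matrix dialect agree", {
  withr::with_seed(3, {
    d <- withr::local_tempdir()
    f1 <- file.path(d, "a.tsv"); f2 <- file.path(d, "b.tsv")
    writeLines(c("seq_id\tn", "s1\t5", "s2\t7"), f1)
    writeLines(c("seq_id\tn", "s2\t1", "s1\t2"), f2)
    cn <- import_counts(c(rA = f1, rB = f2),
                        list(library_def("A", "rA"),
                             library_def("B", "rB")))
    expect_equal(cn$counts["s1", ], c(rA = 5, rB = 2))
    expect_equal(cn$counts["s2", ], c(rA = 7, rB = 1))
  })
})

test_that("rpkm matches its definition and conserves mass", {
  expect_equal(rpkm(50, 2e6, 500), 50)
  expect_equal(rpkm(0, 2e6, 500), 0)
  expect_error(rpkm(1, 0, 10), "N must be")
  tx <- gen_transcriptome(n_seqs = 60, seed = 21)
  cn <- gen_counts(tx$seqs, seed = 22)
  counts <- import_counts(cn$counts_matrix, cn$libraries)
  lens <- setNames(nchar(tx$seqs$residues), tx$seqs$seq_id)
  R <- rpkm_matrix(counts, lens)
  mass <- colSums(R * lens[rownames(R)])
  expect_equal(unname(mass), rep(1e9, ncol(R)), tolerance = 1e-10)
})

test_that("r_statistic follows the formula and its invariances", {
  expect_equal(r_statistic(c(10, 10), c(1000, 1000))$R, 0)
  expect_equal(r_statistic(c(20, 0), c(1000, 1000))$R, 20 * log(2))
  expect_equal(r_statistic(c(0, 0), c(1000, 1000))$R, 0)
  expect_error(r_statistic(c(1, 2), c(1000, 0)), "zero")
  withr::with_seed(7, {
    for (i in 1:200) {
      nl <- sample(2:6, 1)
      N <- sample(1000:50000, nl)
      x <- rpois(nl, 50)
      got <- r_statistic(x, N)$R
      expect_equal(got, max(oracle_rstat(x, N), 0), tolerance = 1e-12)
      # permutation invariance
      p <- sample(nl)
      expect_equal(r_statistic(x[p], N[p])$R, got, tolerance = 1e-12)
      # scaling everything by k increases R (for non-null x)
      if (got > 1e-8)
        expect_gt(r_statistic(3 * x, 3 * N)$R, got)
    }
  })
})

test_that("vectorised R equals the scalar path per sequence", {
  tx <- gen_transcriptome(n_seqs = 40, seed = 31)
  cn <- gen_counts(tx$seqs, seed = 32)
  counts <- import_counts(cn$counts_matrix, cn$libraries)
  rs <- r_statistic_all(counts)
  for (i in sample(nrow(rs), 10)) {
    expect_equal(rs$R[i],
                 r_statistic(counts$lib_counts[rs$seq_id[i], ],
                             counts$lib_totals)$R,
                 tolerance = 1e-12)
  }
  expect_true(all(rs$R >= 0))
})

test_that("fold_change is signed, symmetric and zero-safe", {
  expect_equal(fold_change(5, 5), 0)
  expect_equal(fold_change(0, 0), 0)
  expect_equal(fold_change(4, 1, pseudo = 1e-9), 2, tolerance = 1e-6)
  expect_equal(fold_change(2, 8), -fold_change(8, 2))
  expect_error(fold_change(1, 1, pseudo = 0), "pseudo")
})

test_that("correlation matrix matches the textbook formula", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  r <- correlation_matrix(m)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  withr::with_seed(13, {
    m2 <- matrix(runif(20 * 6, 0, 100), nrow = 20,
                 dimnames = list(paste0("s", 1:20), paste0("L", 1:6)))
    r2 <- correlation_matrix(m2, log2 = TRUE)
    lm2 <- log2(m2 + 1)
    pearson <- function(x, y) {
      n <- length(x)
      (sum(x * y) - n * mean(x) * mean(y)) /
        sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    }
    for (k in 1:30) {
      i <- sample(20, 1); j <- sample(20, 1)
      expect_equal(r2[i, j], pearson(lm2[i, ], lm2[j, ]),
                   tolerance = 1e-10)
    }
    expect_equal(r2, t(r2))
    expect_true(all(r2 >= -1 - 1e-12 & r2 <= 1 + 1e-12))
  })
  # zero variance -> NA off-diagonal
  m3 <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  r3 <- correlation_matrix(m3)
  expect_true(is.na(r3["a", "b"]))
  expect_equal(r3["a", "a"], 1)
})

test_that("p-value columns add, refuse silent overwrite, and remove", {
  tx <- gen_transcriptome(n_seqs = 10, seed = 41)
  store <- new_project("p")
  store$seqs <- tx$seqs
  store$stats <- seq_stats(tx$seqs)
  before <- store$pvals
  df <- data.frame(seq_id = tx$seqs$seq_id[1:3], p = c(0.5, 1e-12, 0))
  add_pvalue_column(store, "TiRo", df)
  expect_equal(sum(!is.na(store$pvals$TiRo)), 3L)
  expect_error(add_pvalue_column(store, "TiRo", df), "already exists")
  add_pvalue_column(store, "TiRo", df, overwrite = TRUE)
  expect_error(add_pvalue_column(store, "bad",
                                 data.frame(s = "s0001", p = 1.5)),
               "outside")
  remove_pvalue_column(store, "TiRo")
  expect_identical(store$pvals, before)
})
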