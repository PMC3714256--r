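mk_pairs <- function(a, b, id = 90, ov = 95, e = 1e-50, bit = 500) {
  data.frame(seq_a = pmin(a, b), seq_b = pmax(a, b),
             percent_identity = id, percent_overlap = ov, e_value = e,
             bit_score = bit, stringsAsFactors = FALSE)
}

test_that("merge prefixes ids, translates, and keeps provenance", {
  tx <- gen_transcriptome(n_seqs = 10, len_range = c(300, 500), seed = 81,
                          n_datasets = 2)
  stores <- lapply(split(tx$seqs, tx$seqs$dataset_id), function(s) {
    st <- new_project(s$dataset_id[1])
    st$seqs <- txwb:::.as_seqs(s)
    st$stats <- seq_stats(s)
    st
  })
  mg <- merge_projects(stores)
  expect_equal(nrow(mg$seqs), 20L)
  expect_true(all(grepl("^ds[AB]\\|", mg$seqs$seq_id)))
  expect_equal(sum(txwb:::.dataset_of(mg$seqs$seq_id) == "dsA"), 10L)
  expect_true(all(mg$proteins$moltype == "protein"))
  expect_error(merge_projects(list(dsA = stores[[1]], dsA = stores[[2]])),
               "colliding")
  # protein project: no translation, records copied as is
  pstore <- new_project("pp")
  pstore$seqs <- txwb:::.as_seqs(data.frame(
    seq_id = "p1", residues = "MKVLH", moltype = "protein",
    dataset_id = "pp", stringsAsFactors = FALSE))
  pstore$stats <- seq_stats(pstore$seqs)
  mg2 <- merge_projects(list(dsP = pstore))
  expect_equal(mg2$proteins$residues, "MKVLH")
})

test_that("load_pairs drops self hits and keeps the best HSP per pair", {
  tf <- withr::local_tempfile()
  ln <- function(q, s, pid, len, bit)
    paste(q, s, pid, len, 0, 0, 1, len, 1, len, "1e-80", bit, sep = "\t")
  writeLines(c(ln("A", "A", 100, 500, 900),
               ln("A", "B", 85, 450, 700),
               ln("B", "A", 85, 430, 810),   # same unordered pair, higher bit
               ln("A", "C", 70, 300, 200)), tf)
  lens <- c(A = 500, B = 480, C = 600)
  p <- load_pairs(tf, lens)
  expect_equal(nrow(p), 2L)
  ab <- p[p$seq_b == "B", ]
  expect_equal(ab$bit_score, 810)
  expect_equal(ab$percent_overlap, 100 * 430 / 480)
  filt <- load_pairs(tf, lens, min_identity = 80, min_overlap = 80)
  expect_equal(nrow(filt), 1L)
})

test_that("redundancy removal keeps the longer twin within a dataset", {
  lens <- c("dsA|x" = 500, "dsA|y" = 400, "dsB|z" = 500)
  p <- mk_pairs("dsA|x", "dsA|y", id = 99, ov = 99)
  rr <- remove_redundant(p, lens)
  expect_equal(rr$removed$seq_id, "dsA|y")
  expect_setequal(rr$kept, c("dsA|x", "dsB|z"))
  # cross-dataset identical pair: both kept
  p2 <- mk_pairs("dsA|x", "dsB|z", id = 100, ov = 100)
  rr2 <- remove_redundant(p2, lens)
  expect_equal(nrow(rr2$removed), 0L)
  # equal lengths: the lexicographically later id goes
  lens3 <- c("dsA|x" = 500, "dsA|y" = 500)
  rr3 <- remove_redundant(mk_pairs("dsA|x", "dsA|y", id = 99, ov = 99),
                          lens3)
  expect_equal(rr3$removed$seq_id, "dsA|y")
})

test_that("greedy redundancy chains match an independent replay", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- 12
      ids <- paste0("dsA|s", sprintf("%02d", 1:n))
      lens <- setNames(sample(300:900, n), ids)
      np <- 18
      a <- sample(ids, np, replace = TRUE)
      b <- sample(ids, np, replace = TRUE)
      keep <- a != b
      p <- data.frame(seq_a = pmin(a, b)[keep], seq_b = pmax(a, b)[keep],
                      percent_identity = runif(sum(keep), 90, 100),
                      percent_overlap = runif(sum(keep), 90, 100),
                      e_value = 1e-40, bit_score = runif(sum(keep), 100,
                                                         900),
                      stringsAsFactors = FALSE)
      p <- p[!duplicated(paste(p$seq_a, p$seq_b)), ]
      got <- remove_redundant(p, lens, 95, 95)
      # replay the stated rule independently
      cand <- p[p$percent_identity >= 95 & p$percent_overlap >= 95, ]
      cand <- cand[order(-cand$percent_identity, -cand$bit_score,
                         cand$seq_a, cand$seq_b), ]
      alive <- setNames(rep(TRUE, n), ids)
      for (i in seq_len(nrow(cand))) {
        x <- cand$seq_a[i]; y <- cand$seq_b[i]
        if (!alive[x] || !alive[y]) next
        drop <- if (lens[x] < lens[y]) x
                else if (lens[y] < lens[x]) y else max(x, y)
        alive[drop] <- FALSE
      }
      expect_setequal(got$kept, names(alive)[alive])
      # invariant: no surviving same-dataset pair above both thresholds
      surv <- p[p$seq_a %in% got$kept & p$seq_b %in% got$kept, ]
      expect_false(any(surv$percent_identity >= 95 &
                         surv$percent_overlap >= 95))
    }
  })
})

test_that("transitive closure finds components including singletons", {
  p <- rbind(mk_pairs("A", "B"), mk_pairs("B", "C"))
  cl <- transitive_closure(p, c("A", "B", "C", "D"), 80, 80)
  expect_equal(cl$clusters$size, c(3L, 1L))
  expect_equal(cl$clusters$cluster_id, c("TC80_0000001", "TC80_0000002"))
  expect_true(cl$clusters$is_singleton[2])
  m <- split(cl$members$seq_id, cl$members$cluster_id)
  expect_setequal(m$TC80_0000001, c("A", "B", "C"))
  expect_equal(m$TC80_0000002, "D")
  # no edges: all singletons
  cl0 <- transitive_closure(mk_pairs("A", "B", id = 10), LETTERS[1:4],
                            80, 80)
  expect_true(all(cl0$clusters$is_singleton))
})

test_that("closure equals the reachability oracle on random graphs", {
  withr::with_seed(29, {
    for (rep in 1:30) {
      n <- sample(10:120, 1)
      nodes <- sprintf("n%03d", 1:n)
      ne <- sample(0:(2 * n), 1)
      p <- rand_pair_table(nodes, ne)
      cl <- transitive_closure(p, nodes, 80, 80)
      expect_equal(sum(cl$clusters$size), n)
      got <- lapply(split(cl$members$seq_id, cl$members$cluster_id), sort)
      want <- lapply(oracle_components(nodes, p$seq_a, p$seq_b), sort)
      expect_setequal(unname(vapply(got, paste, "", collapse = ",")),
                      unname(vapply(want, paste, "", collapse = ",")))
    }
  })
})

test_that("raising thresholds never merges clusters", {
  withr::with_seed(37, {
    nodes <- sprintf("n%02d", 1:40)
    a <- sample(nodes, 60, replace = TRUE)
    b <- sample(nodes, 60, replace = TRUE)
    ok <- a != b
    p <- data.frame(seq_a = pmin(a, b)[ok], seq_b = pmax(a, b)[ok],
                    percent_identity = runif(sum(ok), 50, 100),
                    percent_overlap = runif(sum(ok), 50, 100),
                    e_value = 1e-30, bit_score = 100,
                    stringsAsFactors = FALSE)
    sizes <- vapply(c(60, 70, 80, 90), function(th)
      nrow(transitive_closure(p, nodes, th, th)$clusters), integer(1))
    expect_true(all(diff(sizes) >= 0))
  })
})

test_that("cluster import auto-detects both dialects and round-trips", {
  tf <- withr::local_tempfile()
  writeLines(c("c1\tdsA|s1", "c1\tdsA|s2", "c2\tdsB|s3"), tf)
  cl <- import_clusters(tf, "ext")
  expect_equal(cl$method, "imported:ext")
  expect_equal(cl$clusters$size, c(2L, 1L))
  writeLines("OM4_1: dsA|s1 dsB|s2", tf)
  cl2 <- import_clusters(tf, "om")
  expect_equal(cl2$clusters$size, 2L)
  writeLines(c("c1\tdsA|s1", "c2\tdsA|s1"), tf)
  expect_error(import_clusters(tf, "dup"), "two clusters")
  writeLines(c("c1\tdsA|s1", "c1\tdsX|zz"), tf)
  expect_warning(cl3 <- import_clusters(tf, "unk",
                                        seq_ids = c("dsA|s1", "dsB|s3")),
                 "unknown member")
  expect_equal(cl3$clusters$size, 1L)
  # export -> import identity (both dialects)
  for (fmt in c("tsv", "groups")) {
    out <- withr::local_tempfile()
    export_clusters(cl, out, format = fmt)
    back <- import_clusters(out, "ext")
    expect_equal(back$members, cl$members)
  }
})

test_that("majority annotation follows the counting rule", {
  cl <- transitive_closure(rbind(mk_pairs("dsA|s1", "dsA|s2"),
                                 mk_pairs("dsA|s2", "dsB|s3")),
                           c("dsA|s1", "dsA|s2", "dsB|s3"), 80, 80)
  hits <- data.frame(
    seq_id = c("dsA|s1", "dsA|s2", "dsB|s3", "dsB|s3"),
    hit_id = c("PXM16_ARATH", "PXM16_ARATH", "PXM16_ARATH", "H2"),
    e_value = c(0, 1e-100, 1e-50, 1e-200), stringsAsFactors = FALSE)
  got <- assign_cluster_annotation(cl, hits)$clusters
  expect_equal(got$assigned_hit, "PXM16_ARATH")
  expect_equal(got$assigned_hit_pct, 100)
  expect_equal(got$assigned_hit_best_e, 0)
  # 2 of 3 members share H1
  hits2 <- data.frame(seq_id = c("dsA|s1", "dsA|s2", "dsB|s3"),
                      hit_id = c("H1", "H1", "H2"),
                      e_value = c(1e-10, 1e-20, 1e-90),
                      stringsAsFactors = FALSE)
  got2 <- assign_cluster_annotation(cl, hits2)$clusters
  expect_equal(got2$assigned_hit, "H1")
  expect_equal(got2$assigned_hit_pct, 100 * 2 / 3, tolerance = 1e-12)
  # no hits at all
  got3 <- assign_cluster_annotation(cl, hits2[0, ])$clusters
  expect_true(is.na(got3$assigned_hit))
  # permutation stability
  withr::with_seed(3, for (i in 1:5) {
    hp <- hits2[sample(nrow(hits2)), ]
    expect_equal(assign_cluster_annotation(cl, hp)$clusters$assigned_hit,
                 "H1")
  })
})

test_that("composition filters match a predicate scan", {
  tx <- gen_transcriptome(n_seqs = 10, seed = 91, n_datasets = 3,
                          n_groups = 4, group_size = 3,
                          group_identity = 0.9)
  merged_ids <- paste(tx$seqs$dataset_id, tx$seqs$seq_id, sep = "|")
  g <- tx$manifest$groups
  tf <- withr::local_tempfile()
  seqs2 <- tx$seqs; seqs2$seq_id <- merged_ids
  gen_blast_tab_self(seqs2, g, tf, seed = 92)
  lens <- setNames(nchar(tx$seqs$residues), merged_ids)
  cl <- transitive_closure(load_pairs(tf, lens), merged_ids, 80, 80)
  tab <- filter_clusters(cl, composition = list(dsA = "required",
                                                dsB = "excluded"))
  mem <- split(cl$members$seq_id, cl$members$cluster_id)
  want <- names(mem)[vapply(mem, function(v) {
    ds <- txwb:::.dataset_of(v)
    any(ds == "dsA") && !any(ds == "dsB")
  }, logical(1))]
  expect_setequal(tab$cluster_id, want)
  expect_error(filter_clusters(cl, composition = list(nope = "required")),
               "unknown dataset")
  # rpkm-style predicate on members
  tab2 <- filter_clusters(cl, rpkm_predicate = function(v) length(v) >= 3)
  expect_true(all(tab2$size >= 3))
})
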