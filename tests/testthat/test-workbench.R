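test_that("build_project runs every stage and the overview reflects it", {
  ds <- demo_store()
  store <- ds$store
  expect_equal(nrow(store$seqs), 120L)
  expect_equal(length(store$counts$libraries), 3L)
  expect_equal(ncol(store$pvals) - 1L, 2L)
  expect_gt(nrow(store$hits), 0L)
  expect_equal(nrow(store$go$terms), 50L)
  expect_true(any(grepl("stage sequences: done", store$log)))
  out <- capture.output(print(store))
  expect_true(any(grepl("sequences:\\s+120", out)))
})

test_that("a config without a FASTA fails before any stage runs", {
  expect_error(build_project(list(name = "x")), "FASTA")
})

test_that("a failing stage names itself and keeps earlier results", {
  tx <- gen_transcriptome(n_seqs = 5, seed = 1)
  tf <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tx$seqs, tf)
  err <- tryCatch(
    suppressWarnings(
      build_project(list(name = "x", fasta = tf,
                         counts = "/nonexistent/counts.tsv",
                         libraries = list(library_def("L1", "r1"))))),
    error = identity)
  expect_match(conditionMessage(err), "stage 'counts'")
})

test_that("queries filter conjunctively and match the scan oracle", {
  ds <- demo_store()
  store <- ds$store
  all_rows <- query_sequences(store)
  expect_equal(nrow(all_rows), 120L)
  expect_equal(all_rows$seq_id, sort(all_rows$seq_id, method = "radix"))
  # the planted two-column DE query returns exactly the planted rows
  q <- query_sequences(store, filter_spec(pval_max = 1e-10,
                                          pval_columns = c("TiRo", "TiSt"),
                                          pval_mode = "all"))
  expect_setequal(q$seq_id, ds$fx$pvalues$pass_ids)
  # "any" mode is a superset of "all"
  q_any <- query_sequences(store, filter_spec(pval_max = 1e-10,
                                              pval_columns = c("TiRo",
                                                               "TiSt"),
                                              pval_mode = "any"))
  expect_true(all(q$seq_id %in% q_any$seq_id))
  expect_error(filter_spec(pval_max = 1e-10,
                           pval_columns = c("TiRo", "TiSt")),
               "pval_mode")
  expect_error(query_sequences(store, filter_spec(pval_max = 0.1,
                                                  pval_columns = "Nope")),
               "available")
  expect_error(query_sequences(store, columns = "bogus"), "unknown column")
  withr::with_seed(47, {
    for (i in 1:12) {
      f <- random_filter(store)
      expect_equal(query_sequences(store, f)$seq_id,
                   oracle_filter_scan(store, f))
    }
  })
})

test_that("GO queries count direct annotations unless propagated", {
  ds <- demo_store()
  store <- ds$store
  tab <- query_go(store)
  expect_equal(nrow(tab), 50L)
  lv2 <- query_go(store, level = 2)
  expect_true(all(lv2$level == 2L))
  expect_equal(nrow(query_go(store, go_id = "GO:9999999")), 0L)
  # direct counts: per-term distinct annotated sequences
  ann <- store$seq_go
  want <- tapply(ann$seq_id, ann$go_id, function(v) length(unique(v)))
  expect_equal(unname(setNames(tab$n_seqs, tab$go_id)[names(want)]),
               as.integer(want))
  # propagation equals a transitive-ancestor oracle
  prop <- query_go(store, propagate = TRUE)
  anc <- txwb:::.go_ancestors(store$go)
  exp_counts <- integer(0)
  for (t in prop$go_id) {
    covered <- vapply(seq_len(nrow(ann)), function(i)
      ann$go_id[i] == t || t %in% anc[[ann$go_id[i]]], logical(1))
    exp_counts[t] <- length(unique(ann$seq_id[covered]))
  }
  expect_equal(setNames(prop$n_seqs, prop$go_id), exp_counts)
  expect_true(all(prop$n_seqs >= tab$n_seqs))
})

test_that("remarks import, filter, and skip unknown ids", {
  tx <- gen_transcriptome(n_seqs = 6, seed = 2)
  store <- new_project("r")
  store$seqs <- tx$seqs
  store$stats <- seq_stats(tx$seqs)
  tf <- withr::local_tempfile()
  writeLines(c("s0001 rhizome-specific expression",
               "s0002 tip-enriched",
               "ghost unknown sequence"), tf)
  expect_warning(import_remarks(store, tf), "unknown sequence")
  q <- query_sequences(store, filter_spec(remark = "rhizome"))
  expect_equal(q$seq_id, "s0001")
  # multiple remarks per sequence accumulate
  import_remarks(store, data.frame(seq_id = "s0001", remark = "validated"))
  q2 <- query_sequences(store, filter_spec(remark = "validated"))
  expect_equal(q2$seq_id, "s0001")
})

test_that("csv and fasta exports round-trip", {
  ds <- demo_store()
  store <- ds$store
  tab <- query_sequences(store, columns = c("length", "gc", "best_anno_desc"))
  tf <- withr::local_tempfile(fileext = ".csv")
  export_results(tab, tf, kind = "csv")
  back <- read.csv(tf, stringsAsFactors = FALSE)
  expect_equal(back$seq_id, tab$seq_id)
  expect_equal(back$length, tab$length)
  expect_equal(back$gc, tab$gc, tolerance = 1e-12)
  ff <- withr::local_tempfile(fileext = ".fa")
  export_results(store, ff, kind = "fasta", seq_ids = tab$seq_id[1:10])
  re <- read_fasta(ff)
  expect_equal(re$residues,
               store$seqs$residues[match(tab$seq_id[1:10],
                                         store$seqs$seq_id)])
  cf <- withr::local_tempfile(fileext = ".csv")
  export_results(store, cf, kind = "correlation",
                 seq_ids = tab$seq_id[1:5])
  cm <- as.matrix(read.csv(cf, row.names = 1))
  expect_equal(dim(cm), c(5L, 5L))
  expect_equal(unname(diag(cm)), rep(1, 5))
})

test_that("queries do not mutate the store", {
  ds <- demo_store()
  store <- ds$store
  snap <- list(seqs = store$seqs, pvals = store$pvals, hits = store$hits,
               remarks = store$remarks)
  invisible(query_sequences(store, filter_spec(length_min = 500)))
  invisible(query_go(store, propagate = TRUE))
  expect_identical(store$seqs, snap$seqs)
  expect_identical(store$pvals, snap$pvals)
  expect_identical(store$hits, snap$hits)
  expect_identical(store$remarks, snap$remarks)
})

test_that("save and load preserve query results", {
  ds <- demo_store()
  store <- ds$store
  dir <- withr::local_tempdir()
  save_project(store, dir)
  back <- load_project(dir)
  f <- filter_spec(length_min = 400, has_orf = TRUE)
  expect_equal(query_sequences(back, f), query_sequences(store, f))
  expect_equal(query_go(back, level = 2), query_go(store, level = 2))
})

test_that("config files parse sections, libraries and p-value maps", {
  ds <- demo_store()
  cfg <- read_config(file.path(ds$dir, "config.ini"))
  expect_equal(cfg$name, "demo-replicas")
  expect_equal(length(cfg$libraries), 3L)
  expect_equal(cfg$libraries[[1]]$replicates, c("Ro1", "Ro2", "Ro3"))
  expect_equal(names(cfg$pvalues), c("TiRo", "TiSt"))
  expect_equal(cfg$hits[[1]]$taxonomy_tag, "plant")
  expect_true(file.exists(cfg$fasta))
})
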