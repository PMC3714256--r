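test_that("blast tabular parsing reads UniProt ids and normalises strand", {
  tf <- withr::local_tempfile(fileext = ".tab")
  writeLines(paste("s1", "sp|P12345|XXX_ARATH", "91.2", "100", "8", "1",
                   "11", "110", "200", "101", "1e-50", "200",
                   sep = "\t"), tf)
  h <- parse_blast_tab(tf, taxonomy_tag = "plant")
  expect_equal(h$hit_id, "XXX_ARATH")
  expect_equal(h$db_type, "sp")
  expect_equal(h$accession, "P12345")
  expect_equal(h$e_value, 1e-50)
  expect_equal(h$strand, "-")
  expect_equal(c(h$seq_start, h$seq_end), c(10, 110))
  expect_equal(c(h$hit_start, h$hit_end), c(100, 200))

  writeLines(character(0), tf)
  expect_equal(nrow(parse_blast_tab(tf)), 0L)
  writeLines("s1\tonly\tthree", tf)
  expect_error(parse_blast_tab(tf), "12 tab-separated columns.*line 1")
})

test_that("generated hits parse back line by line", {
  tx <- gen_transcriptome(n_seqs = 50, seed = 61)
  tf <- withr::local_tempfile(fileext = ".tab")
  man <- gen_blast_tab_annotation(tx$seqs, tf, seed = 62)
  h <- parse_blast_tab(tf, taxonomy_tag = "plant")
  raw <- read.delim(tf, header = FALSE, stringsAsFactors = FALSE)
  expect_equal(nrow(h), nrow(raw))
  for (i in sample(nrow(raw), 25)) {
    expect_equal(h$seq_id[i], raw$V1[i])
    expect_equal(h$percent_identity[i], raw$V3[i])
    expect_equal(h$seq_start[i], min(raw$V7[i], raw$V8[i]) - 1)
    expect_equal(h$seq_end[i], max(raw$V7[i], raw$V8[i]))
    expect_equal(h$hit_start[i], min(raw$V9[i], raw$V10[i]) - 1)
    expect_equal(h$hit_end[i], max(raw$V9[i], raw$V10[i]))
    expect_equal(h$strand[i], if (raw$V10[i] < raw$V9[i]) "-" else "+")
    expect_equal(h$db_type[i], sub("\\|.*", "", raw$V2[i]))
  }
})

test_that("flat-file records yield descriptions, EC and DR cross-refs", {
  tf <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "ID   PXM16_ARATH             Reviewed;         331 AA.",
    "AC   Q9FKA4; Q8LGD1;",
    "DE   RecName: Full=Peroxidase 16;",
    "DE            EC=1.11.1.7;",
    "OS   Arabidopsis thaliana.",
    "DR   GO; GO:0008150; P:biological_process; IEA.",
    "DR   Pfam; PF00067; p450; 1.",
    "DR   KEGG; ath:AT5G64100; -.",
    "//",
    "XX   no id line here",
    "//"), tf)
  expect_warning(dat <- parse_uniprot_dat(tf), "without an ID line")
  expect_equal(dat$entries$hit_id, "PXM16_ARATH")
  expect_equal(dat$entries$description, "Peroxidase 16")
  expect_equal(dat$entries$accession, "Q9FKA4")
  expect_true(dat$entries$reviewed)
  expect_setequal(dat$xrefs$accession,
                  c("GO:0008150", "PF00067", "ath:AT5G64100", "1.11.1.7"))
  expect_setequal(dat$xrefs$kind, c("GO", "Pfam", "KEGG", "EC"))
})

test_that("synthetic flat file parses back to the generator's ledger", {
  tx <- gen_transcriptome(n_seqs = 30, seed = 63)
  tf <- withr::local_tempfile(fileext = ".tab")
  man <- gen_blast_tab_annotation(tx$seqs, tf, seed = 64)
  dat_p <- withr::local_tempfile(fileext = ".dat")
  obo_p <- withr::local_tempfile(fileext = ".obo")
  db <- gen_dat_and_obo(man, dat_p, obo_p, seed = 65)
  parsed <- parse_uniprot_dat(dat_p)
  expect_equal(parsed$entries$hit_id, db$records$hit_id)
  expect_equal(parsed$entries$description, db$records$description)
  expect_equal(parsed$entries$reviewed, db$records$reviewed)
  got_go <- parsed$xrefs[parsed$xrefs$kind == "GO", ]
  got_go <- got_go[order(got_go$hit_id, got_go$accession), ]
  want <- db$go_xrefs[order(db$go_xrefs$hit_id, db$go_xrefs$go_id), ]
  expect_equal(got_go$accession, want$go_id)
})

test_that("GO levels are shortest is_a paths plus one", {
  tf <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root",
               "namespace: biological_process", "",
               "[Term]", "id: GO:2", "name: a", "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:3", "name: b", "is_a: GO:2 ! a", "",
               "[Term]", "id: GO:4", "name: diamond",
               "is_a: GO:1 ! root", "is_a: GO:3 ! b", "",
               "[Term]", "id: GO:5", "name: dead", "is_obsolete: true",
               ""), tf)
  go <- go_levels(tf)
  lv <- setNames(go$terms$level, go$terms$go_id)
  expect_equal(unname(lv[c("GO:1", "GO:2", "GO:3", "GO:4")]),
               c(1L, 2L, 3L, 2L))
  expect_false("GO:5" %in% go$terms$go_id)
  writeLines(c("[Term]", "id: GO:1", "is_a: GO:2 ! b", "",
               "[Term]", "id: GO:2", "is_a: GO:1 ! a", ""), tf)
  expect_error(go_levels(tf), "cycle")
})

test_that("generated ontology levels match a shortest-path oracle", {
  skip_if_not_installed("igraph")
  tx <- gen_transcriptome(n_seqs = 10, seed = 66)
  tf <- withr::local_tempfile(fileext = ".tab")
  man <- gen_blast_tab_annotation(tx$seqs, tf, seed = 67)
  dat_p <- withr::local_tempfile(); obo_p <- withr::local_tempfile()
  db <- gen_dat_and_obo(man, dat_p, obo_p, n_go = 60, seed = 68)
  go <- go_levels(obo_p)
  expect_equal(setNames(go$terms$level, go$terms$go_id),
               setNames(db$terms$level, db$terms$go_id))
  g <- igraph::graph_from_data_frame(go$edges[, c("child", "parent")],
                                     vertices = go$terms$go_id)
  roots <- setdiff(go$terms$go_id, go$edges$child)
  d <- igraph::distances(g, v = go$terms$go_id, to = roots,
                         mode = "out")
  expect_equal(go$terms$level, unname(apply(d, 1, min)) + 1)
})

test_that("best annotation demotes uninformative descriptions", {
  hits <- data.frame(
    seq_id = "s1", hit_id = c("H1", "H2"), accession = NA,
    db_type = c("sp", "sp"), taxonomy_tag = "plant",
    description = c("Uncharacterized protein At1g01010",
                    "Cytochrome P450"),
    e_value = c(1e-50, 1e-30), bit_score = c(200, 150),
    stringsAsFactors = FALSE)
  ba <- best_annotation(hits)
  expect_equal(ba$best$hit_id, "H1")
  expect_equal(ba$best_anno$hit_id, "H2")
  one <- hits[2, , drop = FALSE]
  ba1 <- best_annotation(one)
  expect_equal(ba1$best, ba1$best_anno)
  allun <- hits; allun$description <- "hypothetical protein"
  expect_null(best_annotation(allun)$best_anno)
})

test_that("hit ranking is a stable total order", {
  withr::with_seed(77, {
    hits <- data.frame(
      seq_id = "s", hit_id = sprintf("H%02d", 1:12), accession = NA,
      db_type = sample(c("sp", "tr", "TF"), 12, replace = TRUE),
      taxonomy_tag = NA,
      description = sample(c("Kinase", "uncharacterized protein"), 12,
                           replace = TRUE),
      e_value = sample(c(1e-10, 1e-20, 1e-30), 12, replace = TRUE),
      bit_score = sample(c(100, 200), 12, replace = TRUE),
      stringsAsFactors = FALSE)
    ref <- best_annotation(hits)
    for (i in 1:10) {
      p <- sample(nrow(hits))
      got <- best_annotation(hits[p, , drop = FALSE])
      expect_equal(got$best$hit_id, ref$best$hit_id)
      expect_equal(got$best_anno$hit_id, ref$best_anno$hit_id)
    }
  })
})

test_that("hit grouping counts sequences per hit id", {
  hits <- data.frame(
    seq_id = c("s1", "s2", "s3", "s3", "s4"),
    hit_id = c("H1", "H1", "H1", "H1", "H2"), accession = NA,
    db_type = "sp", taxonomy_tag = c(rep("plant", 4), "fungal"),
    description = c(rep("Sucrose kinase", 4), "Transporter"),
    e_value = c(1e-5, 1e-9, 1e-7, 1e-6, 1e-3), bit_score = 100,
    stringsAsFactors = FALSE)
  tab <- hit_group_table(hits)
  expect_equal(tab$hit_id, c("H1", "H2"))
  expect_equal(tab$n_seqs, c(3L, 1L))
  expect_equal(tab$best_e, c(1e-9, 1e-3))
  expect_equal(hit_group_table(hits, description_filter = "kinase")$hit_id,
               "H1")
  expect_equal(hit_group_table(hits, taxonomy = "fungal")$hit_id, "H2")
  # group-by oracle on a random fixture
  tx <- gen_transcriptome(n_seqs = 40, seed = 71)
  tf <- withr::local_tempfile()
  gen_blast_tab_annotation(tx$seqs, tf, seed = 72)
  h <- parse_blast_tab(tf)
  tab2 <- hit_group_table(h)
  want <- tapply(h$seq_id, h$hit_id, function(v) length(unique(v)))
  expect_equal(tab2$n_seqs, as.integer(want[tab2$hit_id]))
})

test_that("sequence GO assignment is the union over hits with best e", {
  hits <- data.frame(seq_id = c("s1", "s1"), hit_id = c("H1", "H2"),
                     e_value = c(1e-8, 1e-4), stringsAsFactors = FALSE)
  xr <- data.frame(hit_id = c("H1", "H2", "H2"), kind = "GO",
                   accession = c("GO:1", "GO:1", "GO:2"),
                   stringsAsFactors = FALSE)
  got <- seq_go_annotations(hits, xr)
  expect_equal(got$go_id, c("GO:1", "GO:2"))
  expect_equal(got$best_e, c(1e-8, 1e-4))
})
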