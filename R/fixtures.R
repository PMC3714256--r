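# Seeded synthetic-fixture generators covering every input format the
# workbench reads, each returning a ground-truth manifest so recovery
# experiments can be scored without re-reading generator code. All
# generators are deterministic in `seed` (the caller's RNG state is left
# untouched).

.rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.mutate_seq <- function(s, identity) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n_mut <- round(length(ch) * (1 - identity))
  if (n_mut > 0) {
    pos <- sample(length(ch), n_mut)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic transcriptome with planted homology groups
#'
#' Random nucleotide sequences across one or more pseudo-datasets, plus
#' mutated copies forming known homology groups: each group has one base
#' sequence and `group_size - 1` substitution-mutated copies (no indels, so
#' the realised identity of each copy to its parent is exact), spread
#' round-robin over the datasets. Unrelated sequences are mutually random
#' (~25% background identity).
#'
#' @param n_seqs Ungrouped sequences per dataset.
#' @param len_range Length range in nt (uniform).
#' @param seed Integer seed; same seed, same output, byte for byte.
#' @param n_datasets Number of pseudo-datasets.
#' @param n_groups Number of planted homology groups.
#' @param group_size Members per group.
#' @param group_identity Target parent-copy identity in (0, 1].
#' @param gc_range Per-sequence GC content range.
#' @param dir If given, one FASTA per dataset is written here.
#' @return List with `seqs` (a `txwb_seqs`) and `manifest` (seed, `groups`
#'   data.frame: `seq_id`, `dataset_id`, `group_id`, `parent_id`,
#'   `realized_identity`; `fasta` paths when written).
#' @export
gen_transcriptome <- function(n_seqs = 40, len_range = c(300, 1200),
                              seed = 1, n_datasets = 1, n_groups = 0,
                              group_size = 3, group_identity = 0.85,
                              gc_range = c(0.35, 0.65), dir = NULL) {
  .stop_if(n_seqs < 1, "n_seqs must be >= 1")
  withr::with_seed(seed, {
    datasets <- paste0("ds", LETTERS[seq_len(n_datasets)])
    rows <- list()
    for (d in datasets) {
      for (i in seq_len(n_seqs)) {
        L <- sample(len_range[1]:len_range[2], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sprintf("s%04d", i), dataset_id = d,
          residues = .rand_dna(L, runif(1, gc_range[1], gc_range[2])),
          group_id = NA_character_, parent_id = NA_character_,
          realized_identity = NA_real_, stringsAsFactors = FALSE)
      }
    }
    for (g in seq_len(n_groups)) {
      gid <- sprintf("g%03d", g)
      L <- sample(len_range[1]:len_range[2], 1L)
      base <- .rand_dna(L, runif(1, gc_range[1], gc_range[2]))
      parent <- NA_character_
      for (m in seq_len(group_size)) {
        d <- datasets[(g + m - 2L) %% n_datasets + 1L]
        id <- sprintf("h%03d_%d", g, m)
        res <- if (m == 1L) base else .mutate_seq(base, group_identity)
        ident <- if (m == 1L) NA_real_ else {
          a <- strsplit(base, "")[[1]]; b <- strsplit(res, "")[[1]]
          mean(a == b)
        }
        if (m == 1L) parent <- paste(d, id, sep = "|")
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = id, dataset_id = d, residues = res, group_id = gid,
          parent_id = if (m == 1L) NA_character_ else parent,
          realized_identity = ident, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    seqs <- .as_seqs(data.frame(seq_id = df$seq_id, residues = df$residues,
                                moltype = "nucleotide",
                                dataset_id = df$dataset_id,
                                stringsAsFactors = FALSE))
    manifest <- list(seed = seed,
                     groups = df[, c("seq_id", "dataset_id", "group_id",
                                     "parent_id", "realized_identity")])
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      manifest$fasta <- vapply(datasets, function(d) {
        p <- file.path(dir, paste0(d, ".fa"))
        write_fasta(seqs[seqs$dataset_id == d, , drop = FALSE], p)
        p
      }, character(1))
    }
    list(seqs = seqs, manifest = manifest)
  })
}

#' Generate replicate read counts with planted DE sequences
#'
#' Replicate counts are drawn from a negative binomial around a
#' per-sequence baseline mean (log-uniform); `dispersion = 0` gives the
#' Poisson limit. A fraction of sequences is planted as differentially
#' expressed: their mean is multiplied by `fold` in one designated library
#' (cycled over libraries). The default library shape is six libraries with
#' the first four having five replicates each and the last two a single
#' replicate.
#'
#' @param seqs A `txwb_seqs` (one dataset) whose ids the counts cover.
#' @param replicates_per_lib Named integer vector: replicates per library.
#' @param de_fraction Fraction of sequences planted as DE.
#' @param fold Rate ratio of the planted libraries.
#' @param dispersion Negative-binomial dispersion (0 = Poisson).
#' @param mean_range Baseline mean count range (log-uniform).
#' @param seed Integer seed.
#' @param dir If given, writes `counts.tsv` (matrix dialect) here.
#' @return List with `counts_matrix` (seq x replicate), `libraries` (list
#'   of [library_def()]), and `manifest` (`de` data.frame: `seq_id`,
#'   `de_lib`, `fold`; `path` when written).
#' @export
gen_counts <- function(seqs,
                       replicates_per_lib = c(Ro = 5L, St = 5L, Ti = 5L,
                                              Le = 5L, Fl = 1L, Se = 1L),
                       de_fraction = 0.1, fold = 8, dispersion = 0.1,
                       mean_range = c(20, 500), seed = 1, dir = NULL) {
  .stop_if(de_fraction < 0 || de_fraction > 1,
           "de_fraction must be in [0, 1]")
  withr::with_seed(seed, {
    ids <- seqs$seq_id
    libs <- names(replicates_per_lib)
    reps <- unlist(lapply(libs, function(l)
      if (replicates_per_lib[[l]] == 1L) l else
        paste0(l, seq_len(replicates_per_lib[[l]]))))
    rep2lib <- rep(libs, replicates_per_lib)
    mu <- exp(runif(length(ids), log(mean_range[1]), log(mean_range[2])))
    n_de <- round(de_fraction * length(ids))
    de_idx <- if (n_de > 0) sample(length(ids), n_de) else integer(0)
    de_lib <- libs[(seq_len(n_de) - 1L) %% length(libs) + 1L]
    mu_mat <- matrix(mu, nrow = length(ids), ncol = length(reps),
                     dimnames = list(ids, reps))
    for (k in seq_len(n_de))
      mu_mat[de_idx[k], rep2lib == de_lib[k]] <-
        mu_mat[de_idx[k], rep2lib == de_lib[k]] * fold
    draw <- if (dispersion > 0)
      function(m) rnbinom(length(m), mu = m, size = 1 / dispersion)
    else function(m) rpois(length(m), m)
    cnt <- matrix(draw(mu_mat), nrow = nrow(mu_mat),
                  dimnames = dimnames(mu_mat))
    libraries <- lapply(libs, function(l)
      library_def(l, replicates = reps[rep2lib == l],
                  tissue = l, species = "Synthetica plantae"))
    manifest <- list(seed = seed,
                     de = data.frame(seq_id = ids[de_idx], de_lib = de_lib,
                                     fold = fold,
                                     stringsAsFactors = FALSE))
    if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(dir, "counts.tsv")
      utils::write.table(data.frame(seq_id = rownames(cnt),
                                    as.data.frame(cnt),
                                    check.names = FALSE),
                         p, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$path <- p
    }
    list(counts_matrix = cnt, libraries = libraries, manifest = manifest)
  })
}

.blast_line <- function(q, s, pid, len, mism, gapo, qs, qe, ss, se, ev,
                        bit) {
  paste(q, s, sprintf("%.2f", pid), len, mism, gapo, qs, qe, ss, se,
        format(ev, scientific = TRUE, digits = 3), round(bit, 1),
        sep = "\t")
}

#' Generate a self-BLAST tabular file for planted homology groups
#'
#' Emits one 12-column HSP line per within-group pair; identity is the
#' exact column-wise identity of the two (equal-length, substitution-only)
#' sequences and the overlap is full-length. Sequence ids in the output
#' match `seqs$seq_id` (prefix them first if merged ids are wanted).
#'
#' @param seqs The `txwb_seqs` from [gen_transcriptome()] (ids possibly
#'   re-prefixed).
#' @param groups The manifest `groups` data.frame, same row order as
#'   `seqs`.
#' @param path Output path.
#' @param seed Integer seed (jitters bit scores reproducibly).
#' @return `path` invisibly; attribute `n_pairs` gives the line count.
#' @export
gen_blast_tab_self <- function(seqs, groups, path, seed = 1) {
  withr::with_seed(seed, {
    lines <- character(0)
    for (g in unique(groups$group_id[!is.na(groups$group_id)])) {
      idx <- which(groups$group_id %in% g)
      for (i in idx) {
        L <- nchar(seqs$residues[i])   # every sequence hits itself too
        lines <- c(lines, .blast_line(seqs$seq_id[i], seqs$seq_id[i], 100,
                                      L, 0L, 0L, 1L, L, 1L, L, 1e-180,
                                      2 * L))
      }
      for (i in idx) for (j in idx) {
        if (i >= j) next
        a <- strsplit(seqs$residues[i], "")[[1]]
        b <- strsplit(seqs$residues[j], "")[[1]]
        L <- length(a)
        matches <- sum(a == b)
        pid <- 100 * matches / L
        bit <- 2 * matches + round(runif(1, 0, 5), 1)
        lines <- c(lines,
                   .blast_line(seqs$seq_id[i], seqs$seq_id[j], pid, L,
                               L - matches, 0L, 1L, L, 1L, L,
                               10^-min(180, round(matches / 4)), bit))
      }
    }
    writeLines(lines, path)
    attr(path, "n_pairs") <- length(lines)
    invisible(path)
  })
}

.hit_vocab <- c("Cytochrome P450 71A1", "Peroxidase 16",
                "Chalcone synthase", "MYB transcription factor 12",
                "Auxin response factor 5", "Cellulose synthase A",
                "Sucrose transporter 2", "Heat shock protein 70",
                "Chlorophyll a-b binding protein", "Expansin-A4")

#' Generate annotation BLAST hits against a synthetic UniProt-style universe
#'
#' Every sequence gets one to three hits on synthetic `sp|`/`tr|` subject
#' ids with controlled e-values; every tenth sequence is planted so that
#' its lowest-e-value hit carries an uninformative description (the
#' descriptions themselves are written by [gen_dat_and_obo()]).
#'
#' @param seqs A `txwb_seqs`.
#' @param path Output tabular path.
#' @param n_hit_universe Number of distinct subject entries.
#' @param seed Integer seed.
#' @return Manifest list: `path`, `hit_ids`, `uninformative_hit_ids`,
#'   `planted` (data.frame: `seq_id`, `best_hit`, `best_informative_hit`
#'   — NA when the best hit is informative already).
#' @export
gen_blast_tab_annotation <- function(seqs, path, n_hit_universe = 30,
                                     seed = 1) {
  withr::with_seed(seed, {
    nm <- sprintf("HIT%03d_SYNT", seq_len(n_hit_universe))
    sp <- seq_len(n_hit_universe) %% 2L == 1L
    full <- ifelse(sp, sprintf("sp|P%05d|%s", seq_len(n_hit_universe), nm),
                   sprintf("tr|Q%05d|%s", seq_len(n_hit_universe), nm))
    uninf <- nm[seq(2, n_hit_universe, by = 7L)]
    lines <- character(0)
    planted <- list()
    for (i in seq_len(nrow(seqs))) {
      L <- nchar(seqs$residues[i])
      n_hits <- sample(1:3, 1L)
      hi <- sample(n_hit_universe, n_hits)
      # exponents decreasing, so hit 1 carries the smallest e-value
      ev_exp <- sort(sample(20:120, n_hits), decreasing = TRUE)
      plant_uninf <- i %% 10L == 0L
      if (plant_uninf) {
        u <- which(nm %in% uninf)
        hi[1L] <- u[(i %/% 10L - 1L) %% length(u) + 1L]
        for (k in seq_len(n_hits)[-1L]) {
          if (nm[hi[k]] %in% uninf)
            hi[k] <- sample(setdiff(which(!nm %in% uninf), hi), 1L)
        }
      }
      for (k in seq_len(n_hits)) {
        alen <- sample(seq(50L, max(60L, L %/% 2L)), 1L)
        qs <- sample(seq_len(max(1L, L - alen)), 1L)
        pid <- runif(1, 40, 95)
        rev <- runif(1) < 0.2
        ss <- sample(1:30, 1L)
        se <- ss + alen - 1L
        lines <- c(lines, .blast_line(
          seqs$seq_id[i], full[hi[k]], pid, alen,
          round(alen * (1 - pid / 100)), sample(0:2, 1L), qs,
          qs + alen - 1L, if (rev) se else ss, if (rev) ss else se,
          10^-ev_exp[k], 2 * alen * pid / 100))
      }
      informative <- !nm[hi] %in% uninf
      planted[[i]] <- data.frame(
        seq_id = seqs$seq_id[i], best_hit = nm[hi[1L]],
        best_informative_hit = if (any(informative))
          nm[hi[which(informative)[1L]]] else NA_character_,
        stringsAsFactors = FALSE)
    }
    writeLines(lines, path)
    list(path = path, hit_ids = nm, full_ids = full, sp = sp,
         uninformative_hit_ids = uninf, planted = do.call(rbind, planted))
  })
}

#' Generate a UniProt-dialect flat file and a mini GO ontology
#'
#' One flat-file record per synthetic hit id, with a description (an
#' uninformative "Uncharacterized protein" one for the designated ids), GO
#' and Pfam and KEGG `DR` lines, and an `EC=` field on some records. The
#' OBO ontology has `n_go` terms in one namespace built level by level
#' (every term's parents sit one or more levels above it, so the true level
#' of each term is known by construction), including at least one diamond.
#'
#' @param hit_manifest Manifest from [gen_blast_tab_annotation()].
#' @param dat_path,obo_path Output paths.
#' @param n_go Number of ontology terms (>= 5).
#' @param seed Integer seed.
#' @return Manifest list: `dat_path`, `obo_path`, `records` (data.frame:
#'   `hit_id`, `description`, `reviewed`, `n_go`, `pfam`, `ec`), `go_xrefs`
#'   (data.frame `hit_id`, `go_id`), `terms` (data.frame `go_id`, `level`).
#' @export
gen_dat_and_obo <- function(hit_manifest, dat_path, obo_path, n_go = 50,
                            seed = 1) {
  .stop_if(n_go < 5, "n_go must be >= 5")
  withr::with_seed(seed, {
    go_ids <- sprintf("GO:%07d", seq_len(n_go))
    level <- integer(n_go)
    parents <- vector("list", n_go)
    level[1L] <- 1L                      # namespace root
    level[2L] <- 2L; parents[[2L]] <- go_ids[1L]
    level[3L] <- 2L; parents[[3L]] <- go_ids[1L]
    level[4L] <- 3L; parents[[4L]] <- go_ids[2L]
    # term 5: diamond — two paths of different length to the root
    level[5L] <- 3L; parents[[5L]] <- c(go_ids[2L], go_ids[4L])
    for (t in 6:n_go) {
      np <- sample(1:2, 1L)
      ps <- sample(t - 1L, np)
      parents[[t]] <- go_ids[ps]
      level[t] <- 1L + min(level[ps])
    }
    obo <- c("format-version: 1.2", "")
    for (t in seq_len(n_go)) {
      obo <- c(obo, "[Term]", paste0("id: ", go_ids[t]),
               sprintf("name: synthetic process %03d", t),
               "namespace: biological_process",
               vapply(parents[[t]], function(p)
                 paste0("is_a: ", p, " ! parent"), character(1)), "")
    }
    writeLines(obo, obo_path)

    nm <- hit_manifest$hit_ids
    uninf <- hit_manifest$uninformative_hit_ids
    recs <- character(0)
    rec_rows <- list(); go_xrefs <- list()
    for (k in seq_along(nm)) {
      desc <- if (nm[k] %in% uninf)
        sprintf("Uncharacterized protein At%dg%05d", sample(1:5, 1L),
                sample(1e5, 1L) - 1L)
      else .hit_vocab[(k - 1L) %% length(.hit_vocab) + 1L]
      reviewed <- hit_manifest$sp[k]
      acc <- sub("^..\\|([^|]+)\\|.*$", "\\1", hit_manifest$full_ids[k])
      n_go_k <- sample(1:3, 1L)
      gk <- sample(go_ids, n_go_k)
      pfam <- sprintf("PF%05d", sample(20000L, 1L))
      has_ec <- runif(1) < 0.3
      ec <- sprintf("%d.%d.%d.%d", sample(6, 1L), sample(20, 1L),
                    sample(20, 1L), sample(200, 1L))
      recs <- c(recs,
                sprintf("ID   %s              %s;         %d AA.", nm[k],
                        if (reviewed) "Reviewed" else "Unreviewed",
                        sample(100:900, 1L)),
                sprintf("AC   %s;", acc),
                sprintf("DE   RecName: Full=%s;", desc),
                if (has_ec) sprintf("DE            EC=%s;", ec),
                "OS   Synthetica plantae.",
                vapply(gk, function(g)
                  sprintf("DR   GO; %s; P:synthetic process; IEA.", g),
                  character(1)),
                sprintf("DR   KEGG; syn:%05d; -.", sample(99999L, 1L)),
                sprintf("DR   Pfam; %s; Synth; 1.", pfam),
                "//")
      rec_rows[[k]] <- data.frame(hit_id = nm[k], description = desc,
                                  reviewed = reviewed, n_go = n_go_k,
                                  pfam = pfam,
                                  ec = if (has_ec) ec else NA_character_,
                                  stringsAsFactors = FALSE)
      go_xrefs[[k]] <- data.frame(hit_id = nm[k], go_id = .sortc(gk),
                                  stringsAsFactors = FALSE)
    }
    writeLines(recs, dat_path)
    list(dat_path = dat_path, obo_path = obo_path,
         records = do.call(rbind, rec_rows),
         go_xrefs = do.call(rbind, go_xrefs),
         terms = data.frame(go_id = go_ids, level = level,
                            stringsAsFactors = FALSE))
  })
}

#' Generate pileup columns with planted variants
#'
#' For each selected contig, every position gets `depth` reads: planted
#' variant positions (rate `snp_rate`) draw the variant allele at fraction
#' ~0.5, and every other read is miscalled to a uniform other base with
#' probability `err`.
#'
#' @param seqs A `txwb_seqs` providing the reference residues.
#' @param contig_ids Which sequences to pile up (default: first 5).
#' @param depth Mean read depth per position.
#' @param err Base-call error rate.
#' @param snp_rate Per-position probability of a planted variant.
#' @param seed Integer seed.
#' @param path If given, the pileup TSV is written here.
#' @return List with `pileup` (data.frame as [read_pileup()] returns) and
#'   `manifest` (`planted` data.frame: `contig`, `pos`, `ref`, `alt`;
#'   `path` when written).
#' @export
gen_pileups <- function(seqs, contig_ids = head(seqs$seq_id, 5L),
                        depth = 30, err = 0.01, snp_rate = 0.01, seed = 1,
                        path = NULL) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    rows <- list(); planted <- list()
    for (cid in contig_ids) {
      ref <- strsplit(seqs$residues[seqs$seq_id == cid], "")[[1]]
      for (pos in seq_along(ref)) {
        if (!ref[pos] %in% bases) next
        n <- max(1L, rpois(1L, depth))
        is_var <- runif(1) < snp_rate
        alt <- if (is_var) sample(setdiff(bases, ref[pos]), 1L) else
          NA_character_
        k_alt <- if (is_var) rbinom(1L, n, 0.5) else 0L
        cnt <- setNames(c(0L, 0L, 0L, 0L, 0L), c(bases, "gap"))
        cnt[ref[pos]] <- n - k_alt
        if (is_var) cnt[alt] <- cnt[alt] + k_alt
        # sequencing errors on the non-variant reads
        n_err <- rbinom(1L, n - k_alt, err)
        if (n_err > 0L) {
          to <- sample(setdiff(bases, ref[pos]), n_err, replace = TRUE)
          cnt[ref[pos]] <- cnt[ref[pos]] - n_err
          for (b in to) cnt[b] <- cnt[b] + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          contig = cid, pos = pos - 1L, ref = ref[pos],
          A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
          gap = cnt[["gap"]], stringsAsFactors = FALSE)
        if (is_var && k_alt > 0L)
          planted[[length(planted) + 1L]] <- data.frame(
            contig = cid, pos = pos - 1L, ref = ref[pos], alt = alt,
            k = k_alt, n = n, stringsAsFactors = FALSE)
      }
    }
    pileup <- do.call(rbind, rows)
    manifest <- list(seed = seed,
                     planted = if (length(planted)) do.call(rbind, planted)
                     else data.frame(contig = character(), pos = integer(),
                                     ref = character(), alt = character(),
                                     k = integer(), n = integer(),
                                     stringsAsFactors = FALSE))
    if (!is.null(path)) {
      utils::write.table(pileup, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$path <- path
    }
    list(pileup = pileup, manifest = manifest)
  })
}

#' Generate planted DE p-value columns
#'
#' Writes one two-column TSV per requested column. A designated subset of
#' sequences passes every column at far below the cutoff (planted p =
#' 1e-15); all other sequences get p-values drawn well above it.
#'
#' @param seq_ids Sequence ids.
#' @param columns Column names (e.g. `c("TiRo", "TiSt")`).
#' @param n_pass How many sequences pass all columns.
#' @param cutoff The query cutoff the fixture is built around.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return Manifest list: `paths` (named), `pass_ids`.
#' @export
gen_pvalues <- function(seq_ids, columns = c("TiRo", "TiSt"), n_pass = 10,
                        cutoff = 1e-10, dir = tempdir(), seed = 1) {
  withr::with_seed(seed, {
    pass <- .sortc(sample(seq_ids, n_pass))
    paths <- setNames(file.path(dir, paste0(columns, ".tsv")), columns)
    for (ci in seq_along(columns)) {
      p <- ifelse(seq_ids %in% pass, 1e-15,
                  10^runif(length(seq_ids), log10(cutoff) + 1, 0))
      # a few near-misses that pass one column only
      miss <- sample(setdiff(seq_ids, pass), min(5L, length(seq_ids) -
                                                   n_pass))
      if (ci == 1L) p[seq_ids %in% miss] <- cutoff / 10
      utils::write.table(data.frame(seq_ids, p), paths[ci], sep = "\t",
                         quote = FALSE, row.names = FALSE,
                         col.names = FALSE)
    }
    list(paths = paths, pass_ids = pass)
  })
}

#' Generate a remarks file
#'
#' @param seq_ids Sequence ids to remark on.
#' @param path Output path.
#' @param seed Integer seed.
#' @return Manifest data.frame (`seq_id`, `remark`), invisibly; file
#'   written at `path`.
#' @export
gen_remarks <- function(seq_ids, path, seed = 1) {
  withr::with_seed(seed, {
    vocab <- c("rhizome-specific", "tip-enriched", "low-confidence",
               "validated by qPCR", "candidate transporter")
    rem <- sample(vocab, length(seq_ids), replace = TRUE)
    writeLines(paste(seq_ids, rem), path)
    invisible(data.frame(seq_id = seq_ids, remark = rem,
                         stringsAsFactors = FALSE))
  })
}

#' Write a complete demo fixture set
#'
#' Three presets mirroring typical single/multi project shapes:
#' `"demo-replicas"` (one dataset, three libraries with three replicates
#' each, planted DE, annotation hits + flat-file records + ontology,
#' pileups, p-value columns and remarks, plus a ready-to-build config
#' file), `"demo-two-lib"` (two single-replicate libraries, counts only)
#' and `"demo-multi"` (four datasets with planted homology groups and a
#' self-BLAST file for the comparison path).
#'
#' @param preset One of `"demo-replicas"`, `"demo-two-lib"`,
#'   `"demo-multi"`.
#' @param dir Output directory (created).
#' @param seed Integer seed; every file is deterministic in it.
#' @return List of manifests (and `config` path for the single-project
#'   presets).
#' @export
fixture_preset <- function(preset = c("demo-replicas", "demo-two-lib",
                                      "demo-multi"),
                           dir, seed = 101) {
  preset <- match.arg(preset)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (preset == "demo-replicas") {
    tx <- gen_transcriptome(n_seqs = 120, len_range = c(300, 1200),
                            seed = seed, dir = dir)
    reps <- c(Ro = 3L, St = 3L, Ti = 3L)
    cn <- gen_counts(tx$seqs, replicates_per_lib = reps,
                     de_fraction = 0.15, fold = 8,
                     seed = seed + 1L, dir = dir)
    pv <- gen_pvalues(tx$seqs$seq_id, columns = c("TiRo", "TiSt"),
                      n_pass = 10, dir = dir, seed = seed + 2L)
    an <- gen_blast_tab_annotation(tx$seqs, file.path(dir, "hits.tab"),
                                   seed = seed + 3L)
    db <- gen_dat_and_obo(an, file.path(dir, "uniprot.dat"),
                          file.path(dir, "go.obo"), seed = seed + 4L)
    pu <- gen_pileups(tx$seqs, contig_ids = head(tx$seqs$seq_id, 3L),
                      seed = seed + 5L, path = file.path(dir,
                                                         "pileup.tsv"))
    rm_ <- gen_remarks(head(tx$seqs$seq_id, 20L),
                       file.path(dir, "remarks.txt"), seed = seed + 6L)
    cfg <- c("[project]", "name = demo-replicas", "fasta = dsA.fa",
             "counts = counts.tsv", "dat = uniprot.dat", "obo = go.obo",
             "pileup = pileup.tsv", "remarks = remarks.txt",
             "min_orf = 90",
             "", "[library:Ro]", "replicates = Ro1,Ro2,Ro3",
             "tissue = root",
             "", "[library:St]", "replicates = St1,St2,St3",
             "tissue = stem",
             "", "[library:Ti]", "replicates = Ti1,Ti2,Ti3",
             "tissue = tip",
             "", "[hits:uniprot]", "path = hits.tab", "taxonomy = plant",
             "", "[pvalues]", "TiRo = TiRo.tsv", "TiSt = TiSt.tsv")
    writeLines(cfg, file.path(dir, "config.ini"))
    list(config = file.path(dir, "config.ini"), transcriptome = tx,
         counts = cn, pvalues = pv, annotation = an, database = db,
         pileups = pu, remarks = rm_)
  } else if (preset == "demo-two-lib") {
    tx <- gen_transcriptome(n_seqs = 80, len_range = c(300, 900),
                            seed = seed, dir = dir)
    cn <- gen_counts(tx$seqs, replicates_per_lib = c(Lf = 1L, Rt = 1L),
                     de_fraction = 0.1, fold = 8, dispersion = 0,
                     seed = seed + 1L, dir = dir)
    cfg <- c("[project]", "name = demo-two-lib", "fasta = dsA.fa",
             "counts = counts.tsv",
             "", "[library:Lf]", "tissue = leaf",
             "", "[library:Rt]", "tissue = root")
    writeLines(cfg, file.path(dir, "config.ini"))
    list(config = file.path(dir, "config.ini"), transcriptome = tx,
         counts = cn)
  } else {
    tx <- gen_transcriptome(n_seqs = 30, len_range = c(300, 900),
                            seed = seed, n_datasets = 4, n_groups = 6,
                            group_size = 4, group_identity = 0.88,
                            dir = dir)
    merged <- tx$seqs
    merged$seq_id <- paste(merged$dataset_id, merged$seq_id, sep = "|")
    gen_blast_tab_self(merged, tx$manifest$groups,
                       file.path(dir, "selfblast.tab"), seed = seed + 1L)
    list(transcriptome = tx,
         selfblast = file.path(dir, "selfblast.tab"))
  }
}
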