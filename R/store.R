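# The project store: an in-memory relational set of tables (one environment
# per project) serialised to a directory of plain TSV files. It holds
# sequences, libraries, counts, expression values, imported p-value columns,
# annotation hits, cross-references, the GO graph, SNP calls and remarks,
# plus a build log. Queries never mutate the store.

#' Create an empty project store
#'
#' @param name Project name.
#' @return A `txwb_project` environment.
#' @export
new_project <- function(name = "project") {
  p <- new.env(parent = emptyenv())
  p$name <- name
  p$seqs <- NULL; p$stats <- NULL
  p$counts <- NULL; p$rpkm <- NULL; p$rstat <- NULL
  p$pvals <- NULL
  p$hits <- .empty_hits()
  p$db_entries <- NULL; p$xrefs <- NULL
  p$go <- NULL; p$seq_go <- NULL
  p$snps <- NULL
  p$remarks <- data.frame(seq_id = character(), remark = character(),
                          stringsAsFactors = FALSE)
  p$log <- character(0)
  class(p) <- "txwb_project"
  p
}

.log_stage <- function(store, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "  ", ...)
  store$log <- c(store$log, msg)
  invisible(msg)
}

.run_stage <- function(store, stage, expr) {
  .log_stage(store, "stage ", stage, ": start")
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  .log_stage(store, "stage ", stage, ": done")
}

#' Build a project store from a configuration
#'
#' Runs the single-project pipeline stage by stage: load sequences, compute
#' per-sequence statistics, import counts and compute RPKM and the R
#' statistic, import externally computed DE p-value columns, load annotation
#' hits and database records and the GO graph, call SNPs from pileups, and
#' import remarks. Any missing input simply skips its stage; a failing stage
#' aborts with the stage name, leaving earlier stages' results in place.
#'
#' @param config A list (or path to a config file, see [read_config()]) with
#'   elements: `name`; `fasta` (path) or `seqs` (a `txwb_seqs`); `moltype`;
#'   `dataset_id`; `min_orf`; `counts` (matrix TSV path, named per-replicate
#'   paths, or matrix) with `libraries` (list of [library_def()]);
#'   `pvalues` (named list of two-column TSV paths); `hits` (list of
#'   `list(path, source_db, taxonomy_tag)`); `dat` (flat-file path); `obo`
#'   (ontology path); `pileup` (path) with optional `snp_err`, `snp_alpha`,
#'   `snp_min_confirm`; `remarks` (path).
#' @return A `txwb_project` store.
#' @export
build_project <- function(config) {
  if (is.character(config)) config <- read_config(config)
  .stop_if(is.null(config$fasta) && is.null(config$seqs),
           "config must name a FASTA file (or provide sequences)")
  store <- new_project(config$name %||% "project")
  min_orf <- config$min_orf %||% 90L

  .run_stage(store, "sequences", {
    store$seqs <- if (!is.null(config$seqs)) config$seqs else
      read_fasta(config$fasta,
                 moltype = config$moltype %||% "auto",
                 dataset_id = config$dataset_id %||% store$name)
    store$stats <- seq_stats(store$seqs, min_orf = min_orf)
  })

  if (!is.null(config$counts)) .run_stage(store, "counts", {
    .stop_if(is.null(config$libraries), "counts given without libraries")
    store$counts <- import_counts(config$counts, config$libraries,
                                  seq_ids = store$seqs$seq_id)
    lens <- setNames(store$stats$length, store$stats$seq_id)
    store$rpkm <- rpkm_matrix(store$counts, lens)
    store$rstat <- r_statistic_all(store$counts)
  })

  for (nm in names(config$pvalues %||% list())) .run_stage(
    store, paste0("pvalue:", nm),
    add_pvalue_column(store, nm, config$pvalues[[nm]]))

  for (h in config$hits %||% list()) .run_stage(store, "annotation", {
    hits <- parse_blast_tab(h$path,
                            source_db = h$source_db %||% basename(h$path),
                            taxonomy_tag = h$taxonomy_tag %||% NA_character_)
    store$hits <- rbind(store$hits, hits)
  })

  if (!is.null(config$dat)) .run_stage(store, "database-records", {
    dat <- parse_uniprot_dat(config$dat)
    store$db_entries <- dat$entries
    store$xrefs <- dat$xrefs
    store$hits <- attach_descriptions(store$hits, dat)
    store$seq_go <- seq_go_annotations(store$hits, dat$xrefs)
  })

  if (!is.null(config$obo)) .run_stage(store, "go-graph",
    store$go <- go_levels(config$obo))

  if (!is.null(config$pileup)) .run_stage(store, "snps", {
    store$snps <- call_snps(read_pileup(config$pileup),
                            e = config$snp_err %||% 0.01,
                            alpha = config$snp_alpha %||% 1e-3,
                            min_confirm = config$snp_min_confirm %||% 2L)
  })

  if (!is.null(config$remarks)) .run_stage(store, "remarks",
    import_remarks(store, config$remarks))

  store
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a key = value configuration file
#'
#' Sections in square brackets group keys; `[library:<id>]` sections define
#' libraries (`replicates = r1,r2,...` plus metadata keys), `[hits:<db>]`
#' sections annotation hit files (`path`, `taxonomy`), `[pvalues]` maps
#' column names to files, and `[project]` holds `name`, `fasta`,
#' `dataset_id`, `min_orf`, `counts`, `dat`, `obo`, `pileup`, `snp_err`,
#' `snp_alpha`, `snp_min_confirm`, `remarks`. Relative paths are resolved
#' against the config file's directory.
#'
#' @param path Config file path.
#' @return A config list for [build_project()].
#' @export
read_config <- function(path) {
  .stop_if(!file.exists(path), "config file not found: ", path)
  base <- dirname(normalizePath(path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  kv <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (is.null(kv[[section]])) kv[[section]] <- list()
    } else {
      .stop_if(!grepl("=", ln, fixed = TRUE),
               "config line is not key = value: ", ln)
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      kv[[section]][[key]] <- val
    }
  }
  rel <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  pr <- kv[["project"]] %||% list()
  cfg <- list(name = pr$name, dataset_id = pr$dataset_id,
              moltype = pr$moltype %||% "auto")
  if (!is.null(pr$fasta)) cfg$fasta <- rel(pr$fasta)
  if (!is.null(pr$min_orf)) cfg$min_orf <- as.integer(pr$min_orf)
  if (!is.null(pr$counts)) cfg$counts <- rel(pr$counts)
  if (!is.null(pr$dat)) cfg$dat <- rel(pr$dat)
  if (!is.null(pr$obo)) cfg$obo <- rel(pr$obo)
  if (!is.null(pr$pileup)) cfg$pileup <- rel(pr$pileup)
  if (!is.null(pr$remarks)) cfg$remarks <- rel(pr$remarks)
  for (k in c("snp_err", "snp_alpha")) {
    if (!is.null(pr[[k]])) cfg[[k]] <- as.numeric(pr[[k]])
  }
  if (!is.null(pr$snp_min_confirm))
    cfg$snp_min_confirm <- as.integer(pr$snp_min_confirm)
  lib_sections <- grep("^library:", names(kv), value = TRUE)
  if (length(lib_sections) > 0L) {
    cfg$libraries <- lapply(lib_sections, function(s) {
      v <- kv[[s]]
      lib_id <- sub("^library:", "", s)
      reps <- if (!is.null(v$replicates))
        trimws(strsplit(v$replicates, ",")[[1]]) else lib_id
      library_def(lib_id, replicates = reps,
                  title = v$title %||% NA, species = v$species %||% NA,
                  cultivar = v$cultivar %||% NA, strain = v$strain %||% NA,
                  tissue = v$tissue %||% NA,
                  treatment = v$treatment %||% NA,
                  sequencing_lab = v$sequencing_lab %||% NA,
                  year = v$year %||% NA)
    })
  }
  hit_sections <- grep("^hits:", names(kv), value = TRUE)
  if (length(hit_sections) > 0L) {
    cfg$hits <- lapply(hit_sections, function(s) {
      v <- kv[[s]]
      .stop_if(is.null(v$path), "section [", s, "] needs a path")
      list(path = rel(v$path), source_db = sub("^hits:", "", s),
           taxonomy_tag = v$taxonomy %||% NA_character_)
    })
  }
  if (!is.null(kv[["pvalues"]]))
    cfg$pvalues <- lapply(kv[["pvalues"]], rel)
  cfg
}

#' Import a DE p-value column
#'
#' Adds a named column of externally computed differential-expression
#' p-values (two-column delimited file `seq_id<TAB>p`, or a data.frame) to
#' the project. Sequences without a value get NA. Columns are the unit of
#' add/remove: re-import under an existing name requires `overwrite`.
#'
#' @param store A `txwb_project`.
#' @param name Column name (e.g. `"TiRo"` for a tip-vs-root contrast).
#' @param x File path or data.frame with columns seq id and p.
#' @param overwrite Allow replacing an existing column?
#' @return The store, invisibly (modified in place).
#' @export
add_pvalue_column <- function(store, name, x, overwrite = FALSE) {
  .stop_if(is.null(store$seqs), "project has no sequences yet")
  if (is.null(store$pvals))
    store$pvals <- data.frame(seq_id = store$seqs$seq_id,
                              stringsAsFactors = FALSE)
  .stop_if(name %in% colnames(store$pvals) && !overwrite,
           "p-value column '", name, "' already exists")
  if (is.character(x)) {
    df <- read.delim(x, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    if (identical(tolower(as.character(df[1, 2])), "p") ||
        is.na(suppressWarnings(as.numeric(df[1, 2]))))
      df <- df[-1, , drop = FALSE]   # tolerate a header line
    p <- suppressWarnings(as.numeric(df[[2]]))
    bad <- which(is.na(p) | p < 0 | p > 1)
    .stop_if(length(bad) > 0L, "p-value outside [0,1] in ", x, " line ",
             bad[1L])
    ids <- as.character(df[[1]])
  } else {
    ids <- as.character(x[[1]])
    p <- as.numeric(x[[2]])
    bad <- which(is.na(p) | p < 0 | p > 1)
    .stop_if(length(bad) > 0L, "p-value outside [0,1] at row ", bad[1L])
  }
  col <- rep(NA_real_, nrow(store$pvals))
  m <- match(ids, store$pvals$seq_id)
  col[m[!is.na(m)]] <- p[!is.na(m)]
  store$pvals[[name]] <- col
  .log_stage(store, "p-value column '", name, "' imported (",
             sum(!is.na(col)), " values)")
  invisible(store)
}

#' Remove a DE p-value column
#'
#' @param store A `txwb_project`.
#' @param name Column to drop.
#' @return The store, invisibly.
#' @export
remove_pvalue_column <- function(store, name) {
  .stop_if(is.null(store$pvals) || !name %in% colnames(store$pvals),
           "no p-value column '", name, "'")
  store$pvals[[name]] <- NULL
  if (ncol(store$pvals) == 1L) store$pvals <- NULL
  .log_stage(store, "p-value column '", name, "' removed")
  invisible(store)
}

#' Import sequence remarks
#'
#' Each line is `seq_id <whitespace> free-text remark`. Multiple remarks per
#' sequence accumulate; lines naming unknown sequences are skipped with a
#' warning. Remarks are substring-filterable through [filter_spec()].
#'
#' @param store A `txwb_project`.
#' @param x Path to a remarks file, or a data.frame (seq_id, remark).
#' @return The store, invisibly.
#' @export
import_remarks <- function(store, x) {
  if (is.character(x)) {
    lines <- readLines(x)
    lines <- lines[nzchar(trimws(lines))]
    ids <- sub("\\s.*$", "", lines)
    txt <- trimws(sub("^\\S+\\s*", "", lines))
    df <- data.frame(seq_id = ids, remark = txt, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(seq_id = as.character(x[[1]]),
                     remark = as.character(x[[2]]),
                     stringsAsFactors = FALSE)
  }
  known <- df$seq_id %in% store$seqs$seq_id
  if (any(!known)) {
    warning(sum(!known), " remark(s) for unknown sequence id(s) skipped: ",
            paste(head(unique(df$seq_id[!known]), 5L), collapse = ", "),
            call. = FALSE)
    .log_stage(store, sum(!known), " unknown remark id(s) skipped")
  }
  store$remarks <- rbind(store$remarks, df[known, , drop = FALSE])
  invisible(store)
}

#' Specify sequence-table filters
#'
#' All set filters are combined by AND. The p-value clause tests the listed
#' columns at `pval_max` under `pval_mode` `"all"` (every listed column
#' passes) or `"any"`; the mode must be given explicitly when more than one
#' column is listed.
#'
#' @param rpkm_min Named numeric: per-library minimum RPKM.
#' @param pval_max P-value cutoff applied to `pval_columns`.
#' @param pval_columns Character vector of imported column names.
#' @param pval_mode `"all"` or `"any"`.
#' @param fold List `list(a = lib, b = lib, min_abs = x, pseudo = 0.1)`:
#'   keep sequences with |log2 fold change| of RPKM between two libraries
#'   at least `min_abs`.
#' @param length_min,length_max Sequence length bounds (nt).
#' @param has_orf Logical: require (or forbid) an ORF call.
#' @param anno_keyword Case-insensitive substring of the best informative
#'   annotation's description.
#' @param taxonomy Taxonomy tag: keep sequences with at least one hit so
#'   tagged.
#' @param go_id,go_keyword,go_level Keep sequences annotated to a GO term
#'   matching the id / name substring / level.
#' @param remark Case-insensitive substring of any remark.
#' @return A `txwb_filter` list.
#' @export
filter_spec <- function(rpkm_min = NULL, pval_max = NULL,
                        pval_columns = NULL, pval_mode = NULL, fold = NULL,
                        length_min = NULL, length_max = NULL, has_orf = NULL,
                        anno_keyword = NULL, taxonomy = NULL, go_id = NULL,
                        go_keyword = NULL, go_level = NULL, remark = NULL) {
  if (!is.null(pval_max)) {
    .stop_if(is.null(pval_columns), "pval_max needs pval_columns")
    .stop_if(length(pval_columns) > 1L && is.null(pval_mode),
             "pval_mode ('all' or 'any') is required for >1 p-value column")
    if (is.null(pval_mode)) pval_mode <- "all"
    .stop_if(!pval_mode %in% c("all", "any"),
             "pval_mode must be 'all' or 'any'")
  }
  structure(list(rpkm_min = rpkm_min, pval_max = pval_max,
                 pval_columns = pval_columns, pval_mode = pval_mode,
                 fold = fold, length_min = length_min,
                 length_max = length_max, has_orf = has_orf,
                 anno_keyword = anno_keyword, taxonomy = taxonomy,
                 go_id = go_id, go_keyword = go_keyword,
                 go_level = go_level, remark = remark),
            class = "txwb_filter")
}

# the master per-sequence table every query filters over
.seq_table <- function(store) {
  tab <- data.frame(seq_id = store$seqs$seq_id,
                    dataset_id = store$seqs$dataset_id,
                    moltype = store$seqs$moltype,
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, store$stats[match(tab$seq_id, store$stats$seq_id),
                                c("length", "gc", "n_orfs",
                                  "longest_orf_nt", "has_orf")])
  if (!is.null(store$rpkm)) {
    r <- store$rpkm[match(tab$seq_id, rownames(store$rpkm)), ,
                    drop = FALSE]
    colnames(r) <- paste0("rpkm_", colnames(r))
    tab <- cbind(tab, as.data.frame(r))
  }
  if (!is.null(store$pvals))
    tab <- cbind(tab,
                 store$pvals[match(tab$seq_id, store$pvals$seq_id), -1L,
                             drop = FALSE])
  if (nrow(store$hits) > 0L) {
    per_seq <- split(store$hits, store$hits$seq_id)
    ba <- lapply(per_seq, best_annotation)
    idx <- match(tab$seq_id, names(ba))
    get <- function(which, field, default) {
      vapply(idx, function(i) {
        if (is.na(i)) return(default)
        h <- ba[[i]][[which]]
        if (is.null(h)) default else h[[field]]
      }, default)
    }
    tab$best_hit <- get("best", "hit_id", NA_character_)
    tab$best_e <- get("best", "e_value", NA_real_)
    tab$best_anno <- get("best_anno", "hit_id", NA_character_)
    tab$best_anno_desc <- get("best_anno", "description", NA_character_)
    tab$best_anno_e <- get("best_anno", "e_value", NA_real_)
    tab$best_anno_db <- get("best_anno", "db_type", NA_character_)
  }
  if (nrow(store$remarks) > 0L) {
    rem <- vapply(split(store$remarks$remark, store$remarks$seq_id),
                  paste, character(1), collapse = "; ")
    tab$remark <- unname(rem[tab$seq_id])
  } else {
    tab$remark <- NA_character_
  }
  rownames(tab) <- NULL
  tab
}

.filter_mask <- function(store, tab, filter) {
  keep <- rep(TRUE, nrow(tab))
  f <- filter
  if (!is.null(f$rpkm_min)) {
    .stop_if(is.null(store$rpkm), "no RPKM values in this project")
    for (lib in names(f$rpkm_min)) {
      col <- paste0("rpkm_", lib)
      .stop_if(!col %in% colnames(tab), "unknown library: ", lib)
      keep <- keep & !is.na(tab[[col]]) & tab[[col]] >= f$rpkm_min[[lib]]
    }
  }
  if (!is.null(f$pval_max)) {
    miss <- setdiff(f$pval_columns, colnames(tab))
    .stop_if(length(miss) > 0L, "unknown p-value column(s): ",
             paste(miss, collapse = ", "), "; available: ",
             paste(colnames(store$pvals)[-1L], collapse = ", "))
    pm <- as.matrix(tab[, f$pval_columns, drop = FALSE])
    pass <- !is.na(pm) & pm <= f$pval_max
    keep <- keep & if (identical(f$pval_mode, "any")) rowSums(pass) >= 1L
                   else rowSums(pass) == ncol(pass)
  }
  if (!is.null(f$fold)) {
    a <- paste0("rpkm_", f$fold$a); b <- paste0("rpkm_", f$fold$b)
    .stop_if(!all(c(a, b) %in% colnames(tab)), "unknown library in fold")
    fc <- fold_change(tab[[a]], tab[[b]], pseudo = f$fold$pseudo %||% 0.1)
    keep <- keep & !is.na(fc) & abs(fc) >= f$fold$min_abs
  }
  if (!is.null(f$length_min)) keep <- keep & tab$length >= f$length_min
  if (!is.null(f$length_max)) keep <- keep & tab$length <= f$length_max
  if (!is.null(f$has_orf))
    keep <- keep & !is.na(tab$has_orf) & tab$has_orf == f$has_orf
  if (!is.null(f$anno_keyword)) {
    d <- tolower(ifelse(is.na(tab$best_anno_desc), "", tab$best_anno_desc))
    keep <- keep & grepl(tolower(f$anno_keyword), d, fixed = TRUE)
  }
  if (!is.null(f$taxonomy)) {
    tagged <- unique(store$hits$seq_id[store$hits$taxonomy_tag %in%
                                         f$taxonomy])
    keep <- keep & tab$seq_id %in% tagged
  }
  if (!is.null(f$go_id) || !is.null(f$go_keyword) ||
      !is.null(f$go_level)) {
    .stop_if(is.null(store$seq_go), "no GO annotations in this project")
    terms <- store$go$terms %||%
      data.frame(go_id = unique(store$seq_go$go_id), name = "",
                 level = NA_integer_, stringsAsFactors = FALSE)
    sel <- rep(TRUE, nrow(terms))
    if (!is.null(f$go_id)) sel <- sel & terms$go_id %in% f$go_id
    if (!is.null(f$go_keyword))
      sel <- sel & grepl(tolower(f$go_keyword), tolower(terms$name),
                         fixed = TRUE)
    if (!is.null(f$go_level)) sel <- sel & terms$level %in% f$go_level
    hit_seqs <- unique(store$seq_go$seq_id[store$seq_go$go_id %in%
                                             terms$go_id[sel]])
    keep <- keep & tab$seq_id %in% hit_seqs
  }
  if (!is.null(f$remark)) {
    r <- tolower(ifelse(is.na(tab$remark), "", tab$remark))
    keep <- keep & grepl(tolower(f$remark), r, fixed = TRUE)
  }
  keep
}

#' Query the sequence table
#'
#' Applies a [filter_spec()] to the project's master sequence table and
#' returns the selected rows and columns, ordered by `seq_id` as the final
#' tiebreak.
#'
#' @param store A `txwb_project`.
#' @param filter A `txwb_filter` (default: empty filter, all sequences).
#' @param columns Optional character vector of columns to keep (seq_id is
#'   always kept); unknown names are an error listing what is available.
#' @return data.frame of matching sequences.
#' @export
query_sequences <- function(store, filter = filter_spec(), columns = NULL) {
  tab <- .seq_table(store)
  keep <- .filter_mask(store, tab, filter)
  out <- tab[keep, , drop = FALSE]
  out <- out[.ordc(out$seq_id), , drop = FALSE]
  if (!is.null(columns)) {
    miss <- setdiff(columns, colnames(out))
    .stop_if(length(miss) > 0L, "unknown column(s): ",
             paste(miss, collapse = ", "), "; available: ",
             paste(colnames(out), collapse = ", "))
    out <- out[, unique(c("seq_id", columns)), drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Query GO terms with sequence counts
#'
#' One row per ontology term passing the filters, with the number of
#' sequences annotated to it. By default only direct annotations count;
#' with `propagate = TRUE` a sequence annotated to a term also counts for
#' every is_a ancestor of that term.
#'
#' @param store A `txwb_project` with a GO graph loaded.
#' @param go_id Exact term id(s); unknown ids give an empty result.
#' @param keyword Case-insensitive substring of the term name.
#' @param level Term level(s) to keep.
#' @param propagate Count annotations up the is_a graph?
#' @return data.frame: `go_id`, `name`, `namespace`, `level`, `n_seqs`.
#' @export
query_go <- function(store, go_id = NULL, keyword = NULL, level = NULL,
                     propagate = FALSE) {
  .stop_if(is.null(store$go), "no GO graph in this project")
  terms <- store$go$terms
  ann <- store$seq_go %||% data.frame(seq_id = character(),
                                      go_id = character())
  if (propagate && nrow(ann) > 0L) {
    anc <- .go_ancestors(store$go)
    ext <- lapply(seq_len(nrow(ann)), function(i)
      data.frame(seq_id = ann$seq_id[i],
                 go_id = c(ann$go_id[i], anc[[ann$go_id[i]]]),
                 stringsAsFactors = FALSE))
    ann <- unique(do.call(rbind, ext))
  }
  cnt <- table(ann$go_id[!duplicated(paste(ann$seq_id, ann$go_id))])
  terms$n_seqs <- as.integer(cnt[terms$go_id])
  terms$n_seqs[is.na(terms$n_seqs)] <- 0L
  keep <- rep(TRUE, nrow(terms))
  if (!is.null(go_id)) keep <- keep & terms$go_id %in% go_id
  if (!is.null(keyword))
    keep <- keep & grepl(tolower(keyword), tolower(terms$name),
                         fixed = TRUE)
  if (!is.null(level)) keep <- keep & terms$level %in% level
  out <- terms[keep, , drop = FALSE]
  out <- out[.ordc(out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# list: term -> all is_a ancestors (possibly empty character())
.go_ancestors <- function(go) {
  parents <- split(go$edges$parent, go$edges$child)
  anc <- new.env(parent = emptyenv())
  get_anc <- function(id) {
    if (!is.null(anc[[id]])) return(anc[[id]])
    ps <- parents[[id]]
    res <- if (is.null(ps)) character(0) else
      unique(c(ps, unlist(lapply(ps, get_anc))))
    anc[[id]] <- res
    res
  }
  setNames(lapply(go$terms$go_id, get_anc), go$terms$go_id)
}

#' Export a query table, sequences, or a correlation matrix
#'
#' @param x The object to export: a data.frame (`kind = "csv"`), a
#'   `txwb_project` plus `seq_ids` (`kind = "fasta"`), or a `txwb_project`
#'   plus `seq_ids` (`kind = "correlation"`).
#' @param path Output file.
#' @param kind `"csv"`, `"fasta"` or `"correlation"`.
#' @param seq_ids Sequence selection for fasta/correlation.
#' @param log2 For correlation: use log2(RPKM + 1).
#' @return `path`, invisibly.
#' @export
export_results <- function(x, path, kind = c("csv", "fasta", "correlation"),
                           seq_ids = NULL, log2 = FALSE) {
  kind <- match.arg(kind)
  if (kind == "csv") {
    write.csv(x, path, row.names = FALSE, quote = TRUE)
  } else if (kind == "fasta") {
    .stop_if(!inherits(x, "txwb_project"), "fasta export needs a project")
    ids <- seq_ids %||% x$seqs$seq_id
    .stop_if(length(ids) == 0L, "no sequences selected")
    write_fasta(x$seqs[match(ids, x$seqs$seq_id), , drop = FALSE], path)
  } else {
    .stop_if(!inherits(x, "txwb_project") || is.null(x$rpkm),
             "correlation export needs a project with RPKM values")
    ids <- seq_ids %||% rownames(x$rpkm)
    .stop_if(length(ids) == 0L, "no sequences selected")
    m <- correlation_matrix(x$rpkm, seq_ids = ids, log2 = log2)
    write.csv(as.data.frame(m), path, row.names = TRUE)
  }
  invisible(path)
}

#' @export
print.txwb_project <- function(x, ...) {
  cat("txwb project '", x$name, "'\n", sep = "")
  fmt <- function(label, n) cat(sprintf("  %-22s %s\n", label, n))
  fmt("sequences:", if (is.null(x$seqs)) 0L else nrow(x$seqs))
  if (!is.null(x$counts)) {
    fmt("libraries:", length(x$counts$libraries))
    fmt("replicates:", ncol(x$counts$counts))
    fmt("total assigned reads:", format(sum(x$counts$lib_totals)))
  }
  if (!is.null(x$pvals)) fmt("p-value columns:", ncol(x$pvals) - 1L)
  fmt("annotation hits:", nrow(x$hits))
  if (!is.null(x$go)) fmt("GO terms:", nrow(x$go$terms))
  if (!is.null(x$snps)) fmt("SNP calls:", nrow(x$snps))
  if (nrow(x$remarks) > 0L) fmt("remarks:", nrow(x$remarks))
  invisible(x)
}

# ---- persistence: a directory of TSV tables --------------------------------

.store_tables <- c("seqs", "stats", "pvals", "hits", "db_entries", "xrefs",
                   "snps", "remarks", "seq_go", "rstat")

#' Save a project store to a directory of TSV tables
#'
#' @param store A `txwb_project`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_project <- function(store, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = TRUE, row.names = FALSE,
    na = "NA")
  for (t in .store_tables) {
    if (!is.null(store[[t]])) wt(store[[t]], paste0(t, ".tsv"))
  }
  if (!is.null(store$counts)) {
    m <- store$counts$counts
    wt(data.frame(seq_id = rownames(m), as.data.frame(m),
                  check.names = FALSE), "counts.tsv")
    libs <- store$counts$libraries
    meta <- do.call(rbind, lapply(libs, function(l) data.frame(
      lib_id = l$lib_id, replicates = paste(l$replicates, collapse = ","),
      as.data.frame(lapply(l$metadata, function(v)
        if (is.na(v)) NA_character_ else as.character(v))),
      stringsAsFactors = FALSE)))
    wt(meta, "libraries.tsv")
  }
  if (!is.null(store$rpkm))
    wt(data.frame(seq_id = rownames(store$rpkm),
                  as.data.frame(store$rpkm), check.names = FALSE),
       "rpkm.tsv")
  if (!is.null(store$go)) {
    wt(store$go$terms, "go_terms.tsv")
    wt(store$go$edges, "go_edges.tsv")
  }
  writeLines(c(paste0("name\t", store$name), "schema\t1"),
             file.path(dir, "meta.tsv"))
  writeLines(store$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Load a project store saved with [save_project()]
#'
#' @param dir Project directory.
#' @return A `txwb_project`.
#' @export
load_project <- function(dir) {
  .stop_if(!file.exists(file.path(dir, "meta.tsv")),
           "not a project directory: ", dir)
  rt <- function(f, ...) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    read.delim(p, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, ...)
  }
  meta <- read.delim(file.path(dir, "meta.tsv"), header = FALSE,
                     stringsAsFactors = FALSE)
  store <- new_project(meta$V2[meta$V1 == "name"])
  for (t in .store_tables) {
    v <- rt(paste0(t, ".tsv"))
    if (!is.null(v)) store[[t]] <- v
  }
  if (!is.null(store$seqs)) store$seqs <- .as_seqs(store$seqs)
  if (is.null(store$hits)) store$hits <- .empty_hits()
  if (is.null(store$remarks))
    store$remarks <- data.frame(seq_id = character(), remark = character(),
                                stringsAsFactors = FALSE)
  cm <- rt("counts.tsv")
  if (!is.null(cm)) {
    mat <- as.matrix(cm[, -1L, drop = FALSE])
    rownames(mat) <- cm$seq_id
    lm <- rt("libraries.tsv")
    libs <- lapply(seq_len(nrow(lm)), function(i) library_def(
      lm$lib_id[i], replicates = strsplit(lm$replicates[i], ",")[[1]],
      title = lm$title[i], species = lm$species[i],
      cultivar = lm$cultivar[i], strain = lm$strain[i],
      tissue = lm$tissue[i], treatment = lm$treatment[i],
      sequencing_lab = lm$sequencing_lab[i], year = lm$year[i]))
    store$counts <- import_counts(mat, libs, seq_ids = store$seqs$seq_id)
  }
  rp <- rt("rpkm.tsv")
  if (!is.null(rp)) {
    m <- as.matrix(rp[, -1L, drop = FALSE])
    rownames(m) <- rp$seq_id
    store$rpkm <- m
  }
  gt <- rt("go_terms.tsv")
  if (!is.null(gt)) store$go <- list(terms = gt,
                                     edges = rt("go_edges.tsv"))
  lg <- file.path(dir, "log.txt")
  if (file.exists(lg)) store$log <- readLines(lg)
  invisible(store)
}
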