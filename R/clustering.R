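# Multi-project comparison: merge projects, self-blast similarity pairs,
# redundancy filtering, transitive-closure clustering, cluster import and
# majority annotation.
#
# Merged sequence ids are "dataset|seq_id" (the orthoMCL groups convention),
# so cluster members always carry their dataset of origin.

.merged_id <- function(dataset_id, seq_id) paste(dataset_id, seq_id,
                                                 sep = "|")

.dataset_of <- function(merged_ids) sub("\\|.*$", "", merged_ids)

#' Merge single projects into a comparison project
#'
#' Copies sequences, annotation hits and expression summaries from each
#' single project, prefixing every sequence id with its dataset id.
#' Nucleotide sequences are translated to proteins via longest-ORF
#' extraction (start codon not required); projects already holding protein
#' sequences are copied as is.
#'
#' @param projects Named list of `txwb_project` stores (names become dataset
#'   ids) — see [build_project()].
#' @param min_orf Minimum ORF length (nt) for coding-sequence extraction.
#' @return A `txwb_merged` list: `seqs` (nucleotide/original records with
#'   merged ids), `proteins` (translated records), `hits`, `rpkm` (long
#'   data.frame: dataset, seq_id, lib_id, rpkm), `datasets`.
#' @export
merge_projects <- function(projects, min_orf = 90L) {
  ds <- names(projects)
  .stop_if(is.null(ds) || any(!nzchar(ds)), "projects must be named")
  .stop_if(anyDuplicated(ds) > 0L, "colliding dataset ids: ",
           paste(unique(ds[duplicated(ds)]), collapse = ", "))
  seqs <- list(); prots <- list(); hits <- list(); rpkm <- list()
  for (d in ds) {
    p <- projects[[d]]
    s <- p$seqs
    s$dataset_id <- d
    s$seq_id <- .merged_id(d, s$seq_id)
    seqs[[d]] <- s
    pr <- lapply(seq_len(nrow(s)), function(i) {
      rec <- s[i, , drop = FALSE]
      if (rec$moltype == "protein") return(rec)
      cds <- extract_cds(rec, min_len = min_orf)
      if (is.null(cds)) return(NULL)
      cds$seq_id <- rec$seq_id   # keep the merged id for cross-referencing
      cds
    })
    prots[[d]] <- do.call(rbind, pr[!vapply(pr, is.null, logical(1))])
    if (!is.null(p$hits) && nrow(p$hits) > 0L) {
      h <- p$hits
      h$seq_id <- .merged_id(d, h$seq_id)
      hits[[d]] <- h
    }
    if (!is.null(p$rpkm)) {
      r <- p$rpkm
      rpkm[[d]] <- data.frame(dataset_id = d,
                              seq_id = .merged_id(d, rep(rownames(r),
                                                         ncol(r))),
                              lib_id = rep(colnames(r), each = nrow(r)),
                              rpkm = as.vector(r), stringsAsFactors = FALSE)
    }
  }
  structure(list(seqs = .as_seqs(do.call(rbind, seqs)),
                 proteins = if (length(prots)) .as_seqs(do.call(rbind,
                                                                prots)),
                 hits = if (length(hits)) do.call(rbind, hits) else
                   .empty_hits(),
                 rpkm = if (length(rpkm)) do.call(rbind, rpkm),
                 datasets = ds),
            class = "txwb_merged")
}

#' Load similarity pairs from a self-BLAST tabular file
#'
#' Drops self-hits, keeps the best HSP (maximum bit score) per unordered
#' pair, computes percent overlap as alignment length over the shorter
#' sequence's length, and drops pairs failing either threshold.
#'
#' @param x Self-BLAST tabular path or a data.frame from
#'   [parse_blast_tab()].
#' @param seq_lengths Named lengths (nt or aa, matching the blasted FASTA)
#'   for every sequence appearing in a pair.
#' @param min_identity,min_overlap Percent thresholds in \[0, 100\].
#' @return data.frame of `txwb_pairs`: `seq_a`, `seq_b` (canonical order:
#'   `seq_a < seq_b`), `percent_identity`, `percent_overlap`, `e_value`,
#'   `bit_score`.
#' @export
load_pairs <- function(x, seq_lengths, min_identity = 0, min_overlap = 0) {
  hits <- if (is.character(x)) parse_blast_tab(x, source_db = "self") else x
  hits <- hits[hits$seq_id != hits$hit_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(.empty_pairs())
  a <- pmin(hits$seq_id, hits$hit_id)
  b <- pmax(hits$seq_id, hits$hit_id)
  .stop_if(!all(c(a, b) %in% names(seq_lengths)),
           "missing sequence length for a paired sequence")
  key <- paste(a, b, sep = "\r")
  ord <- .ordc(key, -hits$bit_score)
  first <- !duplicated(key[ord])
  sel <- ord[first]
  shorter <- pmin(seq_lengths[a[sel]], seq_lengths[b[sel]])
  pairs <- data.frame(seq_a = a[sel], seq_b = b[sel],
                      percent_identity = hits$percent_identity[sel],
                      percent_overlap = pmin(100 * hits$align_len[sel] /
                                               shorter, 100),
                      e_value = hits$e_value[sel],
                      bit_score = hits$bit_score[sel],
                      stringsAsFactors = FALSE)
  pairs <- pairs[pairs$percent_identity >= min_identity &
                   pairs$percent_overlap >= min_overlap, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

.empty_pairs <- function() {
  data.frame(seq_a = character(), seq_b = character(),
             percent_identity = numeric(), percent_overlap = numeric(),
             e_value = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Remove redundant near-identical sequences within a dataset
#'
#' Before cross-dataset comparison, very similar sequences from the same
#' dataset are collapsed: pairs exceeding both thresholds are visited in
#' decreasing identity (ties: higher bit score, then pair ids) and, when
#' both members are still kept, the shorter member is removed (tie: the
#' lexicographically later id). Pairs spanning two datasets never trigger a
#' removal.
#'
#' @param pairs data.frame from [load_pairs()] over merged ids.
#' @param seq_lengths Named lengths for the merged sequences.
#' @param min_identity,min_overlap Percent thresholds in (0, 100\].
#' @return List with `kept` (character vector of surviving ids among those
#'   named in `seq_lengths`) and `removed` (data.frame: `seq_id`, `kept_twin`,
#'   `percent_identity`).
#' @export
remove_redundant <- function(pairs, seq_lengths, min_identity = 98,
                             min_overlap = 98) {
  .stop_if(min_identity <= 0 || min_identity > 100 ||
             min_overlap <= 0 || min_overlap > 100,
           "thresholds must be in (0, 100]")
  cand <- pairs[pairs$percent_identity >= min_identity &
                  pairs$percent_overlap >= min_overlap &
                  .dataset_of(pairs$seq_a) == .dataset_of(pairs$seq_b), ,
                drop = FALSE]
  cand <- cand[.ordc(-cand$percent_identity, -cand$bit_score, cand$seq_a,
                     cand$seq_b), , drop = FALSE]
  removed <- list()
  alive <- setNames(rep(TRUE, length(seq_lengths)), names(seq_lengths))
  for (i in seq_len(nrow(cand))) {
    a <- cand$seq_a[i]; b <- cand$seq_b[i]
    if (!alive[a] || !alive[b]) next
    la <- seq_lengths[a]; lb <- seq_lengths[b]
    drop <- if (la < lb) a else if (lb < la) b else max(a, b)
    keep <- if (drop == a) b else a
    alive[drop] <- FALSE
    removed[[length(removed) + 1L]] <- data.frame(
      seq_id = drop, kept_twin = keep,
      percent_identity = cand$percent_identity[i], stringsAsFactors = FALSE)
  }
  list(kept = names(alive)[alive],
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(seq_id = character(), kept_twin = character(),
                    percent_identity = numeric(), stringsAsFactors = FALSE))
}

#' Transitive-closure clustering of similarity pairs
#'
#' Clusters are the connected components of the graph whose nodes are all
#' sequences and whose edges are the pairs passing both thresholds (and the
#' optional e-value cutoff). Singletons are materialised as one-member
#' clusters so every sequence belongs to exactly one cluster. Clusters are
#' numbered by decreasing member count, ties by lexicographically smallest
#' member; ids look like `TC80_0000001`.
#'
#' @param pairs data.frame from [load_pairs()].
#' @param seq_ids All sequence ids to cluster (nodes, including those
#'   without any pair).
#' @param min_identity,min_overlap Percent edge thresholds (default 80/80).
#' @param max_evalue Optional additional e-value edge filter (default off).
#' @param prefix Cluster-id prefix; default `TC<min_identity>`.
#' @return A `txwb_clusters` list: `clusters` (data.frame: `cluster_id`,
#'   `method`, `size`, `is_singleton`, plus annotation columns once
#'   assigned) and `members` (data.frame: `cluster_id`, `seq_id`).
#' @export
transitive_closure <- function(pairs, seq_ids, min_identity = 80,
                               min_overlap = 80, max_evalue = NULL,
                               prefix = NULL) {
  if (is.null(prefix)) prefix <- sprintf("TC%d", as.integer(min_identity))
  keep <- pairs$percent_identity >= min_identity &
    pairs$percent_overlap >= min_overlap
  if (!is.null(max_evalue)) keep <- keep & pairs$e_value <= max_evalue
  edges <- pairs[keep, , drop = FALSE]
  idx <- seq_along(seq_ids)
  names(idx) <- seq_ids
  parent <- idx
  find <- function(i) {           # union-find with path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find(idx[[edges$seq_a[i]]])
    rb <- find(idx[[edges$seq_b[i]]])
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(unname(idx), find, integer(1))
  comp <- split(seq_ids, root)
  smallest <- vapply(comp, function(v) .sortc(v)[1L], character(1))
  sizes <- lengths(comp)
  ord <- .ordc(-sizes, smallest)
  comp <- comp[ord]
  ids <- sprintf("%s_%07d", prefix, seq_along(comp))
  .new_clusters(ids, comp, method = "transitive")
}

.new_clusters <- function(ids, comp, method) {
  clusters <- data.frame(cluster_id = ids, method = method,
                         size = lengths(comp),
                         is_singleton = lengths(comp) == 1L,
                         assigned_hit = NA_character_,
                         assigned_hit_pct = NA_real_,
                         assigned_hit_best_e = NA_real_,
                         stringsAsFactors = FALSE)
  members <- data.frame(cluster_id = rep(ids, lengths(comp)),
                        seq_id = unname(unlist(comp)),
                        stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(list(clusters = clusters, members = members, method = method),
            class = "txwb_clusters")
}

#' Import a cluster set computed elsewhere
#'
#' Two dialects, auto-detected per file: tab-separated
#' `cluster_id<TAB>seq_id` lines, or orthoMCL groups lines
#' (`cluster_id: member member ...`). A sequence may not appear in two
#' clusters of one file; members not in `seq_ids` (when given) are skipped
#' with a warning.
#'
#' @param path Cluster file.
#' @param method_name Short name; the stored method is
#'   `imported:<method_name>`.
#' @param seq_ids Optional universe of known sequence ids.
#' @return A `txwb_clusters` list (cluster ids are taken from the file).
#' @export
import_clusters <- function(path, method_name, seq_ids = NULL) {
  .stop_if(!file.exists(path), "cluster file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  .stop_if(length(lines) == 0L, "cluster file is empty: ", path)
  groups_style <- grepl("^\\S+:\\s", lines[1L])
  if (groups_style) {
    cid <- sub(":.*$", "", lines)
    mem <- strsplit(trimws(sub("^\\S+:\\s*", "", lines)), "\\s+")
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    .stop_if(any(lengths(parts) != 2L),
             "expected 'cluster_id<TAB>seq_id' lines in ", path)
    cid0 <- vapply(parts, `[`, character(1), 1L)
    mem0 <- vapply(parts, `[`, character(1), 2L)
    cid <- unique(cid0)
    mem <- lapply(cid, function(cc) mem0[cid0 == cc])
  }
  all_members <- unlist(mem)
  dup <- unique(all_members[duplicated(all_members)])
  .stop_if(length(dup) > 0L, "sequence in two clusters of ", path, ": ",
           paste(head(dup, 5L), collapse = ", "))
  if (!is.null(seq_ids)) {
    unknown <- setdiff(all_members, seq_ids)
    if (length(unknown) > 0L) {
      warning(length(unknown), " unknown member id(s) skipped: ",
              paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
      mem <- lapply(mem, setdiff, unknown)
    }
  }
  keep <- lengths(mem) > 0L
  .new_clusters(cid[keep], mem[keep],
                method = paste0("imported:", method_name))
}

#' Export a cluster set
#'
#' @param clusters A `txwb_clusters` object.
#' @param path Output path.
#' @param format `"tsv"` (`cluster_id<TAB>seq_id`) or `"groups"`
#'   (orthoMCL-style `cluster_id: member ...`).
#' @return `path`, invisibly.
#' @export
export_clusters <- function(clusters, path, format = c("tsv", "groups")) {
  format <- match.arg(format)
  m <- clusters$members
  if (format == "tsv") {
    writeLines(paste(m$cluster_id, m$seq_id, sep = "\t"), path)
  } else {
    sp <- split(m$seq_id, m$cluster_id)
    sp <- sp[unique(m$cluster_id)]
    writeLines(paste0(names(sp), ": ",
                      vapply(sp, paste, character(1), collapse = " ")), path)
  }
  invisible(path)
}

#' Assign the majority annotation to each cluster
#'
#' For every cluster, the hit id that hits the largest number of distinct
#' members is assigned (ties: the tied hit with the best e-value within the
#' cluster, then lexicographic hit id), along with the percentage of
#' members having that hit and its best e-value in the cluster. Clusters
#' whose members have no hits stay unannotated.
#'
#' @param clusters A `txwb_clusters` object over merged sequence ids.
#' @param hits data.frame of hits with `seq_id` in merged-id form.
#' @return `clusters` with `assigned_hit`, `assigned_hit_pct`,
#'   `assigned_hit_best_e` filled in.
#' @export
assign_cluster_annotation <- function(clusters, hits) {
  h <- unique(hits[, c("seq_id", "hit_id", "e_value")])
  cl <- clusters$clusters
  mem <- split(clusters$members$seq_id, clusters$members$cluster_id)
  for (i in seq_len(nrow(cl))) {
    members <- mem[[cl$cluster_id[i]]]
    hh <- h[h$seq_id %in% members, , drop = FALSE]
    if (nrow(hh) == 0L) next
    per_hit <- split(hh, hh$hit_id)
    n_mem <- vapply(per_hit, function(x) length(unique(x$seq_id)),
                    integer(1))
    best_e <- vapply(per_hit, function(x) min(x$e_value), numeric(1))
    ord <- .ordc(-n_mem, best_e, names(per_hit))
    top <- ord[1L]
    cl$assigned_hit[i] <- names(per_hit)[top]
    cl$assigned_hit_pct[i] <- 100 * n_mem[top] / length(members)
    cl$assigned_hit_best_e[i] <- best_e[top]
  }
  clusters$clusters <- cl
  clusters
}

#' Filter clusters by species composition and expression
#'
#' Selects clusters by per-dataset membership constraints and an optional
#' RPKM predicate, returning the viewer-style table (id, size, per-dataset
#' member counts, assigned hit columns).
#'
#' @param clusters A `txwb_clusters` object over merged ids.
#' @param composition Named list/vector mapping dataset id to `"required"`
#'   (>= 1 member), `"excluded"` (0 members) or `"any"`.
#' @param datasets Character vector of all dataset ids (columns of the
#'   table); defaults to those observed in the members.
#' @param rpkm_predicate Optional `function(member_ids) -> logical(1)`
#'   evaluated per cluster.
#' @return data.frame: `cluster_id`, `size`, `n_<dataset>` count columns,
#'   `assigned_hit`, `assigned_hit_desc` absent here, `assigned_hit_pct`,
#'   `assigned_hit_best_e`.
#' @export
filter_clusters <- function(clusters, composition = list(),
                            datasets = NULL, rpkm_predicate = NULL) {
  mem <- split(clusters$members$seq_id, clusters$members$cluster_id)
  mem <- mem[clusters$clusters$cluster_id]
  if (is.null(datasets))
    datasets <- .sortc(unique(.dataset_of(clusters$members$seq_id)))
  unknown <- setdiff(names(composition), datasets)
  .stop_if(length(unknown) > 0L, "unknown dataset id: ",
           paste(unknown, collapse = ", "))
  counts <- t(vapply(mem, function(v)
    vapply(datasets, function(d) sum(.dataset_of(v) == d), integer(1)),
    integer(length(datasets))))
  if (length(datasets) == 1L)
    counts <- matrix(counts, ncol = 1L, dimnames = list(NULL, datasets))
  keep <- rep(TRUE, length(mem))
  for (d in names(composition)) {
    rule <- composition[[d]]
    if (identical(rule, "required")) keep <- keep & counts[, d] >= 1L
    else if (identical(rule, "excluded")) keep <- keep & counts[, d] == 0L
    else .stop_if(!identical(rule, "any"),
                  "composition rule must be required/excluded/any")
  }
  if (!is.null(rpkm_predicate))
    keep <- keep & vapply(mem, rpkm_predicate, logical(1))
  out <- cbind(clusters$clusters[, c("cluster_id", "size")],
               as.data.frame(counts))
  colnames(out)[-(1:2)] <- paste0("n_", datasets)
  out <- cbind(out, clusters$clusters[, c("assigned_hit",
                                          "assigned_hit_pct",
                                          "assigned_hit_best_e")])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
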