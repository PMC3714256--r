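# Annotation: BLAST tabular hits, UniProt-style flat-file records, GO levels
# from an OBO ontology, hit ranking and the best-annotation rule.

#' Default uninformative description phrases
#'
#' Hit descriptions containing any of these (case-insensitively) are skipped
#' by the best-annotation rule.
#' @export
txwb_uninformative_phrases <- c("uncharacterized protein",
                                "predicted protein",
                                "hypothetical protein",
                                "unknown",
                                "putative uncharacterized")

#' Parse 12-column BLAST tabular output
#'
#' Reads the standard tabular format (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore; comment lines starting
#' with `#` are ignored). Coordinates are converted to 0-based half-open and
#' reverse-strand HSPs are normalised to forward coordinates with the strand
#' recorded. Subject ids following the UniProt convention `sp|ACC|NAME` or
#' `tr|ACC|NAME` yield `db_type` "sp"/"tr" and `hit_id = NAME`; any other id
#' is kept verbatim with `db_type` set to the user's database tag.
#'
#' @param path BLAST tabular file.
#' @param source_db Label for the searched database (default: file name).
#' @param taxonomy_tag Short user tag ("plant", "invertebrate", ...) carried
#'   on every hit and used as `db_type` for non-UniProt ids.
#' @return data.frame of hits: `seq_id`, `hit_id`, `accession`, `db_type`,
#'   `taxonomy_tag`, `description` (NA until joined to database records),
#'   `percent_identity`, `align_len`, `mismatches`, `gap_opens`,
#'   `seq_start`, `seq_end`, `hit_start`, `hit_end`, `strand`, `e_value`,
#'   `bit_score`, `source_db`.
#' @export
parse_blast_tab <- function(path, source_db = basename(path),
                            taxonomy_tag = NA_character_) {
  .stop_if(!file.exists(path), "BLAST tabular file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  bad <- which(nc != 12L)
  .stop_if(length(bad) > 0L, "expected 12 tab-separated columns in ", path,
           " line ", bad[1L], " (got ", nc[bad[1L]], ")")
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  qs <- as.numeric(m[, 7L]); qe <- as.numeric(m[, 8L])
  ss <- as.numeric(m[, 9L]); se <- as.numeric(m[, 10L])
  strand <- ifelse(sign(qe - qs + 0.5) * sign(se - ss + 0.5) < 0, "-", "+")
  up <- regmatches(m[, 2L],
                   regexec("^(sp|tr)\\|([^|]+)\\|(\\S+)$", m[, 2L]))
  is_up <- lengths(up) == 4L
  hit_id <- m[, 2L]
  acc <- rep(NA_character_, nrow(m))
  db_type <- rep(if (is.na(taxonomy_tag)) "other" else taxonomy_tag, nrow(m))
  if (any(is_up)) {
    hit_id[is_up] <- vapply(up[is_up], `[`, character(1), 4L)
    acc[is_up] <- vapply(up[is_up], `[`, character(1), 3L)
    db_type[is_up] <- vapply(up[is_up], `[`, character(1), 2L)
  }
  data.frame(seq_id = m[, 1L], hit_id = hit_id, accession = acc,
             db_type = db_type, taxonomy_tag = taxonomy_tag,
             description = NA_character_,
             percent_identity = as.numeric(m[, 3L]),
             align_len = as.integer(m[, 4L]),
             mismatches = as.integer(m[, 5L]),
             gap_opens = as.integer(m[, 6L]),
             seq_start = pmin(qs, qe) - 1, seq_end = pmax(qs, qe),
             hit_start = pmin(ss, se) - 1, hit_end = pmax(ss, se),
             strand = strand, e_value = as.numeric(m[, 11L]),
             bit_score = as.numeric(m[, 12L]), source_db = source_db,
             stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  data.frame(seq_id = character(), hit_id = character(),
             accession = character(), db_type = character(),
             taxonomy_tag = character(), description = character(),
             percent_identity = numeric(), align_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             seq_start = numeric(), seq_end = numeric(),
             hit_start = numeric(), hit_end = numeric(),
             strand = character(), e_value = numeric(),
             bit_score = numeric(), source_db = character(),
             stringsAsFactors = FALSE)
}

#' Parse UniProt-style flat-text records
#'
#' Reads the `.dat` dialect: records delimited by a `//` line, with `ID`,
#' `AC`, `DE`, `OS` and `DR` lines. The description is taken from the first
#' `DE   RecName: Full=...` (falling back to the first DE line); `DR` cross
#' references of type GO, KEGG and Pfam are captured, and EC numbers are
#' captured from `EC=` fields on DE lines. Records lacking an ID line are
#' skipped with a warning.
#'
#' @param path Flat file path.
#' @return List with `entries` (data.frame: `hit_id`, `accession`,
#'   `description`, `organism`, `reviewed`) and `xrefs` (data.frame:
#'   `hit_id`, `kind` in GO/KEGG/EC/Pfam, `accession`).
#' @export
parse_uniprot_dat <- function(path) {
  .stop_if(!file.exists(path), "flat file not found: ", path)
  lines <- readLines(path)
  rec_end <- which(trimws(lines) == "//")
  rec_begin <- c(1L, head(rec_end, -1L) + 1L)
  if (length(rec_end) == 0L) { rec_begin <- 1L; rec_end <- length(lines) + 1L }
  entries <- list(); xrefs <- list(); skipped <- 0L
  for (r in seq_along(rec_begin)) {
    rl <- lines[rec_begin[r]:(rec_end[r] - 1L)]
    rl <- rl[nzchar(trimws(rl))]
    if (length(rl) == 0L) next
    idl <- grep("^ID\\s", rl, value = TRUE)
    if (length(idl) == 0L) { skipped <- skipped + 1L; next }
    toks <- strsplit(trimws(sub("^ID\\s+", "", idl[1L])), "\\s+")[[1L]]
    hit_id <- toks[1L]
    reviewed <- any(grepl("\\bReviewed;", idl[1L]))
    acl <- grep("^AC\\s", rl, value = TRUE)
    acc <- if (length(acl)) sub(";.*$", "", sub("^AC\\s+", "", acl[1L]))
           else NA_character_
    del <- grep("^DE\\s", rl, value = TRUE)
    desc <- NA_character_
    if (length(del)) {
      full <- regmatches(del, regexpr("RecName: Full=[^;]+", del))
      desc <- if (length(full)) sub("^RecName: Full=", "", full[1L])
              else trimws(sub("^DE\\s+", "", del[1L]))
    }
    osl <- grep("^OS\\s", rl, value = TRUE)
    org <- if (length(osl)) sub("\\.$", "", trimws(sub("^OS\\s+", "",
                                                       osl[1L])))
           else NA_character_
    entries[[length(entries) + 1L]] <- data.frame(
      hit_id = hit_id, accession = acc, description = desc, organism = org,
      reviewed = reviewed, stringsAsFactors = FALSE)
    drl <- grep("^DR\\s", rl, value = TRUE)
    for (d in drl) {
      f <- strsplit(trimws(sub("^DR\\s+", "", d)), ";\\s*")[[1L]]
      if (length(f) >= 2L && f[1L] %in% c("GO", "KEGG", "Pfam")) {
        xrefs[[length(xrefs) + 1L]] <- data.frame(
          hit_id = hit_id, kind = f[1L], accession = f[2L],
          stringsAsFactors = FALSE)
      }
    }
    ec <- unlist(regmatches(del, gregexpr("EC=[0-9][0-9.n-]*", del)))
    for (e in unique(ec)) {
      xrefs[[length(xrefs) + 1L]] <- data.frame(
        hit_id = hit_id, kind = "EC", accession = sub("^EC=", "", e),
        stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L)
    warning(skipped, " record(s) without an ID line skipped", call. = FALSE)
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(hit_id = character(), accession = character(),
               description = character(), organism = character(),
               reviewed = logical(), stringsAsFactors = FALSE)
  xrefs <- if (length(xrefs)) do.call(rbind, xrefs) else
    data.frame(hit_id = character(), kind = character(),
               accession = character(), stringsAsFactors = FALSE)
  list(entries = entries, xrefs = xrefs)
}

#' Join flat-file descriptions onto parsed hits
#'
#' Matches database records to hits by entry name, falling back to
#' accession.
#'
#' @param hits data.frame from [parse_blast_tab()].
#' @param dat List from [parse_uniprot_dat()].
#' @return `hits` with `description` filled where a record matched.
#' @export
attach_descriptions <- function(hits, dat) {
  i <- match(hits$hit_id, dat$entries$hit_id)
  miss <- is.na(i) & !is.na(hits$accession)
  i[miss] <- match(hits$accession[miss], dat$entries$accession)
  hits$description <- ifelse(is.na(i), hits$description,
                             dat$entries$description[i])
  hits
}

#' Parse an OBO ontology and compute term levels
#'
#' Reads `[Term]` stanzas (`id`, `name`, `namespace`, `is_a`,
#' `is_obsolete`), drops obsolete terms, and assigns each term a level: 1
#' for namespace roots (terms with no `is_a` parent) and
#' `1 + min(parent levels)` otherwise, i.e. the shortest is_a path to a root
#' plus one. Only `is_a` edges contribute; `part_of` and other relationship
#' lines are ignored. A cycle in the is_a graph is an error.
#'
#' @param path OBO 1.2 file.
#' @return List with `terms` (data.frame: `go_id`, `name`, `namespace`,
#'   `level`) and `edges` (data.frame: `child`, `parent`).
#' @export
go_levels <- function(path) {
  .stop_if(!file.exists(path), "OBO file not found: ", path)
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  .stop_if(length(starts) == 0L, "no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); names_ <- character(0); ns <- character(0)
  edges <- list()
  for (t in seq_along(starts)) {
    tl <- lines[(bounds[t] + 1L):(bounds[t + 1L] - 1L)]
    stanza_end <- grep("^\\[", tl)
    if (length(stanza_end)) tl <- tl[seq_len(stanza_end[1L] - 1L)]
    if (any(grepl("^is_obsolete: true", tl))) next
    id <- sub("^id: ", "", grep("^id: ", tl, value = TRUE)[1L])
    nm <- sub("^name: ", "", grep("^name: ", tl, value = TRUE)[1L])
    nsp <- grep("^namespace: ", tl, value = TRUE)
    nsp <- if (length(nsp)) sub("^namespace: ", "", nsp[1L]) else
      NA_character_
    ids <- c(ids, id); names_ <- c(names_, nm); ns <- c(ns, nsp)
    isa <- grep("^is_a: ", tl, value = TRUE)
    for (e in isa) {
      parent <- trimws(sub("!.*$", "", sub("^is_a: ", "", e)))
      edges[[length(edges) + 1L]] <- c(id, parent)
    }
  }
  edges <- if (length(edges))
    data.frame(child = vapply(edges, `[`, character(1), 1L),
               parent = vapply(edges, `[`, character(1), 2L),
               stringsAsFactors = FALSE)
  else data.frame(child = character(), parent = character(),
                  stringsAsFactors = FALSE)
  edges <- edges[edges$parent %in% ids, , drop = FALSE]
  # Kahn topological ordering over is_a, relaxing levels root-down
  level <- setNames(rep(NA_integer_, length(ids)), ids)
  n_par <- table(factor(edges$child, levels = ids))
  queue <- ids[n_par == 0L]
  level[queue] <- 1L
  remaining <- n_par
  ch_by_parent <- split(edges$child, edges$parent)
  processed <- 0L
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]; processed <- processed + 1L
    for (ch in ch_by_parent[[v]]) {
      if (is.na(level[ch]) || level[v] + 1L < level[ch])
        level[ch] <- min(level[ch], level[v] + 1L, na.rm = TRUE)
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  .stop_if(processed < length(ids), "cycle detected in is_a graph of ", path)
  list(terms = data.frame(go_id = ids, name = names_, namespace = ns,
                          level = unname(level[ids]),
                          stringsAsFactors = FALSE),
       edges = edges)
}

# total order used to rank hits: e-value up, bit score down, sp before tr
# before other tags, then hit_id
.hit_order <- function(hits) {
  db_rank <- match(hits$db_type, c("sp", "tr"))
  db_rank[is.na(db_rank)] <- 3L
  .ordc(hits$e_value, -hits$bit_score, db_rank, hits$hit_id)
}

#' Best hit and best informative annotation for one sequence
#'
#' The best hit is the minimum e-value hit, with ties broken by higher bit
#' score, then Swiss-Prot (`sp`) before TrEMBL (`tr`) before other
#' databases, then hit id; this makes the ranking a total order, stable
#' under permutation of the input. The best annotation applies the same
#' rule restricted to hits whose description contains none of the
#' uninformative phrases (case-insensitive); it is `NULL` when every
#' description is uninformative or missing.
#'
#' @param hits data.frame of hits for a single sequence.
#' @param uninformative Character vector of phrases
#'   (default [txwb_uninformative_phrases]).
#' @return List with one-row data.frames `best` and `best_anno` (the latter
#'   `NULL` if no informative hit exists).
#' @export
best_annotation <- function(hits, uninformative = txwb_uninformative_phrases) {
  .stop_if(nrow(hits) == 0L, "best_annotation needs at least one hit")
  ord <- .hit_order(hits)
  best <- hits[ord[1L], , drop = FALSE]
  desc <- tolower(ifelse(is.na(hits$description), "", hits$description))
  uninf <- Reduce(`|`, lapply(tolower(uninformative), function(p)
    grepl(p, desc, fixed = TRUE)), rep(FALSE, nrow(hits)))
  informative <- !uninf & nzchar(desc)
  ord_inf <- ord[informative[ord]]
  best_anno <- if (length(ord_inf)) hits[ord_inf[1L], , drop = FALSE] else
    NULL
  list(best = best, best_anno = best_anno)
}

#' Group hits by database identifier
#'
#' One row per hit id with the number of distinct sequences containing the
#' hit and the best e-value, optionally filtered by description keyword, hit
#' id pattern, or taxonomy tag. Rows are ordered by sequence count
#' descending then hit id.
#'
#' @param hits data.frame of hits (any number of sequences).
#' @param description_filter,id_filter Case-insensitive fixed substrings.
#' @param taxonomy Exact taxonomy tag to keep.
#' @return data.frame: `hit_id`, `description`, `n_seqs`, `best_e`.
#' @export
hit_group_table <- function(hits, description_filter = NULL,
                            id_filter = NULL, taxonomy = NULL) {
  if (!is.null(taxonomy)) hits <- hits[hits$taxonomy_tag %in% taxonomy, ]
  if (!is.null(id_filter))
    hits <- hits[grepl(tolower(id_filter), tolower(hits$hit_id),
                       fixed = TRUE), ]
  if (!is.null(description_filter)) {
    d <- tolower(ifelse(is.na(hits$description), "", hits$description))
    hits <- hits[grepl(tolower(description_filter), d, fixed = TRUE), ]
  }
  if (nrow(hits) == 0L)
    return(data.frame(hit_id = character(), description = character(),
                      n_seqs = integer(), best_e = numeric(),
                      stringsAsFactors = FALSE))
  sp <- split(hits, hits$hit_id)
  out <- data.frame(
    hit_id = names(sp),
    description = vapply(sp, function(h) h$description[1L], character(1)),
    n_seqs = vapply(sp, function(h) length(unique(h$seq_id)), integer(1)),
    best_e = vapply(sp, function(h) min(h$e_value), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[.ordc(-out$n_seqs, out$hit_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GO annotations per sequence
#'
#' Assigns to each sequence the union of the GO cross-references of all its
#' hits; each (sequence, GO term) pair carries the best e-value among the
#' hits contributing it.
#'
#' @param hits data.frame of hits.
#' @param xrefs data.frame of cross references from [parse_uniprot_dat()].
#' @return data.frame: `seq_id`, `go_id`, `best_e`.
#' @export
seq_go_annotations <- function(hits, xrefs) {
  go <- xrefs[xrefs$kind == "GO", , drop = FALSE]
  j <- merge(hits[, c("seq_id", "hit_id", "e_value")], go, by = "hit_id")
  if (nrow(j) == 0L)
    return(data.frame(seq_id = character(), go_id = character(),
                      best_e = numeric(), stringsAsFactors = FALSE))
  agg <- aggregate(e_value ~ seq_id + accession, data = j, FUN = min)
  out <- data.frame(seq_id = agg$seq_id, go_id = agg$accession,
                    best_e = agg$e_value, stringsAsFactors = FALSE)
  out <- out[.ordc(out$seq_id, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
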