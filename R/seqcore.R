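# Sequence records, FASTA I/O, GC content, ORF finding and translation.
#
# Records are plain data.frames (class "txwb_seqs") with columns seq_id,
# residues, moltype ("nucleotide" or "protein") and dataset_id. Coordinates
# throughout are 0-based half-open on the forward strand.

.iupac_nt <- c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "-")

.as_seqs <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("txwb_seqs", "data.frame")
  df
}

.guess_moltype <- function(residues) {
  letters <- strsplit(residues, "", fixed = TRUE)
  vapply(letters, function(ch) {
    if (all(ch %in% .iupac_nt)) "nucleotide" else "protein"
  }, character(1))
}

#' Read sequence records from a FASTA file
#'
#' Reads a standard FASTA file into a `txwb_seqs` data.frame. The record
#' identifier is the first whitespace-delimited token of the header line and
#' residues are uppercased. The molecule type is guessed per record from the
#' residue alphabet unless given.
#'
#' @param path Path to a FASTA file.
#' @param moltype `"auto"` (default) to infer per record from the alphabet,
#'   else `"nucleotide"` or `"protein"` applied to every record.
#' @param dataset_id Optional label naming the project/dataset of origin,
#'   carried on every record.
#' @return A data.frame (class `txwb_seqs`) with columns `seq_id`, `residues`,
#'   `moltype`, `dataset_id`, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgtACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, moltype = c("auto", "nucleotide", "protein"),
                       dataset_id = NA_character_) {
  moltype <- match.arg(moltype)
  .stop_if(!file.exists(path), "FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  .stop_if(length(set) == 0L, "FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  .stop_if(length(dup) > 0L, "duplicate seq_id in ", path, ": ",
           paste(unique(dup), collapse = ", "))
  residues <- toupper(as.character(set))
  .stop_if(any(!nzchar(residues)), "empty sequence for id: ",
           paste(ids[!nzchar(residues)], collapse = ", "))
  mt <- if (moltype == "auto") .guess_moltype(residues) else
    rep(moltype, length(ids))
  .as_seqs(data.frame(seq_id = ids, residues = unname(residues),
                      moltype = mt, dataset_id = dataset_id,
                      stringsAsFactors = FALSE))
}

#' Write sequence records to a FASTA file
#'
#' @param seqs A `txwb_seqs` data.frame or a named character vector.
#' @param path Output path. Lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    .stop_if(is.null(names(seqs)), "a character vector needs names")
    set <- Biostrings::BStringSet(seqs)
  } else {
    set <- Biostrings::BStringSet(setNames(seqs$residues, seqs$seq_id))
  }
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguity codes (including N) are
#' excluded from both numerator and denominator; a sequence with no
#' unambiguous base (e.g. all N) yields `NaN`.
#'
#' @param x A `txwb_seqs` data.frame (all rows must be nucleotide) or a
#'   character vector of nucleotide sequences.
#' @return Numeric vector of fractions in \[0, 1\] (or `NaN`).
#' @examples
#' gc_content(c("GGCC", "ATAT", "ACGTN"))
#' @export
gc_content <- function(x) {
  if (is.data.frame(x)) {
    .stop_if(any(x$moltype == "protein"),
             "gc_content is undefined for protein records: ",
             paste(head(x$seq_id[x$moltype == "protein"], 3), collapse = ", "))
    res <- x$residues
    nm <- x$seq_id
  } else {
    res <- toupper(x)
    nm <- names(x)
  }
  gc <- nchar(gsub("[^GC]", "", res))
  acgt <- nchar(gsub("[^ACGT]", "", res))
  setNames(gc / acgt, nm)
}

#' Reverse complement
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse complements (IUPAC-aware).
#' @export
rev_comp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(chartr("ACGTUNRYSWKMBDHVacgtunryswkmbdhv",
                              "TGCAANYRSWMKVHDBtgcaanyrswmkvhdb", s),
                       "", fixed = TRUE)[[1]])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.stop_codons <- c("TAA", "TAG", "TGA")

# scan one reading frame (offset 0..2) of a forward-oriented sequence;
# returns spans in that orientation's coordinates
.scan_frame <- function(s, offset, min_len, require_start) {
  L <- nchar(s)
  n_codon <- (L - offset) %/% 3L
  if (n_codon < 1L) return(NULL)
  starts <- offset + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts + 1L, starts + 3L)
  is_stop <- codons %in% .stop_codons
  is_atg <- codons == "ATG"
  out <- list()
  region_begin <- 1L   # codon index where the current inter-stop region opens
  k <- 0L
  for (ci in seq_len(n_codon)) {
    if (is_stop[ci]) {
      span <- .region_span(region_begin, ci, is_atg, starts,
                           has_stop = TRUE, require_start = require_start)
      if (!is.null(span) && span$length >= min_len) {
        k <- k + 1L
        out[[k]] <- span
      }
      region_begin <- ci + 1L
    }
  }
  if (region_begin <= n_codon) {   # open region runs off the sequence end
    span <- .region_span(region_begin, n_codon + 1L, is_atg, starts,
                         has_stop = FALSE, require_start = require_start)
    if (!is.null(span) && span$length >= min_len) {
      k <- k + 1L
      out[[k]] <- span
    }
  }
  if (k == 0L) NULL else out
}

# span for one inter-stop region: codons region_begin .. stop_ci (stop
# included when present). With require_start the span is anchored at the
# first ATG of the region; otherwise it covers the whole region and
# has_start records whether it happens to begin with ATG.
.region_span <- function(region_begin, stop_ci, is_atg, starts, has_stop,
                         require_start) {
  last_ci <- if (has_stop) stop_ci else stop_ci - 1L
  if (last_ci < region_begin) return(NULL)
  if (require_start) {
    atg <- which(is_atg[region_begin:last_ci])
    if (length(atg) == 0L) return(NULL)
    first <- region_begin + atg[1L] - 1L
    has_start <- TRUE
  } else {
    first <- region_begin
    has_start <- is_atg[first]
  }
  beg <- starts[first]
  end <- starts[last_ci] + 3L
  list(start = beg, end = end, length = end - beg,
       has_start = has_start, has_stop = has_stop)
}

#' Find open reading frames in all six frames
#'
#' Scans every reading frame of both strands for ATG-to-stop spans (stop
#' codon included in the span). A span still open at the sequence end is
#' reported with `has_stop = FALSE`, trimmed to whole codons. With
#' `require_start = FALSE` each inter-stop region is reported whether or not
#' it begins with ATG (used for coding-sequence extraction from transcript
#' fragments whose true start may be truncated).
#'
#' Coordinates are 0-based half-open on the forward strand; negative-frame
#' spans are mapped back to forward coordinates. Output is sorted by length
#' descending, ties by frame ascending (+1,+2,+3,-1,-2,-3) then start.
#'
#' @param x A single nucleotide sequence (character) or one-row `txwb_seqs`.
#' @param min_len Minimum span length in nucleotides (default 90, >= 3).
#' @param require_start Must a span begin with ATG? Default `TRUE`.
#' @return data.frame with columns `frame`, `start`, `end`, `length_nt`,
#'   `has_start`, `has_stop`.
#' @examples
#' find_orfs("ATGAAATAG", min_len = 9)
#' @export
find_orfs <- function(x, min_len = 90L, require_start = TRUE) {
  if (is.data.frame(x)) {
    .stop_if(nrow(x) != 1L, "find_orfs takes one record at a time")
    .stop_if(x$moltype == "protein", "find_orfs needs a nucleotide record")
    x <- x$residues
  }
  .stop_if(min_len < 3L, "min_len must be >= 3")
  s <- toupper(x)
  L <- nchar(s)
  rc <- rev_comp(s)
  rows <- list()
  for (f in 1:3) {
    for (sp in .scan_frame(s, f - 1L, min_len, require_start)) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, start = sp$start, end = sp$end, length_nt = sp$length,
        has_start = sp$has_start, has_stop = sp$has_stop)
    }
    for (sp in .scan_frame(rc, f - 1L, min_len, require_start)) {
      rows[[length(rows) + 1L]] <- data.frame(
        frame = -f, start = L - sp$end, end = L - sp$start,
        length_nt = sp$length, has_start = sp$has_start,
        has_stop = sp$has_stop)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      length_nt = integer(), has_start = logical(),
                      has_stop = logical()))
  }
  out <- do.call(rbind, rows)
  frame_rank <- match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  out <- out[.ordc(-out$length_nt, frame_rank, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Translate an ORF to a protein record
#'
#' Extracts the ORF span from the record (reverse-complementing first for
#' negative frames), translates it with the standard genetic code, and drops
#' the trailing stop. Fuzzy codons containing ambiguity codes translate to
#' `X` unless resolvable.
#'
#' @param record One-row `txwb_seqs` nucleotide record.
#' @param orf One row of the [find_orfs()] result for that record.
#' @return A one-row `txwb_seqs` protein record; `seq_id` gains the suffix
#'   `"_orf"` and `dataset_id` is preserved.
#' @export
translate_orf <- function(record, orf) {
  .stop_if(!is.data.frame(record) || nrow(record) != 1L,
           "record must be a one-row txwb_seqs data.frame")
  .stop_if(record$moltype == "protein",
           "translate_orf needs a nucleotide record: ", record$seq_id)
  .stop_if(nrow(orf) != 1L, "orf must be a single row")
  L <- nchar(record$residues)
  .stop_if(orf$start < 0L || orf$end > L || orf$start >= orf$end,
           "ORF coordinates out of bounds for ", record$seq_id)
  span <- substr(record$residues, orf$start + 1L, orf$end)
  if (orf$frame < 0L) span <- rev_comp(span)
  if (orf$has_stop) span <- substr(span, 1L, nchar(span) - 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(span),
                                           if.fuzzy.codon = "solve"))
  .as_seqs(data.frame(seq_id = paste0(record$seq_id, "_orf"), residues = aa,
                      moltype = "protein", dataset_id = record$dataset_id,
                      stringsAsFactors = FALSE))
}

#' Longest-ORF coding sequence extraction
#'
#' Convenience used by the multi-project merge: translates the longest open
#' reading frame (start codon not required) of a nucleotide record. Returns
#' `NULL` when no span of at least `min_len` exists.
#'
#' @inheritParams translate_orf
#' @param min_len Minimum ORF length in nucleotides (default 90).
#' @return A one-row protein `txwb_seqs`, or `NULL`.
#' @export
extract_cds <- function(record, min_len = 90L) {
  orfs <- find_orfs(record, min_len = min_len, require_start = FALSE)
  if (nrow(orfs) == 0L) return(NULL)
  translate_orf(record, orfs[1L, , drop = FALSE])
}

#' Per-sequence summary statistics
#'
#' Length, GC fraction, and ORF summary for each nucleotide record (protein
#' records get NA for GC/ORF fields).
#'
#' @param seqs A `txwb_seqs` data.frame.
#' @param min_orf Minimum ORF length passed to [find_orfs()].
#' @return data.frame with one row per record: `seq_id`, `length`, `gc`,
#'   `n_orfs`, `longest_orf_nt`, `has_orf`.
#' @export
seq_stats <- function(seqs, min_orf = 90L) {
  n <- nrow(seqs)
  out <- data.frame(seq_id = seqs$seq_id, length = nchar(seqs$residues),
                    gc = NA_real_, n_orfs = NA_integer_,
                    longest_orf_nt = NA_integer_, has_orf = NA,
                    stringsAsFactors = FALSE)
  nt <- seqs$moltype == "nucleotide"
  if (any(nt)) out$gc[nt] <- unname(gc_content(seqs$residues[nt]))
  for (i in which(nt)) {
    orfs <- find_orfs(seqs$residues[i], min_len = min_orf)
    out$n_orfs[i] <- nrow(orfs)
    out$longest_orf_nt[i] <- if (nrow(orfs)) orfs$length_nt[1L] else 0L
    out$has_orf[i] <- nrow(orfs) > 0L
  }
  out
}
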