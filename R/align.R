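# Pairwise dynamic-programming alignment used by the hit viewer and for
# cluster member comparison. Semi-global with affine gaps: end gaps that let
# the shorter sequence slide inside the longer one are free; a gap run of
# length k costs gap_open + (k - 1) * gap_extend.

.submat_simple <- function(alphabet, match, mismatch) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

.free_flags <- function(na, nb) {
  # overhangs of the longer sequence are unpenalized; equal lengths align
  # globally
  list(free_x = na > nb, free_y = nb > na)
}

#' Semi-global pairwise alignment with affine gaps
#'
#' Aligns two sequences by dynamic programming. End gaps at the longer
#' sequence's ends are free (so a short hit region may match anywhere within
#' a transcript); equal-length inputs are aligned globally. Nucleotide mode
#' scores match/mismatch (+1 / -1.5 by default); protein mode uses a
#' substitution matrix (BLOSUM62 by default). A gap of length k costs
#' `gap_open + (k - 1) * gap_extend`.
#'
#' @param a,b Sequences (single character strings).
#' @param mode `"nucleotide"` or `"protein"`.
#' @param match,mismatch Nucleotide-mode scores.
#' @param gap_open,gap_extend Positive gap penalties (defaults 4 and 1).
#' @param submat Optional substitution matrix (square, dimnames = residue
#'   alphabet) overriding the mode default.
#' @return A `txwb_alignment` list: `score`, `aligned_a`, `aligned_b`,
#'   `identity` (percent of matching columns, terminal gap runs excluded),
#'   `n_gap_columns`.
#' @examples
#' align_pair("ACGT", "ACT")
#' @export
align_pair <- function(a, b, mode = c("nucleotide", "protein"), match = 1,
                       mismatch = -1.5, gap_open = 4, gap_extend = 1,
                       submat = NULL) {
  mode <- match.arg(mode)
  .stop_if(!nzchar(a) || !nzchar(b), "sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  if (is.null(submat)) {
    submat <- if (mode == "protein") .blosum62() else
      .submat_simple(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])),
                     match, mismatch)
  }
  fl <- .free_flags(nchar(a), nchar(b))
  res <- .gotoh_align_cpp(a, b, submat, rownames(submat), gap_open,
                          gap_extend, fl$free_x, fl$free_y)
  ca <- strsplit(res$aligned_a, "")[[1]]
  cb <- strsplit(res$aligned_b, "")[[1]]
  gap <- ca == "-" | cb == "-"
  core <- .core_columns(ca, cb)
  matches <- sum(ca[core] == cb[core] & !gap[core])
  identity <- if (any(core)) 100 * matches / sum(core) else 0
  structure(list(score = res$score, aligned_a = res$aligned_a,
                 aligned_b = res$aligned_b, identity = identity,
                 n_gap_columns = sum(gap & core)),
            class = "txwb_alignment")
}

# columns between the first and last position where both rows have residues
.core_columns <- function(ca, cb) {
  both <- which(ca != "-" & cb != "-")
  core <- rep(FALSE, length(ca))
  if (length(both)) core[both[1L]:both[length(both)]] <- TRUE
  core
}

#' @export
print.txwb_alignment <- function(x, ...) {
  cat(sprintf("pairwise alignment: score %.2f, identity %.1f%%, %d gap column(s)\n",
              x$score, x$identity, x$n_gap_columns))
  cat(x$aligned_a, "\n")
  ca <- strsplit(x$aligned_a, "")[[1]]
  cb <- strsplit(x$aligned_b, "")[[1]]
  cat(paste(ifelse(ca == cb & ca != "-", "|", " "), collapse = ""), "\n")
  cat(x$aligned_b, "\n")
  invisible(x)
}

#' Align an annotation hit region to a sequence
#'
#' Nucleotide mode aligns the hit region directly to the transcript.
#' Protein-vs-translated mode translates the transcript's HSP frame first
#' and aligns the hit residues to the translation with a substitution
#' matrix; the frame is required in that mode unless the record is already a
#' protein.
#'
#' @param record One-row `txwb_seqs`.
#' @param hit_region Residues of the hit (character).
#' @param mode `"nucleotide"` or `"protein"`.
#' @param frame HSP frame (+1..+3, -1..-3); required for protein mode on a
#'   nucleotide record.
#' @param ... Passed to [align_pair()].
#' @return A `txwb_alignment`.
#' @export
align_hit_to_seq <- function(record, hit_region,
                             mode = c("nucleotide", "protein"),
                             frame = NULL, ...) {
  mode <- match.arg(mode)
  seq <- record$residues
  if (mode == "protein" && record$moltype == "nucleotide") {
    .stop_if(is.null(frame), "protein mode needs the HSP frame")
    s <- if (frame < 0) rev_comp(seq) else seq
    off <- abs(frame) - 1L
    s <- substr(s, off + 1L, off + 3L * ((nchar(s) - off) %/% 3L))
    seq <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                              if.fuzzy.codon = "solve"))
    seq <- gsub("\\*.*$", "", seq)  # stop at the first stop codon
    .stop_if(!nzchar(seq), "frame translation is empty")
  }
  if (mode == "nucleotide")
    .stop_if(record$moltype == "protein",
             "nucleotide mode needs a nucleotide record")
  align_pair(seq, hit_region, mode = mode, ...)
}
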