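# Binomial SNP calling on per-position pileup columns.
#
# The null hypothesis at a position is "non-consensus reads are sequencing
# errors only": with depth n and per-base error rate e, the count k of reads
# confirming a variant base is Binomial(n, e), and the call p-value is the
# upper tail P(X >= k). Small p-values reject the error-only null.

#' Upper-tail binomial p-value for variant confirmation
#'
#' `P(X >= k)` for `X ~ Binomial(n, e)`; exact, stable in log space for
#' large `n`. `k = 0` gives 1 by definition.
#'
#' @param k Number of confirming (variant) reads, `0 <= k <= n`; vectorised.
#' @param n Read depth at the position.
#' @param e Estimated base-call error rate in (0, 1).
#' @return p-value(s) in (0, 1].
#' @examples
#' binomial_pvalue(1, 1, 0.01)       # 0.01
#' binomial_pvalue(4, 30, 0.01)      # ~2.2e-4
#' @export
binomial_pvalue <- function(k, n, e) {
  .stop_if(any(e <= 0 | e >= 1), "error rate e must be in (0, 1)")
  .stop_if(any(k < 0), "k must be non-negative")
  .stop_if(any(k > n), "k exceeds depth n")
  pbinom(k - 1, n, e, lower.tail = FALSE)
}

#' Read a per-column pileup table
#'
#' Tab-separated with header `contig`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#' `gap`: one row per contig position, 0-based, with the consensus base and
#' the count of reads showing each base (or a gap) at that position.
#'
#' @param path Pileup TSV path.
#' @return data.frame with those columns, validated.
#' @export
read_pileup <- function(path) {
  .stop_if(!file.exists(path), "pileup file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "A", "C", "G", "T", "gap")
  .stop_if(!all(need %in% colnames(df)), "pileup ", path,
           " must have columns: ", paste(need, collapse = ", "))
  for (cc in c("pos", "A", "C", "G", "T", "gap")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v) | v < 0)
    .stop_if(length(bad) > 0L, "malformed pileup ", path, " line ",
             bad[1L] + 1L, ", column '", cc, "'")
    df[[cc]] <- v
  }
  badref <- which(!df$ref %in% c("A", "C", "G", "T"))
  .stop_if(length(badref) > 0L, "malformed pileup ", path, " line ",
           badref[1L] + 1L, ": consensus base must be A/C/G/T")
  df
}

#' Call SNPs from pileup columns
#'
#' For every column and every non-consensus base (including the gap, coded
#' `-`) with at least `min_confirm` supporting reads, a call is emitted when
#' the upper-tail binomial p-value at depth `n` (total of all base and gap
#' counts) is at most `alpha`. Several variant bases may be called at one
#' position. No multiple-testing correction is applied; the raw p-value and
#' depth are reported for downstream filtering.
#'
#' @param pileup data.frame from [read_pileup()] (or of the same shape).
#' @param e Base-call error rate (default 0.01).
#' @param alpha Call threshold on the p-value (default 1e-3).
#' @param min_confirm Minimum confirming reads (default 2).
#' @return data.frame of calls: `contig_id`, `pos`, `consensus_base`,
#'   `variant_base`, `k`, `n`, `e`, `p_value`.
#' @export
call_snps <- function(pileup, e = 0.01, alpha = 1e-3, min_confirm = 2L) {
  .stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  .stop_if(min_confirm < 1L, "min_confirm must be >= 1")
  bases <- c("A", "C", "G", "T", "gap")
  cnt <- as.matrix(pileup[, bases])
  n <- rowSums(cnt)
  out <- list()
  for (b in bases) {
    k <- cnt[, b]
    cand <- which(pileup$ref != b & k >= min_confirm & n >= 1)
    if (length(cand) == 0L) next
    p <- binomial_pvalue(k[cand], n[cand], e)
    keep <- p <= alpha
    if (!any(keep)) next
    i <- cand[keep]
    out[[b]] <- data.frame(contig_id = pileup$contig[i], pos = pileup$pos[i],
                           consensus_base = pileup$ref[i],
                           variant_base = if (b == "gap") "-" else b,
                           k = unname(k[i]), n = unname(n[i]), e = e,
                           p_value = unname(p[keep]),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(), pos = numeric(),
                      consensus_base = character(),
                      variant_base = character(), k = numeric(),
                      n = numeric(), e = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[.ordc(res$contig_id, res$pos, res$variant_base), , drop = FALSE]
  rownames(res) <- NULL
  res
}
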