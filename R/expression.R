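# Libraries, replicates, count import, RPKM, the Poisson-based R statistic,
# fold change and co-expression correlation.

#' Define a count library
#'
#' A library is one biological condition column of the project; its counts
#' may come from several replicate columns, which are summed for display and
#' normalisation but kept separate for external DE analysis.
#'
#' @param lib_id Short column-heading string, unique within a project.
#' @param replicates Character vector of replicate column ids (default: the
#'   library id itself, i.e. a single-replicate library).
#' @param title,species,cultivar,strain,tissue,treatment,sequencing_lab,year
#'   Optional metadata shown on the project overview.
#' @return A `txwb_library` list.
#' @export
library_def <- function(lib_id, replicates = lib_id, title = NA,
                        species = NA, cultivar = NA, strain = NA,
                        tissue = NA, treatment = NA, sequencing_lab = NA,
                        year = NA) {
  .stop_if(!nzchar(lib_id), "lib_id must be non-empty")
  .stop_if(length(replicates) < 1L, "library '", lib_id,
           "' needs at least one replicate")
  structure(list(lib_id = lib_id, replicates = as.character(replicates),
                 metadata = list(title = title, species = species,
                                 cultivar = cultivar, strain = strain,
                                 tissue = tissue, treatment = treatment,
                                 sequencing_lab = sequencing_lab,
                                 year = year)),
            class = "txwb_library")
}

.read_count_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  .stop_if(ncol(df) < 2L, "count file ", path,
           " needs a seq_id column plus count columns")
  for (j in 2:ncol(df)) {
    v <- df[[j]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))) | is.na(v))
    .stop_if(length(bad) > 0L, "non-numeric count in ", path, " line ",
             bad[1L] + 1L, ", column '", colnames(df)[j], "'")
    neg <- which(as.numeric(v) < 0)
    .stop_if(length(neg) > 0L, "negative count in ", path, " line ",
             neg[1L] + 1L, ", column '", colnames(df)[j], "'")
    df[[j]] <- as.numeric(v)
  }
  df
}

#' Import read counts for a set of libraries
#'
#' Accepts either a single delimited matrix (first column sequence ids,
#' header naming replicate columns) or one two-column file per library /
#' replicate. Every replicate column must map to exactly one library; a
#' sequence present in the project but absent from the counts gets zeros
#' with a warning.
#'
#' @param x Path to a matrix TSV, a named character vector of per-replicate
#'   two-column TSV paths (names = replicate ids), or a numeric matrix with
#'   rownames = seq ids and colnames = replicate ids.
#' @param libraries List of [library_def()] objects.
#' @param seq_ids Optional character vector of all project sequence ids, used
#'   to zero-fill and order rows.
#' @return A `txwb_counts` list: `counts` (seq x replicate), `lib_counts`
#'   (seq x library, replicates summed), `lib_totals` (named per-library
#'   totals N_i), `rep2lib`, and `libraries`.
#' @export
import_counts <- function(x, libraries, seq_ids = NULL) {
  .stop_if(length(libraries) == 0L, "no libraries defined")
  lib_ids <- vapply(libraries, `[[`, character(1), "lib_id")
  .stop_if(anyDuplicated(lib_ids) > 0L, "duplicate lib_id: ",
           paste(unique(lib_ids[duplicated(lib_ids)]), collapse = ", "))
  rep2lib <- unlist(lapply(libraries, function(l)
    setNames(rep(l$lib_id, length(l$replicates)), l$replicates)))
  .stop_if(anyDuplicated(names(rep2lib)) > 0L,
           "replicate mapped to more than one library: ",
           paste(unique(names(rep2lib)[duplicated(names(rep2lib))]),
                 collapse = ", "))

  if (is.matrix(x)) {
    mat <- x
  } else if (is.character(x) && length(x) > 1L) {
    cols <- lapply(x, function(p) {
      df <- .read_count_table(p)
      setNames(df[[2L]], df[[1L]])
    })
    ids <- .sortc(unique(unlist(lapply(cols, names))))
    mat <- vapply(cols, function(v) {
      out <- setNames(numeric(length(ids)), ids)
      out[names(v)] <- v
      out
    }, numeric(length(ids)))
    colnames(mat) <- names(x)
  } else {
    df <- .read_count_table(x)
    .stop_if(anyDuplicated(colnames(df)[-1L]) > 0L,
             "count column named twice in ", x, ": ",
             paste(unique(colnames(df)[-1L][duplicated(colnames(df)[-1L])]),
                   collapse = ", "))
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- as.character(df[[1L]])
  }
  .stop_if(anyDuplicated(colnames(mat)) > 0L, "count column named twice: ",
           paste(unique(colnames(mat)[duplicated(colnames(mat))]),
                 collapse = ", "))
  unknown <- setdiff(colnames(mat), names(rep2lib))
  .stop_if(length(unknown) > 0L,
           "count column not mapped to any library: ",
           paste(unknown, collapse = ", "))
  missing_rep <- setdiff(names(rep2lib), colnames(mat))
  .stop_if(length(missing_rep) > 0L, "no counts for replicate: ",
           paste(missing_rep, collapse = ", "))
  mat <- mat[, names(rep2lib), drop = FALSE]

  if (!is.null(seq_ids)) {
    absent <- setdiff(seq_ids, rownames(mat))
    if (length(absent) > 0L) {
      warning(length(absent), " sequence(s) absent from counts, ",
              "zero-filled: ", paste(head(absent, 5L), collapse = ", "),
              if (length(absent) > 5L) ", ..." else "", call. = FALSE)
      zero <- matrix(0, nrow = length(absent), ncol = ncol(mat),
                     dimnames = list(absent, colnames(mat)))
      mat <- rbind(mat, zero)
    }
    extra <- setdiff(rownames(mat), seq_ids)
    .stop_if(length(extra) > 0L, "counts given for unknown sequence(s): ",
             paste(head(extra, 5L), collapse = ", "))
    mat <- mat[seq_ids, , drop = FALSE]
  } else {
    mat <- mat[.sortc(rownames(mat)), , drop = FALSE]
  }

  lib_counts <- vapply(lib_ids, function(l)
    rowSums(mat[, names(rep2lib)[rep2lib == l], drop = FALSE]),
    numeric(nrow(mat)))
  if (nrow(mat) == 1L)
    lib_counts <- matrix(lib_counts, nrow = 1L,
                         dimnames = list(rownames(mat), lib_ids))
  structure(list(counts = mat, lib_counts = lib_counts,
                 lib_totals = colSums(lib_counts), rep2lib = rep2lib,
                 libraries = libraries),
            class = "txwb_counts")
}

#' RPKM normalisation
#'
#' Reads Per Kilobase of transcript per Million mapped reads:
#' `1e9 * c / (N * L)` for raw count `c`, library total `N` and transcript
#' length `L` in nucleotides.
#'
#' @param counts Raw count(s), recycled with `N` and `len`.
#' @param N Per-library total of assigned reads (> 0).
#' @param len Transcript length in nt (> 0).
#' @return Numeric vector of RPKM values.
#' @examples
#' rpkm(50, 2e6, 500)   # 50
#' @export
rpkm <- function(counts, N, len) {
  .stop_if(any(N <= 0), "library total N must be > 0")
  .stop_if(any(len <= 0), "sequence length must be > 0")
  1e9 * counts / (N * len)
}

#' RPKM matrix for a project
#'
#' @param counts A `txwb_counts` object.
#' @param seq_lengths Named vector of transcript lengths (nt) covering every
#'   row of the count matrix.
#' @return Matrix of RPKM values, sequences x libraries, computed on
#'   replicate-summed library counts with N the per-library grand total.
#' @export
rpkm_matrix <- function(counts, seq_lengths) {
  ids <- rownames(counts$lib_counts)
  .stop_if(!all(ids %in% names(seq_lengths)), "missing sequence length")
  L <- seq_lengths[ids]
  sweep(counts$lib_counts / L, 2L, counts$lib_totals, "/") * 1e9
}

#' Poisson-based R statistic for count heterogeneity across libraries
#'
#' Log-likelihood-ratio score (Stekel-style) for whether one sequence's
#' counts are distributed across libraries in proportion to the library
#' sizes: with counts `x_i`, library totals `N_i` and overall proportion
#' `f = sum(x) / sum(N)`,
#' \deqn{R = \sum_i x_i \ln\left(\frac{x_i}{N_i f}\right)}
#' using the convention 0 ln 0 = 0 and natural logarithms (nats). R is 0
#' exactly when all `x_i / N_i` are equal and grows with library
#' specificity.
#'
#' @param x Non-negative counts, one per library.
#' @param N Positive library totals, same length (names used in errors).
#' @return List with elements `R` and `f`.
#' @examples
#' r_statistic(c(20, 0), c(1000, 1000))$R   # 20 * log(2)
#' @export
r_statistic <- function(x, N) {
  .stop_if(length(x) != length(N), "x and N lengths differ")
  bad <- which(N <= 0)
  .stop_if(length(bad) > 0L, "library total is zero for: ",
           paste(if (is.null(names(N))) bad else names(N)[bad],
                 collapse = ", "))
  .stop_if(any(x < 0), "counts must be non-negative")
  f <- sum(x) / sum(N)
  if (f == 0) return(list(R = 0, f = 0))
  pos <- x > 0
  R <- sum(x[pos] * log(x[pos] / (N[pos] * f)))
  list(R = max(R, 0), f = f)
}

#' R statistic for every sequence of a project
#'
#' @param counts A `txwb_counts` object (uses replicate-summed library counts
#'   and per-library totals).
#' @return data.frame with `seq_id`, `R` (nats) and `f`.
#' @export
r_statistic_all <- function(counts) {
  x <- counts$lib_counts
  N <- counts$lib_totals
  f <- rowSums(x) / sum(N)
  lx <- x
  rate <- sweep(matrix(1, nrow(x), ncol(x)), 2L, N, "*") * f
  term <- ifelse(x > 0, x * log(x / rate), 0)
  R <- pmax(rowSums(term), 0)
  data.frame(seq_id = rownames(x), R = unname(R), f = unname(f),
             stringsAsFactors = FALSE)
}

#' Signed log2 fold change between two expression values
#'
#' `log2((a + pseudo) / (b + pseudo))`; the pseudo-count (default 0.1 RPKM)
#' keeps zero counts finite.
#'
#' @param a,b RPKM (or count) values; vectorised.
#' @param pseudo Positive pseudo-count.
#' @return Signed log2 ratio(s).
#' @export
fold_change <- function(a, b, pseudo = 0.1) {
  .stop_if(pseudo <= 0, "pseudo must be > 0")
  log2((a + pseudo) / (b + pseudo))
}

#' Pearson co-expression matrix over selected sequences
#'
#' Correlates RPKM profiles (optionally log2(RPKM + 1)) across the selected
#' libraries. Pairs with fewer than 3 mutually finite points, or involving a
#' zero-variance profile, are `NA`; the diagonal is 1.
#'
#' @param rpkm Matrix from [rpkm_matrix()] (sequences x libraries).
#' @param seq_ids,libraries Optional selections (default: all).
#' @param log2 Apply `log2(x + 1)` first?
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(rpkm, seq_ids = NULL, libraries = NULL,
                               log2 = FALSE) {
  if (!is.null(seq_ids)) rpkm <- rpkm[seq_ids, , drop = FALSE]
  if (!is.null(libraries)) rpkm <- rpkm[, libraries, drop = FALSE]
  .stop_if(ncol(rpkm) < 2L, "need at least 2 libraries for correlation")
  m <- if (log2) log2(rpkm + 1) else rpkm
  r <- suppressWarnings(cor(t(m), use = "pairwise.complete.obs",
                            method = "pearson"))
  nfin <- is.finite(m) %*% t(is.finite(m))
  r[nfin < 3L] <- NA_real_
  diag(r) <- 1
  r
}
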