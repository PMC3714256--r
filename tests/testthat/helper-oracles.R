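# Independent reference implementations used to cross-check the package.
# Each oracle is written from the definition, not from the package code.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# exhaustive six-frame ORF scan: enumerate every candidate start codon,
# walk codon by codon to its first stop, dedupe to maximal spans
oracle_orfs <- function(s, min_len = 90L, require_start = TRUE) {
  L <- nchar(s)
  rows <- list()
  for (ori in c(1L, -1L)) {
    str <- if (ori == 1L) s else oracle_revcomp(s)
    for (f in 1:3) {
      n_codon <- (L - (f - 1L)) %/% 3L
      if (n_codon < 1L) next
      codons <- substring(str, f + 3L * (seq_len(n_codon) - 1L),
                          f + 3L * seq_len(n_codon) - 1L)
      stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
      spans <- list()
      if (require_start) {
        for (a in which(codons == "ATG")) {
          st <- stop_idx[stop_idx >= a]
          has_stop <- length(st) > 0L
          end_c <- if (has_stop) st[1L] else n_codon
          key <- paste(has_stop, end_c)
          if (is.null(spans[[key]]) || a < spans[[key]]$a)
            spans[[key]] <- list(a = a, end_c = end_c,
                                 has_stop = has_stop, has_start = TRUE)
        }
      } else {
        region_starts <- c(1L, stop_idx + 1L)
        region_stops <- c(stop_idx, n_codon + 1L)
        for (r in seq_along(region_starts)) {
          a <- region_starts[r]
          has_stop <- region_stops[r] <= n_codon
          end_c <- if (has_stop) region_stops[r] else n_codon
          if (end_c < a) next
          spans[[length(spans) + 1L]] <- list(
            a = a, end_c = end_c, has_stop = has_stop,
            has_start = codons[a] == "ATG")
        }
      }
      for (sp in spans) {
        start_nt <- (f - 1L) + 3L * (sp$a - 1L)
        end_nt <- (f - 1L) + 3L * sp$end_c
        len <- end_nt - start_nt
        if (len < min_len) next
        if (ori == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            frame = f, start = start_nt, end = end_nt, length_nt = len,
            has_start = sp$has_start, has_stop = sp$has_stop)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            frame = -f, start = L - end_nt, end = L - start_nt,
            length_nt = len, has_start = sp$has_start,
            has_stop = sp$has_stop)
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(), start = integer(),
                      end = integer(), length_nt = integer(),
                      has_start = logical(), has_stop = logical()))
  out <- do.call(rbind, rows)
  fr <- match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  out <- out[order(-out$length_nt, fr, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# term-by-term binomial upper tail, log-space
oracle_binom_upper <- function(k, n, e) {
  if (k == 0L) return(1)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(e) + (n - j) * log1p(-e)))
}

# direct evaluation of the heterogeneity statistic from its definition
oracle_rstat <- function(x, N) {
  f <- sum(x) / sum(N)
  if (f == 0) return(0)
  s <- 0
  for (i in seq_along(x)) {
    if (x[i] > 0) s <- s + x[i] * log(x[i] / (N[i] * f))
  }
  s
}

# connected components by boolean matrix closure (reachability)
oracle_components <- function(nodes, edge_a, edge_b) {
  n <- length(nodes)
  A <- diag(TRUE, n)
  dimnames(A) <- list(nodes, nodes)
  if (length(edge_a)) {
    A[cbind(edge_a, edge_b)] <- TRUE
    A[cbind(edge_b, edge_a)] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp_key <- apply(A, 1L, function(r) paste(which(r), collapse = ","))
  unname(split(nodes, comp_key))
}

# exhaustive alignment optimum over all paths (independent compiled
# enumerator; different algorithm from the DP it checks)
oracle_align_score <- function(a, b, match = 1, mismatch = -1.5,
                               gap_open = 4, gap_extend = 1) {
  alpha <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sm <- matrix(mismatch, length(alpha), length(alpha),
               dimnames = list(alpha, alpha))
  diag(sm) <- match
  txwb:::.bruteforce_align_cpp(a, b, sm, alpha, gap_open, gap_extend,
                               nchar(a) > nchar(b), nchar(b) > nchar(a))
}

rand_dna_str <- function(L) paste(sample(c("A", "C", "G", "T"), L,
                                         replace = TRUE), collapse = "")

# row-by-row predicate scan over the master sequence table
oracle_filter_scan <- function(store, f) {
  tab <- txwb:::.seq_table(store)
  pass <- function(row) {
    ok <- TRUE
    if (!is.null(f$rpkm_min)) {
      for (lib in names(f$rpkm_min)) {
        v <- row[[paste0("rpkm_", lib)]]
        ok <- ok && !is.na(v) && v >= f$rpkm_min[[lib]]
      }
    }
    if (ok && !is.null(f$pval_max)) {
      ps <- unlist(row[f$pval_columns])
      hit <- !is.na(ps) & ps <= f$pval_max
      ok <- if (identical(f$pval_mode, "any")) any(hit) else all(hit)
    }
    if (ok && !is.null(f$length_min)) ok <- row$length >= f$length_min
    if (ok && !is.null(f$length_max)) ok <- row$length <= f$length_max
    if (ok && !is.null(f$has_orf))
      ok <- !is.na(row$has_orf) && row$has_orf == f$has_orf
    if (ok && !is.null(f$anno_keyword)) {
      d <- if (is.na(row$best_anno_desc)) "" else row$best_anno_desc
      ok <- grepl(tolower(f$anno_keyword), tolower(d), fixed = TRUE)
    }
    if (ok && !is.null(f$taxonomy))
      ok <- row$seq_id %in%
        store$hits$seq_id[store$hits$taxonomy_tag %in% f$taxonomy]
    if (ok && !is.null(f$remark)) {
      r <- if (is.na(row$remark)) "" else row$remark
      ok <- grepl(tolower(f$remark), tolower(r), fixed = TRUE)
    }
    isTRUE(ok)
  }
  keep <- vapply(seq_len(nrow(tab)), function(i)
    pass(as.list(tab[i, , drop = FALSE])), logical(1))
  sort(tab$seq_id[keep])
}

# a random filter over the facets the scan oracle understands
random_filter <- function(store) {
  f <- list()
  if (runif(1) < 0.4 && !is.null(store$rpkm)) {
    lib <- sample(colnames(store$rpkm), 1L)
    f$rpkm_min <- setNames(runif(1, 0, 50), lib)
  }
  if (runif(1) < 0.4 && !is.null(store$pvals)) {
    cols <- sample(colnames(store$pvals)[-1L],
                   sample(ncol(store$pvals) - 1L, 1L))
    f$pval_max <- 10^runif(1, -12, -1)
    f$pval_columns <- cols
    f$pval_mode <- sample(c("all", "any"), 1L)
  }
  if (runif(1) < 0.4) f$length_min <- sample(300:900, 1L)
  if (runif(1) < 0.3) f$length_max <- sample(600:1200, 1L)
  if (runif(1) < 0.3) f$has_orf <- runif(1) < 0.5
  if (runif(1) < 0.3) f$anno_keyword <- sample(c("cytochrome", "synthase",
                                                 "protein", "kinase"), 1L)
  if (runif(1) < 0.2) f$remark <- sample(c("rhizome", "qpcr", "tip"), 1L)
  do.call(txwb::filter_spec, f)
}

# one small fully-loaded single project reused across workbench tests
demo_store <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "txwb-demo-fixture")
      fx <- txwb::fixture_preset("demo-replicas", d, seed = 101)
      cache <<- list(store = txwb::build_project(fx$config), fx = fx,
                     dir = d)
    }
    cache
  }
})

# random undirected similarity-pair table over the given nodes
rand_pair_table <- function(nodes, ne) {
  a <- sample(nodes, ne, replace = TRUE)
  b <- sample(nodes, ne, replace = TRUE)
  ok <- a != b
  k <- sum(ok)
  data.frame(seq_a = pmin(a, b)[ok], seq_b = pmax(a, b)[ok],
             percent_identity = rep(90, k), percent_overlap = rep(90, k),
             e_value = rep(1e-30, k), bit_score = rep(100, k),
             stringsAsFactors = FALSE)
}
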