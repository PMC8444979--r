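#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling normalization for count data. The reference sample
#' is the library whose log total count is closest to the mean log total
#' count. For every other sample, genes expressed in both the sample and the
#' reference contribute an M-value (log2 depth-adjusted expression ratio) and
#' an A-value (average log2 expression); after trimming the most extreme 30%
#' of M-values and 5% of A-values on each side, the factor is the
#' precision-weighted mean of the surviving M-values (weights from the
#' asymptotic binomial variance of M). Factors are normalized to geometric
#' mean 1.
#'
#' @param counts non-negative gene x sample matrix (>= 2 samples); `NA`s are
#'   treated as unobserved (counted as 0 in library sizes, excluded from
#'   trimming).
#' @param logratio_trim two-sided trim fraction on M-values (default 0.3).
#' @param abs_trim two-sided trim fraction on A-values (default 0.05).
#' @return Named numeric vector of per-sample scaling factors, geometric
#'   mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abs_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  counts[is.na(counts)] <- 0
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    if (is.null(bad)) bad <- which(lib == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  ref <- which.min(abs(log(lib) - mean(log(lib))))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], lib[j], counts[, ref], lib[ref],
                    logratio_trim, abs_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One sample against the reference: doubly trimmed, weighted mean of M.
tmm_pair_factor <- function(obs, n_obs, ref, n_ref, logratio_trim, abs_trim) {
  keep <- obs > 0 & ref > 0
  if (!any(keep)) {
    warning("no doubly-expressed genes against reference; factor set to 1")
    return(1)
  }
  o <- obs[keep]; r <- ref[keep]
  m <- log2((o / n_obs) / (r / n_ref))
  a <- 0.5 * log2((o / n_obs) * (r / n_ref))
  w <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_trim) + 1;      hi_a <- n + 1 - lo_a
  rm_ <- rank(m, ties.method = "first")
  ra_ <- rank(a, ties.method = "first")
  keep2 <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep2) || sum(1 / w[keep2]) == 0) return(1)
  fac <- 2^(sum(m[keep2] / w[keep2]) / sum(1 / w[keep2]))
  if (!is.finite(fac) || fac <= 0) 1 else fac
}

#' Counts per million with optional TMM scaling
#'
#' @param counts gene x sample matrix.
#' @param norm_factors per-sample scaling factors (e.g. from
#'   [tmm_factors()]); default 1.
#' @param log whether to return log1p-transformed values.
#' @return Matrix of (TMM-scaled) counts per million.
#' @export
cpm_normalize <- function(counts, norm_factors = NULL, log = FALSE) {
  counts <- as.matrix(counts)
  lib <- colSums(counts, na.rm = TRUE)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  eff <- lib * norm_factors
  if (any(eff == 0)) stop("effective library size of 0")
  out <- sweep(counts, 2L, eff / 1e6, "/")
  if (log) log1p(out) else out
}
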