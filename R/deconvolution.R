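#' Estimate cell-type fractions by nu-support-vector regression
#'
#' Linear-kernel nu-SVR deconvolution of bulk expression profiles against a
#' signature matrix (the CIBERSORT algorithm). Per sample: the mixture and
#' the signature are restricted to their shared genes, both are z-scored
#' (the signature by its global mean/SD, the mixture per sample), and a
#' nu-SVR with linear kernel is fitted for every nu in `nu_grid`; the fit
#' minimizing the root-mean-square reconstruction error is kept. Negative
#' coefficients are clipped to zero and the remainder renormalized to a
#' simplex. Quantile normalization is not applied (RNA-seq practice).
#'
#' @param bulk gene x sample matrix on a linear scale; raw counts
#'   (`input_scale = "counts"`, TMM + CPM applied internally) or
#'   already-normalized values such as TPM/CPM (`input_scale =
#'   "normalized"`, used as-is).
#' @param sig a `signature_matrix` (genes x cell types).
#' @param nu_grid candidate nu values (default 0.25, 0.5, 0.75).
#' @param input_scale `"normalized"` or `"counts"`.
#' @param min_coverage minimum fraction of signature genes that must be
#'   present in the bulk matrix (default 0.5; fewer is an error).
#' @return An object of class `proportion_estimate`: list with `fractions`
#'   (sample x cell-type matrix, rows on the unit simplex) and `diagnostics`
#'   (data.frame `sample`, `rmse`, `corr`, `nu`).
#' @export
deconvolve <- function(bulk, sig, nu_grid = c(0.25, 0.5, 0.75),
                       input_scale = c("normalized", "counts"),
                       min_coverage = 0.5) {
  input_scale <- match.arg(input_scale)
  bulk <- as.matrix(bulk)
  if (any(bulk < 0, na.rm = TRUE)) stop("bulk expression must be non-negative")
  if (input_scale == "counts")
    bulk <- cpm_normalize(bulk, tmm_factors(bulk))
  shared <- intersect(rownames(sig), rownames(bulk))
  coverage <- length(shared) / nrow(sig)
  if (coverage < min_coverage)
    stop(sprintf("only %.0f%% of signature genes present in bulk (need >= %.0f%%)",
                 100 * coverage, 100 * min_coverage))
  X <- sig[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  Xz <- (X - mean(X)) / stats::sd(X)

  n_types <- ncol(X)
  samples <- colnames(B)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(B)))
  fractions <- matrix(NA_real_, nrow = ncol(B), ncol = n_types,
                      dimnames = list(samples, colnames(X)))
  diag_df <- data.frame(sample = samples, rmse = NA_real_, corr = NA_real_,
                        nu = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(B))) {
    y <- B[, j]
    if (stats::sd(y) == 0)
      stop("degenerate (constant) mixture vector in sample ", samples[j])
    yz <- (y - mean(y)) / stats::sd(y)
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(x = Xz, y = yz, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE,
                        tolerance = 1e-4)
      q <- as.vector(t(fit$coefs) %*% fit$SV)
      q[q < 0] <- 0
      recon <- as.vector(Xz %*% q)
      rmse <- sqrt(mean((recon - yz)^2))
      if (is.null(best) || rmse < best$rmse)
        best <- list(q = q, rmse = rmse,
                     corr = suppressWarnings(stats::cor(recon, yz)), nu = nu)
    }
    if (sum(best$q) == 0)
      stop("deconvolution degenerate (all coefficients <= 0) in sample ",
           samples[j])
    fractions[j, ] <- best$q / sum(best$q)
    diag_df$rmse[j] <- best$rmse
    diag_df$corr[j] <- best$corr
    diag_df$nu[j] <- best$nu
  }
  structure(list(fractions = fractions, diagnostics = diag_df),
            class = "proportion_estimate")
}

#' @export
print.proportion_estimate <- function(x, ...) {
  cat("proportion_estimate:", nrow(x$fractions), "samples x",
      ncol(x$fractions), "cell types; mean rmse",
      signif(mean(x$diagnostics$rmse), 3), "\n")
  invisible(x)
}

#' @rdname sigdecon-io
#' @export
write_fractions_tsv <- function(x, path) {
  f <- if (inherits(x, "proportion_estimate")) x$fractions else x
  df <- data.frame(sample = rownames(f), f, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sigdecon-io
#' @export
read_fractions_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
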