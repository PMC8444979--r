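#' Median split of a continuous feature
#'
#' Labels every sample `H` when its value lies strictly above the cohort
#' median, `L` otherwise (ties at the median go to `L`). Errors when either
#' group would be empty (constant vectors, or a median equal to the
#' maximum).
#'
#' @param values named numeric vector (sample -> value), length >= 2.
#' @return An object of class `stratification`: list with `labels` (named
#'   character), `scheme = "single"` and `split_value` (the median).
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("median split needs >= 2 samples")
  if (is.null(names(values))) names(values) <- paste0("s", seq_along(values))
  med <- stats::median(values)
  labels <- ifelse(values > med, "H", "L")
  if (length(unique(labels)) < 2L)
    stop("degenerate median split: all samples on one side of the median")
  structure(list(labels = labels, scheme = "single", split_value = med),
            class = "stratification")
}

#' Two-factor median stratification
#'
#' Median-splits two features independently on the same samples and crosses
#' the labels into the four strata L/L, L/H, H/L and H/H (first factor
#' first).
#'
#' @param x,y named numeric vectors over the same sample set.
#' @return A `stratification` with `scheme = "two-factor"` and a
#'   `split_value` per factor.
#' @export
two_factor_strata <- function(x, y) {
  if (!setequal(names(x), names(y)))
    stop("x and y must cover the same samples")
  y <- y[names(x)]
  sx <- tryCatch(median_split(x), error = function(e)
    stop("factor x: ", conditionMessage(e)))
  sy <- tryCatch(median_split(y), error = function(e)
    stop("factor y: ", conditionMessage(e)))
  labels <- paste(sx$labels, sy$labels[names(sx$labels)], sep = "/")
  names(labels) <- names(sx$labels)
  structure(list(labels = labels, scheme = "two-factor",
                 split_value = c(x = sx$split_value, y = sy$split_value)),
            class = "stratification")
}

strat_labels <- function(strat) {
  if (inherits(strat, "stratification")) strat$labels else strat
}

#' Kaplan-Meier survival curves per stratum
#'
#' Product-limit estimate of the survival function within each stratum.
#' Censored times reduce the at-risk count without producing a step.
#'
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @param strat a `stratification` (or named label vector) covering the
#'   clinical samples; groups must be non-empty.
#' @return An object of class `km_result`: list with `curves` (data.frame
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`) and `groups`.
#' @export
km_estimate <- function(clinical, strat) {
  labels <- strat_labels(strat)
  d <- align_clinical(clinical, labels)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  groups <- sort(unique(d$group))
  if (is.null(fit$strata)) {
    gvec <- rep(groups, length(fit$time))
  } else {
    gvec <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = gvec, time = fit$time, n_risk = fit$n.risk,
                       n_event = fit$n.event, n_censor = fit$n.censor,
                       surv = fit$surv, stringsAsFactors = FALSE)
  structure(list(curves = curves, groups = groups), class = "km_result")
}

align_clinical <- function(clinical, labels) {
  missing <- setdiff(names(labels), clinical$sample_id)
  if (length(missing))
    stop("stratified sample(s) without clinical data: ",
         paste(utils::head(missing, 5), collapse = ", "))
  d <- clinical[match(names(labels), clinical$sample_id), ]
  d$group <- unname(labels)
  if (any(table(d$group) == 0)) stop("empty stratum")
  d
}

#' Log-rank (Mantel-Cox) test across strata
#'
#' Observed-versus-expected chi-square test on k groups with k - 1 degrees
#' of freedom; p-value from the upper chi-square tail.
#'
#' @inheritParams km_estimate
#' @return List with `chi2`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(clinical, strat) {
  labels <- strat_labels(strat)
  d <- align_clinical(clinical, labels)
  k <- length(unique(d$group))
  if (k < 2L) stop("log-rank test needs >= 2 non-empty groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- k - 1L
  list(chi2 = unname(sd_$chisq), df = df,
       p_value = stats::pchisq(sd_$chisq, df = df, lower.tail = FALSE),
       n_groups = k)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' input order is preserved.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Median-split survival screen over a feature family
#'
#' Runs the single-factor analysis of the stratified Kaplan-Meier design for
#' every feature (cell-type fraction or gene expression column): median
#' split, log-rank test, then BH adjustment across the whole family of
#' features screened in this call.
#'
#' @param features sample x feature numeric matrix (rownames = sample ids).
#' @param clinical data.frame with `sample_id`, `time`, `event`.
#' @return data.frame `feature`, `split_value`, `chi2`, `p_value`, `q_value`
#'   (features whose split is degenerate get `NA` statistics and are
#'   excluded from the BH family).
#' @export
survival_screen <- function(features, clinical) {
  features <- as.matrix(features)
  out <- data.frame(feature = colnames(features), split_value = NA_real_,
                    chi2 = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(features))) {
    res <- tryCatch({
      strat <- median_split(features[, j])
      lr <- logrank_test(clinical, strat)
      list(split = strat$split_value, chi2 = lr$chi2, p = lr$p_value)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$split_value[j] <- res$split
      out$chi2[j] <- res$chi2
      out$p_value[j] <- res$p
    }
  }
  ok <- !is.na(out$p_value)
  out$q_value[ok] <- bh_adjust(out$p_value[ok])
  out
}

#' Gene-fraction correlation matrix
#'
#' Correlates the expression of each gene with each cell-type fraction
#' across shared samples, as in receptor-transcript versus phenotype
#' heatmaps. Expression is log1p-transformed by default (supply normalized
#' values); the coefficient type and transform are recorded as attributes.
#' Zero-variance features yield `NA` coefficients and are flagged rather
#' than erroring.
#'
#' @param expr gene x sample matrix of normalized expression.
#' @param fractions sample x cell-type matrix (or `proportion_estimate`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param transform `"log1p"` (default) or `"none"` applied to `expr`.
#' @return gene x cell-type correlation matrix with attributes `method`,
#'   `transform` and `undefined` (data.frame of zero-variance features).
#' @export
correlate_features <- function(expr, fractions,
                               method = c("pearson", "spearman"),
                               transform = c("log1p", "none")) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  if (inherits(fractions, "proportion_estimate"))
    fractions <- fractions$fractions
  expr <- as.matrix(expr)
  fractions <- as.matrix(fractions)
  shared <- intersect(colnames(expr), rownames(fractions))
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  E <- expr[, shared, drop = FALSE]
  if (transform == "log1p") E <- log1p(E)
  F_ <- fractions[shared, , drop = FALSE]
  flat_genes <- rownames(E)[apply(E, 1L, stats::sd) == 0]
  flat_types <- colnames(F_)[apply(F_, 2L, stats::sd) == 0]
  cc <- suppressWarnings(stats::cor(t(E), F_, method = method))
  undefined <- rbind(
    if (length(flat_genes)) data.frame(feature = flat_genes, kind = "gene"),
    if (length(flat_types)) data.frame(feature = flat_types,
                                       kind = "cell_type"))
  if (is.null(undefined))
    undefined <- data.frame(feature = character(), kind = character())
  structure(cc, method = method, transform = transform,
            undefined = undefined)
}
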