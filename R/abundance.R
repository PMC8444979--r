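#' Settings for the Bayesian NB abundance model
#'
#' @param prior_sd standard deviation (log scale) of the gene-level
#'   log-normal prior shared across cell types. Large values make the prior
#'   weakly informative; pairs with no observed replicates inherit an
#'   interval of roughly `exp(+-1.96 * prior_sd)` around the gene-level mean.
#' @param grid_points number of grid points for the 1-D posterior
#'   integration over log expected abundance.
#' @param dispersion optional fixed NB dispersion (scalar or per-gene
#'   vector); when `NULL` gene-wise dispersions are estimated from the data
#'   (edgeR tagwise estimates).
#' @param pseudo_cpm pseudo-abundance (CPM) added when centring the
#'   gene-level prior, so all-zero genes keep a finite prior.
#' @param ci_level credible-interval mass (default 0.95, reported as the
#'   2.5/97.5% posterior quantiles).
#' @return A list of class `abundance_config`.
#' @export
abundance_config <- function(prior_sd = 2, grid_points = 257L,
                             dispersion = NULL, pseudo_cpm = 0.1,
                             ci_level = 0.95) {
  stopifnot(prior_sd > 0, grid_points >= 51L, pseudo_cpm > 0,
            ci_level > 0, ci_level < 1)
  structure(list(prior_sd = prior_sd, grid_points = as.integer(grid_points),
                 dispersion = dispersion, pseudo_cpm = pseudo_cpm,
                 ci_level = ci_level),
            class = "abundance_config")
}

#' Fit the Bayesian negative-binomial abundance model
#'
#' Infers, for every (cell type, gene) pair, the posterior distribution of
#' the expected transcript abundance on a common TMM-scaled
#' counts-per-million scale. The likelihood is negative binomial
#' (Var = mu + phi mu^2) with per-replicate exposures (effective library
#' size); the prior on log abundance is a gene-level normal centred on the
#' gene's overall mean across all replicates and shared across cell types,
#' which is what lets the model produce a (prior-dominated, wide) posterior
#' for pairs with no observed replicates. The 1-D posterior per pair is
#' integrated exactly on an adaptive grid in log abundance; reported
#' intervals are posterior quantiles, `post_mean` is the posterior mean.
#'
#' `NA` counts are treated as unobserved and simply drop out of the
#' likelihood, so incomplete reference collections (a gene measured for only
#' some cell types) are fitted without imputation.
#'
#' @param ref a `reference_set`, or a gene x replicate count matrix.
#' @param config an [abundance_config()].
#' @param labels replicate -> cell type labels; required when `ref` is a bare
#'   matrix, ignored otherwise.
#' @return A data.frame of class `posterior_summary` with columns
#'   `cell_type`, `gene`, `post_mean`, `ci_low`, `ci_high`, `n_obs`, and
#'   attributes `cell_types` (column order for downstream signature
#'   assembly) and `genes`.
#' @export
fit_abundance_model <- function(ref, config = abundance_config(),
                                labels = NULL) {
  if (inherits(ref, "reference_set")) {
    counts <- ref$counts
    if (is.null(labels)) labels <- ref$labels
  } else {
    counts <- as.matrix(ref)
    if (is.null(labels)) stop("labels required when ref is a matrix")
  }
  stopifnot(inherits(config, "abundance_config"))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  labels <- labels[colnames(counts)]
  if (anyNA(labels)) stop("every replicate column needs a cell-type label")
  validate_counts(counts)

  lib <- colSums(counts, na.rm = TRUE)
  nf <- tmm_factors(counts)
  exposure <- lib * nf / 1e6   # mu is on the TMM-scaled CPM scale
  phi <- resolve_dispersion(counts, labels, nf, config)

  cpm <- sweep(counts, 2L, exposure, "/")
  prior_mean <- log(rowMeans(cpm, na.rm = TRUE) + config$pseudo_cpm)
  prior_mean[is.na(prior_mean)] <- log(config$pseudo_cpm)

  types <- unique(labels)
  out <- vector("list", length(types))
  alpha <- (1 - config$ci_level) / 2
  for (k in seq_along(types)) {
    out[[k]] <- fit_one_type(counts[, labels == types[k], drop = FALSE],
                             exposure[labels == types[k]], phi, prior_mean,
                             config, types[k], alpha)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("posterior_summary", "data.frame"),
            cell_types = types, genes = rownames(counts))
}

validate_counts <- function(counts) {
  v <- counts[!is.na(counts)]
  if (any(v < 0)) stop("counts must be non-negative")
  if (any(abs(v - round(v)) > 1e-8))
    stop("counts must be integers (raw counts, not normalized expression)")
  invisible(TRUE)
}

resolve_dispersion <- function(counts, labels, norm_factors, config,
                               default = 0.1) {
  if (!is.null(config$dispersion)) {
    phi <- rep_len(config$dispersion, nrow(counts))
    return(pmax(phi, 1e-4))
  }
  phi <- rep(default, nrow(counts))
  complete <- rowSums(is.na(counts)) == 0L
  if (sum(complete) >= 2L) {
    est <- tryCatch({
      y <- edgeR::DGEList(counts = counts[complete, , drop = FALSE])
      y$samples$norm.factors <- norm_factors
      design <- stats::model.matrix(~ 0 + factor(labels))
      y <- edgeR::estimateDisp(y, design)
      list(tag = y$tagwise.dispersion, common = y$common.dispersion)
    }, error = function(e) NULL)
    if (is.null(est)) {
      warning("gene-wise dispersion estimation failed; using default ",
              default)
    } else {
      phi[complete] <- est$tag
      if (any(!complete) && is.finite(est$common)) phi[!complete] <- est$common
    }
  }
  pmax(phi, 1e-4)
}

# Grid posterior for all genes of one cell type. Vectorized over genes:
# each gene gets its own grid in log-mu, centred on the (pseudo-counted)
# normalized mean with a width of ~8 posterior SDs, or on the prior when the
# pair has no observations.
fit_one_type <- function(Y, E, phi, prior_mean, config, type, alpha) {
  G <- nrow(Y); M <- config$grid_points
  obs <- !is.na(Y)
  n_obs <- rowSums(obs)
  ysum <- rowSums(Y, na.rm = TRUE)
  esum <- as.vector(obs %*% E)
  mu_hat <- (ysum + 0.25) / ifelse(esum > 0, esum, 1)
  sd_hat <- sqrt(phi / pmax(n_obs, 1) + 1 / (ysum + 0.5))
  centre <- ifelse(n_obs > 0, log(mu_hat), prior_mean)
  half <- ifelse(n_obs > 0, pmin(8 * sd_hat + 0.5, 25), 4.5 * config$prior_sd)

  step_grid <- seq(-1, 1, length.out = M)
  grid <- centre + outer(half, step_grid)          # G x M, log scale
  ll <- stats::dnorm(grid, mean = prior_mean, sd = config$prior_sd,
                     log = TRUE)
  mu_grid <- exp(grid)
  for (j in seq_len(ncol(Y))) {
    yj <- Y[, j]
    lj <- stats::dnbinom(yj, size = 1 / phi, mu = mu_grid * E[j], log = TRUE)
    lj[is.na(yj), ] <- 0
    ll <- ll + lj
  }
  w <- exp(ll - apply(ll, 1L, max))
  wsum <- rowSums(w)
  post_mean <- rowSums(w * mu_grid) / wsum

  qs <- vapply(seq_len(G), function(i) {
    cdf <- cumsum(w[i, ]) / wsum[i]
    c(stats::approx(cdf, grid[i, ], xout = alpha, rule = 2,
                    ties = "ordered")$y,
      stats::approx(cdf, grid[i, ], xout = 1 - alpha, rule = 2,
                    ties = "ordered")$y)
  }, numeric(2))

  data.frame(cell_type = type, gene = rownames(Y), post_mean = post_mean,
             ci_low = exp(qs[1, ]), ci_high = exp(qs[2, ]), n_obs = n_obs,
             stringsAsFactors = FALSE)
}

#' Fit node-level posteriors at every hierarchy level
#'
#' For marker selection, internal nodes of the hierarchy (broad categories
#' such as "immune") are treated as cell types in their own right: the
#' replicates of all leaves under a node are pooled and the abundance model
#' is refitted with node-level labels. Level `l` keeps only replicates whose
#' leaf sits at depth >= `l` (a level-1 leaf has no level-2 ancestor and is
#' not compared there).
#'
#' @param ref a `reference_set`.
#' @param hierarchy a `cell_hierarchy`; defaults to the one stored in `ref`.
#' @param config an [abundance_config()].
#' @return Named list (level -> `posterior_summary`).
#' @export
fit_level_posteriors <- function(ref, hierarchy = NULL,
                                 config = abundance_config()) {
  stopifnot(inherits(ref, "reference_set"))
  if (is.null(hierarchy)) hierarchy <- ref$hierarchy
  depth <- hierarchy_depth(hierarchy)
  out <- vector("list", depth)
  names(out) <- as.character(seq_len(depth))
  for (lev in seq_len(depth)) {
    anc <- vapply(ref$labels, ancestor_at, character(1),
                  hierarchy = hierarchy, level = lev)
    keep <- !is.na(anc)
    if (!any(keep)) next
    out[[as.character(lev)]] <- fit_abundance_model(
      ref$counts[, keep, drop = FALSE], config = config,
      labels = anc[keep])
  }
  out
}

#' Credible-interval separation between two cell types
#'
#' For entries of a posterior summary matched by gene, returns
#' `ci_low(a) - ci_high(b)`: the distance between a's lower and b's upper
#' 95% credible bound. The gap is positive exactly when a's expected
#' abundance credibly exceeds b's (the intervals are disjoint with a above
#' b).
#'
#' @param a,b rows of a `posterior_summary` (data.frames with columns
#'   `gene`, `ci_low`, `ci_high`) for the same gene set and two cell types.
#' @return Named numeric vector of gaps (one per gene).
#' @export
credible_gap <- function(a, b) {
  need <- c("gene", "ci_low", "ci_high")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  if (nrow(a) != nrow(b) || !setequal(a$gene, b$gene) ||
      anyDuplicated(a$gene) || anyDuplicated(b$gene))
    stop("credible_gap: mismatched gene sets")
  b <- b[match(a$gene, b$gene), ]
  stats::setNames(a$ci_low - b$ci_high, a$gene)
}

#' @rdname sigdecon-io
#' @export
write_posterior_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname sigdecon-io
#' @export
read_posterior_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(df, class = c("posterior_summary", "data.frame"),
            cell_types = unique(df$cell_type), genes = unique(df$gene))
}
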