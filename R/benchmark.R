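#' Sample survival times from a clinical pool
#'
#' Draws `n` progression-free survival times from an existing clinical
#' table, emulating sampling from a real cohort's clinical annotation.
#'
#' @param clinical_pool data.frame with a `time` column (non-empty).
#' @param n number of draws.
#' @param replace sample with replacement (default); without replacement
#'   `n` must not exceed the pool size.
#' @param seed optional integer seed.
#' @return Numeric vector of `n` times.
#' @export
sample_survival <- function(clinical_pool, n, replace = TRUE, seed = NULL) {
  if (is.null(clinical_pool) || !nrow(clinical_pool))
    stop("empty clinical pool")
  if (!is.null(seed)) set.seed(as.integer(seed))
  sample(clinical_pool$time, n, replace = replace)
}

#' Simulate survival-coupled cell-type proportions
#'
#' Dirichlet-distributed proportion vectors whose mean for one chosen cell
#' type follows a linear model in survival time on the logit scale:
#' `logit(m_i[variable]) = logit(intercept) + S * z_i`, with `z_i` the
#' standardized survival time. All other types share the remaining mass
#' equally (slope 0), so at S = 0 every type sits at the common baseline
#' proportion. Each sample's proportions are drawn from
#' `Dirichlet(concentration * m_i)`.
#'
#' @param times survival times (one per sample).
#' @param variable_type the single cell type carrying the slope.
#' @param cell_types all K cell types.
#' @param slope S, the logit-scale effect of standardized survival time.
#' @param intercept baseline proportion, identical for all cell types;
#'   default `1/K`. `intercept * K` may not exceed 1.
#' @param concentration Dirichlet total concentration (precision); larger
#'   values concentrate draws around the mean vector.
#' @param seed optional integer seed.
#' @return N x K matrix of proportions; every row sums to 1.
#' @export
simulate_proportions <- function(times, variable_type, cell_types, slope,
                                 intercept = NULL, concentration = 100,
                                 seed = NULL) {
  K <- length(cell_types)
  stopifnot(K >= 2L, concentration > 0)
  if (!variable_type %in% cell_types)
    stop("variable_type must be one of cell_types")
  if (is.null(intercept)) intercept <- 1 / K
  if (intercept <= 0 || intercept * K > 1 + 1e-12)
    stop("infeasible baseline: intercept * K must not exceed 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(times)
  z <- if (stats::sd(times) > 0) (times - mean(times)) / stats::sd(times)
       else rep(0, n)
  m_var <- stats::plogis(stats::qlogis(intercept) + slope * z)
  props <- matrix(NA_real_, nrow = n, ncol = K,
                  dimnames = list(sprintf("m%04d", seq_len(n)), cell_types))
  vi <- match(variable_type, cell_types)
  for (i in seq_len(n)) {
    m <- rep((1 - m_var[i]) / (K - 1), K)
    m[vi] <- m_var[i]
    g <- stats::rgamma(K, shape = concentration * m, rate = 1)
    while (sum(g) == 0) g <- stats::rgamma(K, shape = concentration * m,
                                           rate = 1)
    props[i, ] <- g / sum(g)
  }
  props
}

#' Compose in-silico bulk mixtures
#'
#' For each sample, one reference replicate per cell type is drawn uniformly
#' at random, CPM-scaled, and combined according to the sample's proportion
#' vector. Optionally a fixed proportion `P` of a foreign profile (a cell
#' type absent from the signature) is blended in:
#' `mixture = (1 - P) * sum_k prop_k * profile_k + P * foreign`.
#'
#' @param props sample x cell-type proportion matrix (rows on the simplex).
#' @param ref a `reference_set` with >= 1 replicate per cell type in
#'   `props`.
#' @param foreign_profile a `foreign_profile` (or named CPM vector);
#'   required when `P > 0`.
#' @param P foreign-cell proportion in \[0, 1).
#' @param seed optional integer seed (controls replicate draws).
#' @return gene x sample mixture matrix on the CPM scale.
#' @export
compose_mixtures <- function(props, ref, foreign_profile = NULL, P = 0,
                             seed = NULL) {
  stopifnot(inherits(ref, "reference_set"), P >= 0, P < 1)
  props <- as.matrix(props)
  if (any(abs(rowSums(props) - 1) > 1e-6))
    stop("proportion rows must sum to 1")
  types <- colnames(props)
  miss <- types[!types %in% ref$labels]
  if (length(miss))
    stop("cell type(s) without reference replicates: ",
         paste(miss, collapse = ", "))
  if (P > 0 && is.null(foreign_profile))
    stop("foreign_profile required when P > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cpm <- cpm_normalize(ref$counts)
  cpm[is.na(cpm)] <- 0
  reps_by_type <- split(seq_along(ref$labels), ref$labels)
  fg <- if (inherits(foreign_profile, "foreign_profile"))
    foreign_profile$profile else foreign_profile
  if (!is.null(fg)) fg <- fg[rownames(cpm)]

  mix <- matrix(0, nrow = nrow(cpm), ncol = nrow(props),
                dimnames = list(rownames(cpm), rownames(props)))
  for (i in seq_len(nrow(props))) {
    v <- numeric(nrow(cpm))
    for (ty in types) {
      cols <- reps_by_type[[ty]]
      pick <- if (length(cols) == 1L) cols else cols[sample.int(length(cols), 1L)]
      v <- v + props[i, ty] * cpm[, pick]
    }
    if (P > 0) v <- (1 - P) * v + P * fg
    mix[, i] <- v
  }
  mix
}

#' Censor half of the samples
#'
#' A seeded random half (floor(N/2)) of the samples has its survival time
#' halved and its event indicator set to censored; the remaining samples
#' keep their times as observed events.
#'
#' @param times survival times (length >= 2).
#' @param seed optional integer seed.
#' @return data.frame `sample_id`, `time`, `event`.
#' @export
censor_half <- function(times, seed = NULL) {
  n <- length(times)
  if (n < 2L) stop("need >= 2 samples to censor half")
  if (!is.null(seed)) set.seed(as.integer(seed))
  cens <- sample.int(n, n %/% 2L)
  event <- rep(1L, n)
  event[cens] <- 0L
  t_out <- times
  t_out[cens] <- times[cens] / 2
  data.frame(sample_id = sprintf("m%04d", seq_len(n)), time = t_out,
             event = event, stringsAsFactors = FALSE)
}

#' Multiple Cox regression on logit-transformed fractions
#'
#' Fits one Cox proportional-hazards model (Efron ties) of the censored
#' survival time on the logit-transformed fractions of all cell types
#' jointly, and reports the Wald p-value per cell type. The logit offset
#' epsilon is half the smallest nonzero fraction (floor 1e-6).
#' Non-convergence is surfaced per fit via the `flag` column; rank-deficient
#' fits are retried with a small ridge penalty and flagged.
#'
#' @param fractions sample x cell-type matrix (or `proportion_estimate`);
#'   rownames must match `clinical$sample_id`.
#' @param clinical data.frame `sample_id`, `time`, `event` with >= 1 event.
#' @return data.frame `cell_type`, `coef`, `se`, `z`, `p_value`, `flag`.
#' @export
cox_regression <- function(fractions, clinical) {
  if (inherits(fractions, "proportion_estimate"))
    fractions <- fractions$fractions
  fractions <- as.matrix(fractions)
  if (sum(clinical$event) < 1L) stop("no observed events")
  d <- clinical[match(rownames(fractions), clinical$sample_id), ]
  if (anyNA(d$time)) stop("fractions contain samples without clinical data")
  nz <- fractions[fractions > 0]
  eps <- max(1e-6, if (length(nz)) min(nz) / 2 else 1e-6)
  X <- stats::qlogis(pmin(pmax(fractions, 0) + eps, 1 - 1e-9))
  colnames(X) <- colnames(fractions)

  flag <- "ok"
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(survival::Surv(d$time, d$event) ~ X,
                             ties = "efron"),
             error = function(e) NULL),
    warning = function(w) {
      flag <<- "nonconvergence"
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || anyNA(stats::coef(fit))) {
    # collinear covariates: ridge fallback, flagged
    flag <- "ridge"
    fit <- suppressWarnings(
      survival::coxph(survival::Surv(d$time, d$event) ~
                        survival::ridge(X, theta = 0.1), ties = "efron"))
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- co / se
  data.frame(cell_type = colnames(fractions), coef = unname(co),
             se = unname(se), z = unname(z),
             p_value = 2 * stats::pnorm(-abs(unname(z))), flag = flag,
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC from per-run significance against planted truth
#'
#' Pools all (run, cell type) tests, scores each as `1 - p`, labels it
#' positive when the cell type is the run's planted variable type, and
#' sweeps the score threshold to obtain the full ROC curve. The AUC is the
#' rank-based (Mann-Whitney) area, so tied scores are handled by rank
#' averaging.
#'
#' @param p_values run x cell-type matrix of Cox p-values (`NA` treated as
#'   p = 1, i.e. no call).
#' @param truth character vector (one per run) naming each run's variable
#'   cell type.
#' @return An object of class `benchmark_roc`: list with `points`
#'   (data.frame `fpr`, `tpr` from (0,0) to (1,1)), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(p_values, truth) {
  p_values <- as.matrix(p_values)
  if (nrow(p_values) != length(truth))
    stop("one truth label per run required")
  if (!all(truth %in% colnames(p_values)))
    stop("truth labels must be cell types of the p-value matrix")
  p_values[is.na(p_values)] <- 1
  lab <- matrix(FALSE, nrow(p_values), ncol(p_values))
  lab[cbind(seq_along(truth), match(truth, colnames(p_values)))] <- TRUE
  scores <- 1 - as.vector(p_values)
  labels <- as.vector(lab)
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: need both positive and negative labels")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = rev(1 - r$specificities),
                    tpr = rev(r$sensitivities))
  structure(list(points = pts, auc = as.numeric(pROC::auc(r)),
                 n_pos = sum(labels), n_neg = sum(!labels)),
            class = "benchmark_roc")
}

#' @export
print.benchmark_roc <- function(x, ...) {
  cat("benchmark_roc: AUC", signif(x$auc, 4), "over", x$n_pos, "positives /",
      x$n_neg, "negatives\n")
  invisible(x)
}

#' Run the survival-association simulation benchmark
#'
#' For every condition (N samples, slope S, foreign proportion P) the
#' benchmark performs `runs_per_condition` runs, cycling the variable cell
#' type round-robin through the hierarchy leaves. Each run samples survival
#' times from the clinical pool, simulates survival-coupled Dirichlet
#' proportions, composes in-silico mixtures (optionally contaminated with
#' the foreign profile), TMM-normalizes and deconvolves them against the
#' signature, censors half the samples to half their time, fits the multiple
#' Cox regression on logit fractions, and records the per-cell-type
#' p-values. Per condition, the pooled p-values are scored against the
#' planted variable types by ROC/AUC.
#'
#' Seeds: each run's seed is derived from the master seed and the run index
#' only, so conditions are paired (identical draws where the condition does
#' not intervene).
#'
#' @param ref a `reference_set`.
#' @param sig a `signature_matrix` derived from `ref`.
#' @param clinical_pool clinical table supplying survival times.
#' @param conditions data.frame with columns `N`, `S`, `P`.
#' @param foreign_profile `foreign_profile` used when a condition has P > 0.
#' @param runs_per_condition runs per condition (default 63).
#' @param concentration,intercept passed to [simulate_proportions()].
#' @param nu_grid passed to [deconvolve()].
#' @param proportions `"estimated"` (deconvolution, default) or `"oracle"`
#'   (the true simulated proportions bypass deconvolution, bounding the
#'   information loss of estimation).
#' @param seed master integer seed.
#' @return An object of class `benchmark_result`: list with `summary`
#'   (data.frame `N`, `S`, `P`, `auc`, `n_runs`, `seed`), `rocs` (list of
#'   `benchmark_roc` per condition) and `runs` (per-run records with the
#'   run seed, variable type and p-values).
#' @export
run_benchmark <- function(ref, sig, clinical_pool, conditions,
                          foreign_profile = NULL, runs_per_condition = 63L,
                          concentration = 100, intercept = NULL,
                          nu_grid = c(0.25, 0.5, 0.75),
                          proportions = c("estimated", "oracle"), seed = 1L) {
  proportions <- match.arg(proportions)
  stopifnot(inherits(ref, "reference_set"),
            all(c("N", "S", "P") %in% names(conditions)),
            runs_per_condition >= 1L)
  leaves <- hierarchy_leaves(ref$hierarchy)
  run_seeds <- (as.integer(seed) * 7919L +
                  seq_len(runs_per_condition) * 104729L) %% 2147483629L
  summary_df <- conditions[, c("N", "S", "P")]
  summary_df$auc <- NA_real_
  summary_df$n_runs <- as.integer(runs_per_condition)
  summary_df$seed <- as.integer(seed)
  rocs <- vector("list", nrow(conditions))
  all_runs <- vector("list", nrow(conditions))

  for (ci in seq_len(nrow(conditions))) {
    N <- conditions$N[ci]; S <- conditions$S[ci]; P <- conditions$P[ci]
    pmat <- matrix(NA_real_, nrow = runs_per_condition, ncol = length(leaves),
                   dimnames = list(NULL, leaves))
    truth <- character(runs_per_condition)
    for (r in seq_len(runs_per_condition)) {
      vt <- leaves[(r - 1L) %% length(leaves) + 1L]
      truth[r] <- vt
      set.seed(run_seeds[r])
      times <- sample_survival(clinical_pool, N)
      props <- simulate_proportions(times, vt, leaves, slope = S,
                                    intercept = intercept,
                                    concentration = concentration)
      if (proportions == "estimated") {
        mix <- compose_mixtures(props, ref, foreign_profile, P)
        mix <- cpm_normalize(mix, tmm_factors(mix))
        est <- deconvolve(mix, sig, nu_grid = nu_grid,
                          input_scale = "normalized")
        frac <- est$fractions
        rownames(frac) <- rownames(props)
      } else {
        frac <- props
      }
      clin <- censor_half(times)
      rownames(frac) <- clin$sample_id
      cox <- cox_regression(frac, clin)
      pmat[r, cox$cell_type] <- cox$p_value
    }
    roc <- roc_auc(pmat, truth)
    rocs[[ci]] <- roc
    summary_df$auc[ci] <- roc$auc
    all_runs[[ci]] <- list(condition = conditions[ci, ],
                           run_seeds = run_seeds, truth = truth,
                           p_values = pmat)
  }
  structure(list(summary = summary_df, rocs = rocs, runs = all_runs),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result over", nrow(x$summary), "condition(s):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
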