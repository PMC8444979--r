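#' Generative settings for a synthetic reference
#'
#' Parameters of the negative-binomial generator used to build synthetic
#' reference transcriptomes with planted marker genes. Counts for gene g in a
#' replicate of cell type t are drawn NB with mean `mu[t, g] * L` and
#' dispersion `phi` (Var = mu + phi * mu^2, the edgeR convention), where `L`
#' is a per-replicate library-size factor drawn log-uniformly over
#' `library_size_range`. Each leaf type owns `n_marker_per_type` disjoint
#' marker genes whose mean is `baseline_mean * fold_change` in that type and
#' `baseline_mean` everywhere else; all remaining genes sit at baseline in
#' every type.
#'
#' @param n_genes total number of genes.
#' @param n_marker_per_type planted markers per leaf cell type.
#' @param baseline_mean expected counts of a non-marker gene at library
#'   factor 1.
#' @param fold_change marker elevation over baseline (> 1).
#' @param dispersion NB dispersion phi (> 0).
#' @param library_size_range range of per-replicate library-size factors
#'   (log-uniform draw).
#' @param replicates_per_type biological replicates per leaf type.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return A list of class `generative_spec`.
#' @export
generative_spec <- function(n_genes = 200L, n_marker_per_type = 10L,
                            baseline_mean = 100, fold_change = 8,
                            dispersion = 0.1,
                            library_size_range = c(0.5, 2),
                            replicates_per_type = 10L, seed = 1L) {
  stopifnot(n_genes >= 1, n_marker_per_type >= 1, baseline_mean > 0,
            fold_change >= 1, dispersion > 0, replicates_per_type >= 1,
            length(library_size_range) == 2L, all(library_size_range > 0))
  structure(list(n_genes = as.integer(n_genes),
                 n_marker_per_type = as.integer(n_marker_per_type),
                 baseline_mean = baseline_mean, fold_change = fold_change,
                 dispersion = dispersion,
                 library_size_range = sort(library_size_range),
                 replicates_per_type = as.integer(replicates_per_type),
                 seed = as.integer(seed)),
            class = "generative_spec")
}

# Expected mean matrix (leaf x gene) implied by a spec + hierarchy: planted
# markers are assigned blockwise in gene order, leaf by leaf.
planted_mean_matrix <- function(spec, leaves, genes) {
  mu <- matrix(spec$baseline_mean, nrow = length(leaves), ncol = length(genes),
               dimnames = list(leaves, genes))
  for (k in seq_along(leaves)) {
    idx <- ((k - 1L) * spec$n_marker_per_type + 1L):(k * spec$n_marker_per_type)
    mu[k, idx] <- spec$baseline_mean * spec$fold_change
  }
  mu
}

#' Generate a synthetic reference transcriptome collection
#'
#' Draws an NB count matrix (genes x replicates) for every leaf of the
#' hierarchy, with planted cell-type marker genes and per-replicate
#' library-size factors. Optionally drops a fraction of (cell type, gene)
#' cells to `NA` to emulate incomplete reference collections in which a gene
#' was not measured for some cell types.
#'
#' @param spec a [generative_spec()].
#' @param hierarchy a [cell_hierarchy()] with at least 2 leaves.
#' @param missing_frac fraction of (leaf, gene) cells whose counts are
#'   dropped to `NA` in all replicates of that leaf (default 0).
#' @return An object of class `reference_set`: list with `counts` (gene x
#'   replicate integer matrix, possibly with `NA`s), `labels` (named
#'   character vector, replicate -> leaf type), `hierarchy`,
#'   `planted_markers` (data.frame gene/cell_type), `true_mean` (leaf x gene
#'   NB means at library factor 1), `true_cpm` (leaf x gene expected
#'   counts-per-million), `library_factors`, and `spec`.
#' @export
generate_reference <- function(spec, hierarchy, missing_frac = 0) {
  stopifnot(inherits(spec, "generative_spec"),
            inherits(hierarchy, "cell_hierarchy"),
            missing_frac >= 0, missing_frac < 1)
  leaves <- hierarchy_leaves(hierarchy)
  if (length(leaves) < 2L) stop("hierarchy must have at least 2 leaves")
  need <- length(leaves) * spec$n_marker_per_type
  if (spec$n_genes < need)
    stop("n_genes (", spec$n_genes, ") < n_leaves * n_marker_per_type (",
         need, ")")
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  mu <- planted_mean_matrix(spec, leaves, genes)

  set.seed(spec$seed)
  n_rep <- spec$replicates_per_type
  reps <- paste0(rep(leaves, each = n_rep), "_r",
                 rep(seq_len(n_rep), times = length(leaves)))
  labels <- stats::setNames(rep(leaves, each = n_rep), reps)
  lr <- log(spec$library_size_range)
  libfac <- exp(stats::runif(length(reps), lr[1], lr[2]))
  names(libfac) <- reps

  counts <- matrix(0L, nrow = spec$n_genes, ncol = length(reps),
                   dimnames = list(genes, reps))
  for (j in seq_along(reps)) {
    m <- mu[labels[j], ] * libfac[j]
    counts[, j] <- stats::rnbinom(spec$n_genes, size = 1 / spec$dispersion,
                                  mu = m)
  }

  if (missing_frac > 0) {
    cells <- expand.grid(leaf = leaves, gene = genes,
                         stringsAsFactors = FALSE)
    drop <- cells[stats::runif(nrow(cells)) < missing_frac, , drop = FALSE]
    for (i in seq_len(nrow(drop)))
      counts[drop$gene[i], names(labels)[labels == drop$leaf[i]]] <- NA_integer_
  }

  planted <- data.frame(
    gene = genes[seq_len(need)],
    cell_type = rep(leaves, each = spec$n_marker_per_type),
    stringsAsFactors = FALSE)
  true_cpm <- mu / rowSums(mu) * 1e6
  structure(list(counts = counts, labels = labels, hierarchy = hierarchy,
                 planted_markers = planted, true_mean = mu,
                 true_cpm = true_cpm, library_factors = libfac, spec = spec),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat("reference_set:", nrow(x$counts), "genes x", ncol(x$counts),
      "replicates;", length(unique(x$labels)), "cell types\n")
  invisible(x)
}

#' Generate a synthetic clinical table
#'
#' Draws progression-free survival times from a Weibull distribution
#' (`shape = 1` gives the exponential default) with an independent Bernoulli
#' event indicator, emulating the clinical annotation of a tumor cohort.
#'
#' @param n number of patients (> 0).
#' @param event_rate probability that progression/death is observed
#'   (0 < rate <= 1).
#' @param scale Weibull scale in days.
#' @param shape Weibull shape (1 = exponential).
#' @param seed integer seed.
#' @return data.frame with columns `sample_id`, `time` (days), `event`
#'   (1 = observed, 0 = censored).
#' @export
generate_clinical <- function(n, event_rate = 0.6, scale = 1000, shape = 1,
                              seed = 1L) {
  if (n < 1) stop("cannot generate an empty clinical table (n = 0)")
  stopifnot(event_rate > 0, event_rate <= 1, scale > 0, shape > 0)
  set.seed(as.integer(seed))
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             time = stats::rweibull(n, shape = shape, scale = scale),
             event = stats::rbinom(n, 1L, event_rate),
             stringsAsFactors = FALSE)
}

#' Generate a foreign (out-of-reference) expression profile
#'
#' Builds the expression profile of a cell type absent from the hierarchy
#' (e.g. neural cells contaminating a tumor mixture). The profile carries its
#' own planted markers, drawn from genes that are markers of no leaf type, so
#' it overlaps no leaf signature by construction. Counts are NB-sampled and
#' returned on the counts-per-million scale.
#'
#' @param spec a [generative_spec()]; `n_genes` must leave room for one more
#'   marker block beyond the hierarchy leaves.
#' @param hierarchy the [cell_hierarchy()] whose leaves the foreign type must
#'   avoid.
#' @param cell_type name of the foreign type; must not be a hierarchy leaf.
#' @param seed integer seed (defaults to `spec$seed + 1`).
#' @return A list of class `foreign_profile`: `cell_type`, `profile` (named
#'   CPM vector over the spec's genes), `markers` (its planted marker genes).
#' @export
generate_foreign_profile <- function(spec, hierarchy, cell_type = "neural",
                                     seed = NULL) {
  stopifnot(inherits(spec, "generative_spec"),
            inherits(hierarchy, "cell_hierarchy"))
  leaves <- hierarchy_leaves(hierarchy)
  if (cell_type %in% leaves)
    stop("foreign cell type must not be a hierarchy leaf: ", cell_type)
  need <- (length(leaves) + 1L) * spec$n_marker_per_type
  if (spec$n_genes < need)
    stop("n_genes too small to plant disjoint foreign markers (need ",
         need, ")")
  genes <- sprintf("g%04d", seq_len(spec$n_genes))
  idx <- (length(leaves) * spec$n_marker_per_type + 1L):need
  mu <- rep(spec$baseline_mean, spec$n_genes)
  mu[idx] <- spec$baseline_mean * spec$fold_change
  set.seed(as.integer(if (is.null(seed)) spec$seed + 1L else seed))
  y <- stats::rnbinom(spec$n_genes, size = 1 / spec$dispersion, mu = mu)
  prof <- y / sum(y) * 1e6
  names(prof) <- genes
  structure(list(cell_type = cell_type, profile = prof, markers = genes[idx]),
            class = "foreign_profile")
}

# ---- plain-text I/O -------------------------------------------------------

#' Read and write reference-style TSV files
#'
#' Counts matrices are written genes-as-rows with a leading `gene` column;
#' labels as two columns `replicate`, `cell_type`; clinical tables as
#' `sample_id`, `time`, `event`.
#'
#' @param x matrix or data.frame to write.
#' @param path file path.
#' @name sigdecon-io
#' @return Readers return a matrix (counts) or data.frame; writers return
#'   `path` invisibly.
NULL

#' @rdname sigdecon-io
#' @export
write_counts_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sigdecon-io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname sigdecon-io
#' @export
write_clinical_tsv <- function(x, path) {
  utils::write.table(x[, c("sample_id", "time", "event")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sigdecon-io
#' @export
read_clinical_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
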