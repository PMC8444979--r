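#' PCA of reference replicates restricted to marker genes
#'
#' Sanity check of a marker selection: replicates (optionally restricted to
#' a scope of cell types, e.g. only NK-analog phenotypes) are TMM + CPM
#' normalized, log1p-transformed, gene-centred, and projected on principal
#' components computed from the marker genes only. Component signs are fixed
#' by forcing the largest-magnitude loading of each component positive, so
#' outputs are reproducible across platforms.
#'
#' @param ref a `reference_set`.
#' @param markers a `marker_list` or character vector of genes (>= 2 in the
#'   counts matrix).
#' @param scope optional character vector of leaf cell types to restrict the
#'   replicates to (default: all).
#' @param d number of components to keep.
#' @return An object of class `embedding`: list with `coords` (replicate x
#'   component matrix), `explained_variance` (per kept component, fraction
#'   of total variance, non-increasing) and `labels` (replicate cell
#'   types).
#' @export
pca_markers <- function(ref, markers, scope = NULL, d = 10L) {
  stopifnot(inherits(ref, "reference_set"))
  genes <- if (inherits(markers, "marker_list")) markers$genes else
    as.character(markers)
  keep_rep <- if (is.null(scope)) rep(TRUE, length(ref$labels)) else
    ref$labels %in% scope
  if (sum(keep_rep) < 3L) stop("need >= 3 replicates in scope")
  genes <- intersect(genes, rownames(ref$counts))
  if (length(genes) < 2L) stop("need >= 2 marker genes present in counts")
  counts <- ref$counts[, keep_rep, drop = FALSE]
  counts[is.na(counts)] <- 0
  mat <- log1p(cpm_normalize(counts, tmm_factors(counts)))[genes, ,
                                                           drop = FALSE]
  x <- t(mat)                       # replicates x genes
  x <- scale(x, center = TRUE, scale = FALSE)
  d <- min(d, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = FALSE, rank. = d)
  # reproducible sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  total_var <- sum(apply(x, 2L, stats::var))
  structure(list(coords = pc$x[, seq_len(d), drop = FALSE],
                 explained_variance = (pc$sdev[seq_len(d)]^2) / total_var,
                 labels = ref$labels[keep_rep]),
            class = "embedding")
}

#' Mean silhouette separation of labelled points in an embedding
#'
#' Quantifies how well label classes segregate in an embedding: the mean
#' silhouette coefficient over all replicates (Euclidean distance on the
#' embedding coordinates). Classes with a single member cannot have a
#' silhouette and are excluded with a warning.
#'
#' @param emb an `embedding` (or a coordinate matrix).
#' @param labels per-point labels; defaults to the embedding's own labels.
#' @return Mean silhouette width in \[-1, 1\].
#' @export
separation_score <- function(emb, labels = NULL) {
  coords <- if (inherits(emb, "embedding")) emb$coords else as.matrix(emb)
  if (is.null(labels) && inherits(emb, "embedding")) labels <- emb$labels
  stopifnot(length(labels) == nrow(coords))
  tab <- table(labels)
  if (any(tab == 1L)) {
    warning("excluding singleton class(es): ",
            paste(names(tab)[tab == 1L], collapse = ", "))
    keep <- labels %in% names(tab)[tab > 1L]
    coords <- coords[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  if (length(unique(labels)) < 2L) stop("need >= 2 label classes")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(coords))
  mean(sil[, "sil_width"])
}
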