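#' Marker-selection settings
#'
#' @param k_per_level named list/vector mapping hierarchy level to the number
#'   of top genes kept per ordered cell-type pair. The default keeps the top
#'   5, 10 and 20 genes at levels 1, 2 and 3: broad categories contribute few
#'   but strong markers, fine-grained activation states contribute more.
#' @param min_gap minimum credible-interval separation (on the normalized
#'   abundance scale) for a gene to be eligible; the default 0 demands strict
#'   positivity, i.e. disjoint 95% credible intervals.
#' @return A list of class `marker_config`.
#' @export
marker_config <- function(k_per_level = c("1" = 5L, "2" = 10L, "3" = 20L),
                          min_gap = 0) {
  k <- as.integer(k_per_level)
  names(k) <- names(k_per_level)
  if (is.null(names(k)) || any(!nzchar(names(k))))
    stop("k_per_level must be named by hierarchy level")
  stopifnot(all(k >= 1L), min_gap >= 0)
  structure(list(k_per_level = k, min_gap = min_gap), class = "marker_config")
}

#' Rank genes by credible-interval separation for one ordered pair
#'
#' Genes are ranked by how far cell type `type_a`'s lower 95% credible bound
#' sits above `type_b`'s upper bound. Only genes whose gap exceeds `min_gap`
#' are retained; ties are broken by gene identifier so the ranking is fully
#' deterministic.
#'
#' @param posterior a `posterior_summary` containing both types.
#' @param type_a,type_b cell types compared (a over b).
#' @param min_gap minimum retained gap.
#' @return data.frame `gene`, `gap`, sorted by decreasing gap.
#' @export
pairwise_rank <- function(posterior, type_a, type_b, min_gap = 0) {
  if (!nrow(posterior)) stop("empty posterior summary")
  a <- posterior[posterior$cell_type == type_a, , drop = FALSE]
  b <- posterior[posterior$cell_type == type_b, , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    stop("cell type absent from posterior: ",
         if (!nrow(a)) type_a else type_b)
  gap <- credible_gap(a, b)
  gap <- gap[gap > min_gap]
  if (!length(gap)) return(data.frame(gene = character(), gap = numeric()))
  ord <- order(-gap, names(gap))
  data.frame(gene = names(gap)[ord], gap = unname(gap)[ord],
             stringsAsFactors = FALSE)
}

#' Select marker genes over the cell-type hierarchy
#'
#' At each hierarchy level, every ordered pair of sibling nodes (both
#' directions — permutations, not combinations) is ranked by credible-
#' interval separation and the top `k_per_level[level]` positive-gap genes
#' are kept. The overall marker list is the union of all per-pair
#' selections; a gene selected by several comparisons appears once but keeps
#' the full provenance of every comparison that picked it. A pair with no
#' eligible genes contributes nothing.
#'
#' @param posteriors either a single `posterior_summary` (flat hierarchy) or
#'   a named list level -> `posterior_summary` as produced by
#'   [fit_level_posteriors()]; node-level entries must cover the sibling
#'   nodes compared at that level.
#' @param hierarchy a `cell_hierarchy`.
#' @param cfg a [marker_config()].
#' @return An object of class `marker_list`: list with `genes` (sorted
#'   character vector) and `provenance` (data.frame `gene`, `level`,
#'   `winner`, `loser`, `gap`).
#' @export
select_markers <- function(posteriors, hierarchy, cfg = marker_config()) {
  stopifnot(inherits(hierarchy, "cell_hierarchy"),
            inherits(cfg, "marker_config"))
  if (inherits(posteriors, "posterior_summary"))
    posteriors <- stats::setNames(
      rep(list(posteriors), hierarchy_depth(hierarchy)),
      as.character(seq_len(hierarchy_depth(hierarchy))))
  prov <- list()
  for (lev in seq_len(hierarchy_depth(hierarchy))) {
    key <- as.character(lev)
    if (!key %in% names(cfg$k_per_level)) next
    post <- posteriors[[key]]
    if (is.null(post)) next
    k <- cfg$k_per_level[[key]]
    pairs <- sibling_pairs(hierarchy, lev)
    for (i in seq_len(nrow(pairs))) {
      rk <- pairwise_rank(post, pairs$a[i], pairs$b[i], cfg$min_gap)
      if (!nrow(rk)) next
      top <- utils::head(rk, k)
      prov[[length(prov) + 1L]] <- data.frame(
        gene = top$gene, level = lev, winner = pairs$a[i],
        loser = pairs$b[i], gap = top$gap, stringsAsFactors = FALSE)
    }
  }
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(), level = integer(), winner = character(),
               loser = character(), gap = numeric())
  structure(list(genes = sort(unique(provenance$gene)),
                 provenance = provenance),
            class = "marker_list")
}

#' @export
print.marker_list <- function(x, ...) {
  cat("marker_list:", length(x$genes), "genes from",
      nrow(x$provenance), "pair selections\n")
  invisible(x)
}

#' Assemble the signature matrix
#'
#' Expected normalized abundance (posterior mean) of every marker gene in
#' every leaf cell type — the design matrix for deconvolution. Columns
#' follow the posterior's cell-type order (hierarchy leaf order).
#'
#' @param posterior the leaf-level `posterior_summary`.
#' @param markers a `marker_list` (or character vector of genes).
#' @return A gene x cell-type numeric matrix of class `signature_matrix`.
#' @export
build_signature_matrix <- function(posterior, markers) {
  genes <- if (inherits(markers, "marker_list")) markers$genes else
    as.character(markers)
  types <- attr(posterior, "cell_types")
  if (is.null(types)) types <- unique(posterior$cell_type)
  missing <- setdiff(genes, posterior$gene)
  if (length(missing))
    stop("marker gene(s) absent from posterior: ",
         paste(utils::head(missing, 5), collapse = ", "))
  sig <- matrix(NA_real_, nrow = length(genes), ncol = length(types),
                dimnames = list(genes, types))
  for (ty in types) {
    p <- posterior[posterior$cell_type == ty, , drop = FALSE]
    sig[, ty] <- p$post_mean[match(genes, p$gene)]
  }
  structure(sig, class = c("signature_matrix", "matrix", "array"))
}

#' One-call signature derivation
#'
#' Convenience wrapper: fits level posteriors, selects hierarchical markers
#' and assembles the leaf-level signature matrix.
#'
#' @param ref a `reference_set`.
#' @param cfg a [marker_config()].
#' @param config an [abundance_config()].
#' @return List with `posteriors`, `markers`, `signature`.
#' @export
derive_signature <- function(ref, cfg = marker_config(),
                             config = abundance_config()) {
  posts <- fit_level_posteriors(ref, config = config)
  markers <- select_markers(posts, ref$hierarchy, cfg)
  # leaves can live at any depth, so the signature comes from a dedicated
  # leaf-level fit rather than the deepest level's node fit
  leaf_fit <- fit_abundance_model(ref, config = config)
  list(posteriors = posts, markers = markers,
       signature = build_signature_matrix(leaf_fit, markers))
}

#' @rdname sigdecon-io
#' @export
write_markers_tsv <- function(x, path) {
  utils::write.table(x$provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname sigdecon-io
#' @export
read_markers_tsv <- function(path) {
  prov <- utils::read.delim(path, stringsAsFactors = FALSE)
  structure(list(genes = sort(unique(prov$gene)), provenance = prov),
            class = "marker_list")
}

#' @rdname sigdecon-io
#' @export
write_signature_tsv <- function(x, path) write_counts_tsv(x, path)

#' @rdname sigdecon-io
#' @export
read_signature_tsv <- function(path) {
  m <- read_counts_tsv(path)
  structure(m, class = c("signature_matrix", "matrix", "array"))
}
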