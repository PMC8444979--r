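#' Cell-type hierarchy
#'
#' Builds a validated cell-type hierarchy from a nested named list (as
#' returned by [yaml::read_yaml()] on a nested mapping). Nodes directly under
#' the (implicit) root are level-1 categories; their children are level 2,
#' and so on, up to a maximum depth of 3. Terminal nodes are the leaf cell
#' types, i.e. the deconvolution targets.
#'
#' @param tree named nested list; a leaf is an entry with a `NULL` (or empty)
#'   value, an internal node is an entry whose value is itself a named list.
#' @return An object of class `cell_hierarchy` with components `tree` (the
#'   input), `nodes` (per-node name/parent/depth/children), and `leaves`
#'   (character vector of terminal cell types, in tree order).
#' @examples
#' h <- cell_hierarchy(list(immune = list(nk = NULL, t_cell = NULL),
#'                          stromal = NULL))
#' hierarchy_leaves(h)
#' @export
cell_hierarchy <- function(tree) {
  if (!is.list(tree) || length(tree) == 0L)
    stop("hierarchy must be a non-empty named list")
  nodes <- new.env(parent = emptyenv())
  order_seen <- character()
  walk <- function(sub, parent, depth) {
    if (depth > 3L) stop("hierarchy depth exceeds 3 levels")
    nms <- names(sub)
    if (is.null(nms) || any(!nzchar(nms)))
      stop("every hierarchy node must be named")
    for (nm in nms) {
      if (!is.null(nodes[[nm]])) stop("duplicate node name in hierarchy: ", nm)
      child <- sub[[nm]]
      kids <- if (is.list(child) && length(child)) names(child) else character()
      nodes[[nm]] <- list(name = nm, parent = parent, depth = depth,
                          children = kids)
      order_seen <<- c(order_seen, nm)
      if (length(kids)) walk(child, nm, depth + 1L)
    }
  }
  walk(tree, NA_character_, 1L)
  node_list <- mget(order_seen, envir = nodes)
  leaves <- order_seen[vapply(node_list, function(n) length(n$children) == 0L,
                              logical(1))]
  structure(list(tree = tree, nodes = node_list, leaves = leaves),
            class = "cell_hierarchy")
}

#' Read a cell-type hierarchy from a YAML file
#'
#' @param path path to a YAML file holding a nested mapping of cell types.
#' @return A `cell_hierarchy` object.
#' @export
read_hierarchy <- function(path) cell_hierarchy(yaml::read_yaml(path))

#' @export
print.cell_hierarchy <- function(x, ...) {
  cat("cell_hierarchy:", length(x$nodes), "nodes,",
      length(x$leaves), "leaves, depth", hierarchy_depth(x), "\n")
  invisible(x)
}

#' Leaf cell types of a hierarchy
#' @param hierarchy a `cell_hierarchy`.
#' @return Character vector of terminal cell-type names, in tree order.
#' @export
hierarchy_leaves <- function(hierarchy) {
  stopifnot(inherits(hierarchy, "cell_hierarchy"))
  hierarchy$leaves
}

#' Maximum depth of a hierarchy
#' @param hierarchy a `cell_hierarchy`.
#' @return Integer depth (1 to 3).
#' @export
hierarchy_depth <- function(hierarchy) {
  max(vapply(hierarchy$nodes, `[[`, integer(1), "depth"))
}

#' Depth of a named node
#' @param hierarchy a `cell_hierarchy`.
#' @param name node name.
#' @return Integer level of the node (1 = directly under the root).
#' @export
node_depth <- function(hierarchy, name) {
  n <- hierarchy$nodes[[name]]
  if (is.null(n)) stop("unknown hierarchy node: ", name)
  n$depth
}

#' Leaves descending from a node
#' @param hierarchy a `cell_hierarchy`.
#' @param name node name (a leaf returns itself).
#' @return Character vector of leaf names under `name`.
#' @export
node_leaves <- function(hierarchy, name) {
  n <- hierarchy$nodes[[name]]
  if (is.null(n)) stop("unknown hierarchy node: ", name)
  if (!length(n$children)) return(name)
  unlist(lapply(n$children, node_leaves, hierarchy = hierarchy),
         use.names = FALSE)
}

#' Ancestor of a leaf at a given level
#'
#' Walks up from a leaf to the node occupying the requested level. Returns
#' `NA` when the leaf sits above that level (e.g. a level-1 leaf has no
#' level-2 ancestor).
#'
#' @param hierarchy a `cell_hierarchy`.
#' @param leaf leaf name.
#' @param level target level (1-3).
#' @return Node name, or `NA_character_`.
#' @export
ancestor_at <- function(hierarchy, leaf, level) {
  n <- hierarchy$nodes[[leaf]]
  if (is.null(n)) stop("unknown hierarchy node: ", leaf)
  if (n$depth < level) return(NA_character_)
  while (n$depth > level) n <- hierarchy$nodes[[n$parent]]
  n$name
}

# Ordered pairs of sibling nodes at a level: nodes sharing a parent (or, at
# level 1, sharing the implicit root) are compared against each other in both
# directions. Returns a data.frame with columns a, b.
sibling_pairs <- function(hierarchy, level) {
  depths <- vapply(hierarchy$nodes, `[[`, integer(1), "depth")
  at_level <- names(depths)[depths == level]
  parents <- vapply(hierarchy$nodes[at_level], function(n)
    ifelse(is.na(n$parent), ".root", n$parent), character(1))
  out <- list()
  for (p in unique(parents)) {
    sibs <- at_level[parents == p]
    if (length(sibs) < 2L) next
    grid <- expand.grid(a = sibs, b = sibs, stringsAsFactors = FALSE)
    out[[p]] <- grid[grid$a != grid$b, ]
  }
  if (!length(out)) return(data.frame(a = character(), b = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Packaged example hierarchies
#'
#' `default_hierarchy()` returns the package's default mixed-depth hierarchy
#' (root-level epithelial, endothelial and fibroblast categories next to an
#' immune branch that resolves into myeloid and lymphoid subtypes and, for NK
#' cells, activation states). `benchmark_hierarchy()` returns the balanced
#' depth-3 tree with 8 leaf types used throughout the package's simulation
#' studies, in which every terminal phenotype is compared at level 3.
#'
#' @return A `cell_hierarchy`.
#' @export
default_hierarchy <- function() {
  read_hierarchy(system.file("extdata", "default_hierarchy.yaml",
                             package = "sigdecon", mustWork = TRUE))
}

#' @rdname default_hierarchy
#' @export
benchmark_hierarchy <- function() {
  read_hierarchy(system.file("extdata", "benchmark_hierarchy.yaml",
                             package = "sigdecon", mustWork = TRUE))
}
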