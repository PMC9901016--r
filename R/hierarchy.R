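#' Rooted differentiation hierarchies over population labels
#'
#' A hierarchy is a rooted tree whose *every* node (internal and terminal)
#' is a named cell population. This mirrors how differentiation models are
#' drawn: the stem population sits at the root and each edge is a
#' parent-to-daughter transition, so internal nodes are themselves sorted,
#' measurable populations rather than abstract ancestors.
#'
#' @param edges A data frame with columns `parent` and `child`, one row per
#'   edge. Labels must be unique, the graph must be a single connected
#'   rooted tree (exactly one node without a parent, no cycles).
#' @return An object of class `ssc_hierarchy` with elements `parent`
#'   (named character vector mapping each non-root node to its parent),
#'   `root`, and `nodes` (all labels in a stable order).
#' @examples
#' h <- hierarchy(data.frame(parent = c("A", "A"), child = c("B", "C")))
#' hierarchy_root(h)
#' @export
hierarchy <- function(edges) {
  edges <- as.data.frame(edges)
  if (!all(c("parent", "child") %in% names(edges))) {
    abort("`edges` must have columns `parent` and `child`")
  }
  parent <- as.character(edges$parent)
  child <- as.character(edges$child)
  if (anyDuplicated(child)) {
    abort("each node may have at most one parent (duplicated child label)")
  }
  nodes <- unique(c(parent, child))
  roots <- setdiff(nodes, child)
  if (length(roots) != 1L) {
    abort(sprintf("hierarchy must have exactly one root, found %d (cycle or forest)",
                  length(roots)))
  }
  # walk up from every node; a cycle would loop forever within n steps
  pmap <- setNames(parent, child)
  for (nd in nodes) {
    seen <- character()
    cur <- nd
    while (cur %in% names(pmap)) {
      if (cur %in% seen) abort("hierarchy contains a cycle")
      seen <- c(seen, cur)
      cur <- pmap[[cur]]
    }
    if (cur != roots) abort("hierarchy is not connected")
  }
  structure(
    list(parent = pmap, root = roots, nodes = c(roots, child)),
    class = "ssc_hierarchy"
  )
}

#' @export
print.ssc_hierarchy <- function(x, ...) {
  cat("<ssc_hierarchy> ", length(x$nodes), " populations, root: ", x$root,
      "\n", sep = "")
  cat(write_hierarchy(x), "\n")
  invisible(x)
}

#' @rdname hierarchy
#' @param h An `ssc_hierarchy`.
#' @export
hierarchy_root <- function(h) h$root

#' @rdname hierarchy
#' @export
hierarchy_nodes <- function(h) h$nodes

#' @rdname hierarchy
#' @export
hierarchy_edges <- function(h) {
  tibble::tibble(parent = unname(h$parent), child = names(h$parent))
}

#' Default SSC differentiation hierarchy
#'
#' The transplantation-determined model of skeletal stem cell
#' differentiation: the CD24+CD29+ SSC at the apex gives rise to
#' adipocyte-committed CD24+ SSCs, osteoblast-committed CD29+ SSCs and a
#' CD24-CD29- fraction; the CD29+ branch matures further into CD105+,
#' THY+, 6C3+ and THY+6C3+ derivatives.
#'
#' @return An `ssc_hierarchy` over the eight sorted populations.
#' @export
default_ssc_hierarchy <- function() {
  hierarchy(data.frame(
    parent = c("CD24+CD29+", "CD24+CD29+", "CD24+CD29+",
               "CD29+", "CD29+", "CD29+", "CD29+"),
    child = c("CD24+", "CD24-CD29-", "CD29+",
              "CD105+", "THY+", "6C3+", "THY+6C3+")
  ))
}

children_of <- function(h, node) {
  names(h$parent)[h$parent == node]
}

ancestors_of <- function(h, node) {
  out <- character()
  while (node %in% names(h$parent)) {
    node <- h$parent[[node]]
    out <- c(out, node)
  }
  out
}

# all nodes in the subtree rooted at `node`, including `node`
subtree_of <- function(h, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- names(h$parent)[h$parent %in% frontier]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

node_depths <- function(h) {
  vapply(h$nodes, function(n) length(ancestors_of(h, n)), integer(1))
}

#' Pairwise path distances between populations of a hierarchy
#'
#' Unit-length edges; the distance between two populations is the number of
#' parent-daughter transitions on the path connecting them through the tree.
#'
#' @param h An `ssc_hierarchy`.
#' @return A symmetric numeric matrix with population labels as dimnames.
#' @export
hierarchy_distances <- function(h) {
  g <- igraph::graph_from_data_frame(hierarchy_edges(h), directed = FALSE)
  d <- igraph::distances(g)
  d[h$nodes, h$nodes, drop = FALSE]
}

#' Read and write hierarchies as newick
#'
#' Internal-node populations are written as newick internal node labels, so
#' the file round-trips through standard tree software. Reading accepts any
#' newick string whose internal nodes are all labelled.
#'
#' @param h An `ssc_hierarchy`.
#' @param path File path; for `write_hierarchy`, `NULL` returns the newick
#'   string instead of writing.
#' @return `write_hierarchy`: the newick string, invisibly if written to a
#'   file. `read_hierarchy`: an `ssc_hierarchy`.
#' @export
write_hierarchy <- function(h, path = NULL) {
  build <- function(node) {
    kids <- children_of(h, node)
    if (!length(kids)) return(node)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","),
           ")", node)
  }
  nwk <- paste0(build(h$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' @rdname write_hierarchy
#' @param text Newick string (alternative to `path`).
#' @export
read_hierarchy <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) abort("could not parse newick input")
  ntip <- length(tr$tip.label)
  lab <- c(tr$tip.label, tr$node.label)
  if (length(lab) != ntip + tr$Nnode || any(!nzchar(lab))) {
    abort("every internal node of the newick tree must carry a population label")
  }
  edges <- tibble::tibble(parent = lab[tr$edge[, 1]], child = lab[tr$edge[, 2]])
  hierarchy(edges)
}

#' @export
#' @method as.phylo ssc_hierarchy
as.phylo.ssc_hierarchy <- function(x, ...) {
  ape::read.tree(text = write_hierarchy(x))
}
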