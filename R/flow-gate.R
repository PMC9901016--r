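#' Hierarchical gating trees
#'
#' A gating tree is a rooted set of nested gates applied to transformed
#' marker intensities. Each node restricts its parent's events by one or
#' more threshold conditions: side `"+"` keeps events with
#' `marker >= threshold`, side `"-"` keeps `marker < threshold`, so a
#' quadrant gate's four children partition the parent exactly.
#'
#' @param gates A data frame with columns `node`, `parent`, `marker`,
#'   `side` (`"+"`/`"-"`), `threshold`; multiple rows per node give a
#'   multi-marker (rectangle) gate. Parents must either be `root` or be
#'   defined as nodes themselves.
#' @param root Name of the implicit root holding all events.
#' @return A list of class `gate_tree`.
#' @export
gate_tree <- function(gates, root = "all") {
  gates <- tibble::as_tibble(gates)
  need <- c("node", "parent", "marker", "side", "threshold")
  if (!all(need %in% names(gates))) {
    abort(paste("`gates` must have columns", paste(need, collapse = ", ")))
  }
  if (!all(gates$side %in% c("+", "-"))) abort("`side` must be '+' or '-'")
  if (root %in% gates$node) abort("the root may not itself carry a gate")
  nodes <- unique(gates$node)
  parent <- vapply(nodes, function(nd) {
    p <- unique(gates$parent[gates$node == nd])
    if (length(p) != 1L) abort(sprintf("node '%s' has multiple parents", nd))
    p
  }, character(1))
  if (!all(parent %in% c(root, nodes))) {
    abort("every parent must be the root or a defined node")
  }
  # cycle check: walk each node up to the root
  for (nd in nodes) {
    seen <- character()
    cur <- nd
    while (cur != root) {
      if (cur %in% seen) abort("gating tree contains a cycle")
      seen <- c(seen, cur)
      cur <- parent[[cur]]
    }
  }
  structure(list(gates = gates, root = root, nodes = nodes, parent = parent),
            class = "gate_tree")
}

#' Four-way quadrant gate rows
#'
#' Builds the four children of a 2-D quadrant gate on two markers with
#' shared thresholds; child names follow flow convention, e.g.
#' `"CD24+CD29+"`.
#'
#' @param parent Parent node name.
#' @param markers Length-2 marker names.
#' @param thresholds Length-2 thresholds (transformed scale).
#' @return A gate data frame to pass into [gate_tree()] (eight rows).
#' @export
quadrant_gates <- function(parent, markers, thresholds) {
  stopifnot(length(markers) == 2L, length(thresholds) == 2L)
  sides <- expand.grid(s1 = c("+", "-"), s2 = c("+", "-"),
                       stringsAsFactors = FALSE)
  purrr::map_dfr(seq_len(4), function(i) {
    nm <- paste0(markers[1], sides$s1[i], markers[2], sides$s2[i])
    tibble::tibble(node = nm, parent = parent,
                   marker = markers,
                   side = c(sides$s1[i], sides$s2[i]),
                   threshold = thresholds)
  })
}

#' The default SSC gating tree
#'
#' The standard backbone used to define skeletal stem cells —
#' Lineage- then THY- 6C3-, then CD200+ CD105- (the SSC gate) — followed
#' by the CD24 x CD29 quadrant split of SSCs into the four subsets.
#'
#' @param threshold Positivity threshold on the asinh-transformed scale
#'   applied to every marker (default 1.0, which falls between the
#'   negative and positive modes of [default_flow_model()] at cofactor
#'   150).
#' @return A `gate_tree`.
#' @export
default_ssc_gate_tree <- function(threshold = 1.0) {
  g <- dplyr::bind_rows(
    tibble::tibble(node = "Lin-", parent = "all", marker = "Lin",
                   side = "-", threshold = threshold),
    tibble::tibble(node = "THY-6C3-", parent = "Lin-",
                   marker = c("THY", "6C3"), side = "-",
                   threshold = threshold),
    tibble::tibble(node = "SSC", parent = "THY-6C3-",
                   marker = c("CD200", "CD105"), side = c("+", "-"),
                   threshold = threshold),
    quadrant_gates("SSC", c("CD24", "CD29"), c(threshold, threshold))
  )
  gate_tree(g)
}

#' Apply a gating tree to flow events
#'
#' Membership is fully deterministic: an event belongs to a node iff it
#' belongs to the parent and satisfies every condition of the node's gate.
#' Reports are computed per `sample` when that column is present.
#'
#' @param events Transformed event tibble (see [transform_flow()]).
#' @param tree A `gate_tree`.
#' @return A tibble of class `subset_report`: per (sample,) node the event
#'   `count`, `pct_parent` and `pct_root`. Per-event node membership is
#'   attached as attribute `"membership"` (named list of logical vectors)
#'   and each event's deepest node as attribute `"labels"`.
#' @export
apply_gating_tree <- function(events, tree) {
  stopifnot(inherits(tree, "gate_tree"))
  missing_mk <- setdiff(unique(tree$gates$marker), names(events))
  if (length(missing_mk)) {
    abort(paste0("events are missing gated marker(s): ",
                 paste(missing_mk, collapse = ", ")))
  }
  for (mk in unique(tree$gates$marker)) {
    if (any(!is.finite(events[[mk]]))) {
      abort(sprintf("non-finite intensities in marker '%s'", mk))
    }
  }
  n <- nrow(events)
  membership <- list()
  membership[[tree$root]] <- rep(TRUE, n)
  depth <- c(setNames(0L, tree$root))
  # parents are defined before children in `nodes` only by convention, so
  # resolve order by repeatedly taking nodes whose parent is done
  todo <- tree$nodes
  while (length(todo)) {
    ready <- todo[tree$parent[todo] %in% names(membership)]
    for (nd in ready) {
      g <- tree$gates[tree$gates$node == nd, ]
      inside <- membership[[tree$parent[[nd]]]]
      for (i in seq_len(nrow(g))) {
        x <- events[[g$marker[i]]]
        inside <- inside & if (g$side[i] == "+") x >= g$threshold[i]
                           else x < g$threshold[i]
      }
      membership[[nd]] <- inside
      depth[nd] <- depth[[tree$parent[[nd]]]] + 1L
    }
    todo <- setdiff(todo, ready)
  }
  # deepest node per event
  ord <- names(depth)[order(depth)]
  labels <- rep(tree$root, n)
  for (nd in ord[-1]) labels[membership[[nd]]] <- nd

  samples <- if ("sample" %in% names(events)) events$sample else
    rep("sample1", n)
  sample_levels <- unique(samples)
  if (!length(sample_levels)) sample_levels <- "sample1"
  report <- purrr::map_dfr(sample_levels, function(s) {
    sel <- samples == s
    n_root <- sum(sel)
    purrr::map_dfr(c(tree$root, tree$nodes), function(nd) {
      cnt <- sum(membership[[nd]][sel])
      par_cnt <- if (nd == tree$root) cnt else
        sum(membership[[tree$parent[[nd]]]][sel])
      tibble::tibble(
        sample = s, node = nd,
        parent = if (nd == tree$root) NA_character_ else tree$parent[[nd]],
        count = cnt,
        pct_parent = if (nd == tree$root) 100 else
          if (par_cnt > 0) 100 * cnt / par_cnt else NA_real_,
        pct_root = if (n_root > 0) 100 * cnt / n_root else NA_real_
      )
    })
  })
  if (!"sample" %in% names(events)) report$sample <- NULL
  class(report) <- c("subset_report", class(report))
  attr(report, "membership") <- membership
  attr(report, "labels") <- labels
  report
}

#' Per-event terminal gate labels
#'
#' @param report A `subset_report` from [apply_gating_tree()].
#' @return Character vector, one deepest-node label per event.
#' @export
gate_labels <- function(report) attr(report, "labels")

#' Read / write a gating tree as JSON
#'
#' @param tree A `gate_tree`; `path` a file path.
#' @export
write_gate_tree <- function(tree, path) {
  jsonlite::write_json(list(root = tree$root, gates = tree$gates), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gate_tree
#' @param path JSON file written by [write_gate_tree()].
#' @export
read_gate_tree <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gate_tree(x$gates, root = x$root)
}
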