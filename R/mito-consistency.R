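#' Transmission consistency of variants with a candidate hierarchy
#'
#' A variant's presence pattern across populations is *transmission
#' consistent* with a rooted differentiation model when it can be explained
#' by a single origin followed by inheritance down the tree: there is a
#' unique topmost present population, and every present population lies in
#' the subtree rooted there. The score is the fraction of observed (present
#' anywhere) variants that are consistent. Its significance is assessed
#' against a null of `R` random relabelings of the tree's populations,
#' giving an empirical p-value
#' `(1 + #\{null score >= observed\}) / (R + 1)`.
#'
#' @param m A `heteroplasmy_tbl`.
#' @param h An `ssc_hierarchy` covering every population in `m`.
#' @param tau Presence threshold on allele fraction.
#' @param min_depth Minimum depth for presence (default 0: fraction only).
#' @param R Number of random relabelings for the null (default 999).
#' @param seed RNG seed for the relabelings.
#' @return An object of class `consistency_result`: list with `score`,
#'   `verdicts` (per-variant tibble), `null_scores`, `p_value`, and the
#'   settings. [tidy()] returns the verdicts, [glance()] the score and
#'   p-value.
#' @export
hierarchy_consistency <- function(m, h, tau = 0.01, min_depth = 0,
                                  R = 999, seed = 1L) {
  stopifnot(inherits(h, "ssc_hierarchy"))
  if (!(tau > 0 && tau < 1)) abort("`tau` must be in (0, 1)")
  pops <- attr(m, "populations") %||% unique(m$population)
  missing_pops <- setdiff(pops, hierarchy_nodes(h))
  if (length(missing_pops)) {
    abort(paste0("population(s) missing from the hierarchy: ",
                 paste(missing_pops, collapse = ", ")))
  }
  af <- af_matrix(m, "af")
  P <- af >= tau
  if (min_depth > 0) P <- P & af_matrix(m, "depth") >= min_depth
  # order rows by the hierarchy's node order
  nodes <- hierarchy_nodes(h)
  Pm <- matrix(FALSE, length(nodes), ncol(P),
               dimnames = list(nodes, colnames(P)))
  Pm[rownames(P), ] <- P

  d <- node_depths(h)[nodes]
  S <- vapply(nodes, function(nd) nodes %in% subtree_of(h, nd),
              logical(length(nodes)))        # S[j, i]: node j in subtree of i
  S <- t(S)                                  # S[i, j]: j in subtree of i

  verdict <- consistency_verdicts(Pm, d, S, nodes)
  evaluated <- verdict$n_present > 0L
  score <- if (any(evaluated)) {
    mean(verdict$consistent[evaluated])
  } else NA_real_

  null_scores <- with_seed(seed, vapply(seq_len(R), function(i) {
    Pp <- Pm[sample.int(nrow(Pm)), , drop = FALSE]
    v <- consistency_verdicts(Pp, d, S, nodes)
    ev <- v$n_present > 0L
    if (any(ev)) mean(v$consistent[ev]) else NA_real_
  }, numeric(1)))

  p_value <- if (is.na(score)) NA_real_ else {
    (1 + sum(null_scores >= score, na.rm = TRUE)) / (R + 1)
  }
  structure(list(score = score, verdicts = verdict,
                 null_scores = null_scores, p_value = p_value,
                 tau = tau, min_depth = min_depth, R = R, seed = seed,
                 hierarchy = h),
            class = "consistency_result")
}

# vectorised consistency check over the columns of a presence matrix
# P: populations x variants (rows in `nodes` order); d: node depths;
# S[i, j]: node j is in the subtree rooted at node i
consistency_verdicts <- function(P, d, S, nodes) {
  nvar <- ncol(P)
  if (nvar == 0L) {
    return(tibble::tibble(variant = character(), n_present = integer(),
                          top = character(), consistent = logical()))
  }
  dP <- ifelse(P, d, Inf)
  min_d <- apply(dP, 2, min)                     # Inf when nothing present
  at_top <- P & sweep(dP, 2, min_d, "==")
  n_top <- colSums(at_top)
  top_idx <- max.col(t(at_top), ties.method = "first")
  outside <- colSums(P & !t(S[top_idx, , drop = FALSE])) > 0
  n_present <- colSums(P)
  consistent <- n_present > 0L & n_top == 1L & !outside
  tibble::tibble(
    variant = colnames(P) %||% as.character(seq_len(nvar)),
    n_present = as.integer(n_present),
    top = ifelse(n_present > 0L, nodes[top_idx], NA_character_),
    consistent = consistent
  )
}

#' @export
print.consistency_result <- function(x, ...) {
  cat("<consistency_result> score ", format(x$score, digits = 3),
      " over ", sum(x$verdicts$n_present > 0), " observed variants; ",
      "p = ", format(x$p_value, digits = 3),
      " vs ", x$R, " random relabelings\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname hierarchy_consistency
#' @param x A `consistency_result`.
#' @param ... Unused.
#' @method tidy consistency_result
tidy.consistency_result <- function(x, ...) x$verdicts

#' @export
#' @rdname hierarchy_consistency
#' @method glance consistency_result
glance.consistency_result <- function(x, ...) {
  tibble::tibble(
    score = x$score,
    n_observed = sum(x$verdicts$n_present > 0),
    n_consistent = sum(x$verdicts$consistent),
    p_value = x$p_value,
    null_mean = mean(x$null_scores, na.rm = TRUE),
    R = x$R
  )
}

#' Write a consistency report to JSON
#'
#' @param x A `consistency_result`.
#' @param path Output path.
#' @export
write_consistency <- function(x, path) {
  jsonlite::write_json(
    list(score = x$score, p_value = x$p_value, tau = x$tau, R = x$R,
         null_mean = mean(x$null_scores, na.rm = TRUE),
         verdicts = x$verdicts),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
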