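#' Unsupervised hierarchical clustering of populations by heteroplasmy
#'
#' Builds the dendrogram over sorted populations from their variant
#' allele-fraction profiles. The default distance is `1 - Pearson`
#' correlation between square-root-transformed allele-fraction vectors
#' (the square root stabilises the variance of small fractions), with
#' average linkage. If a population has a constant (e.g. all-zero) profile
#' the correlation is undefined for its pairs; those pairs fall back to
#' Euclidean distance, with a warning.
#'
#' @param m A `heteroplasmy_tbl` with at least 2 populations and 1 variant.
#' @param method Linkage passed to [stats::hclust()] (default
#'   `"average"`).
#' @param metric `"pearson_sqrt"` (default) or `"euclidean"`.
#' @return An object of class `pop_dendrogram`: a list with the `hclust`
#'   fit, the input distance matrix `dist`, the `cophenetic` distance
#'   matrix, and the settings used.
#' @export
cluster_populations <- function(m, method = "average",
                                metric = c("pearson_sqrt", "euclidean")) {
  metric <- match.arg(metric)
  X <- sqrt(af_matrix(m, "af"))
  if (nrow(X) < 2L) abort("need at least 2 populations to cluster")
  if (ncol(X) < 1L) abort("need at least 1 variant to cluster")
  if (metric == "euclidean") {
    D <- as.matrix(dist(X))
  } else {
    flat <- apply(X, 1, sd) == 0
    suppressWarnings(R <- cor(t(X)))
    D <- 1 - R
    if (any(flat)) {
      warn(paste0("constant allele-fraction profile for population(s) ",
                  paste(rownames(X)[flat], collapse = ", "),
                  "; falling back to Euclidean distance for their pairs"))
      E <- as.matrix(dist(X))
      bad <- outer(flat, flat, "|")
      D[bad] <- E[bad]
    }
    diag(D) <- 0
  }
  hc <- hclust(as.dist(D), method = method)
  coph <- as.matrix(cophenetic(hc))
  structure(list(hclust = hc, dist = D, cophenetic = coph,
                 method = method, metric = metric),
            class = "pop_dendrogram")
}

#' @export
print.pop_dendrogram <- function(x, ...) {
  cat("<pop_dendrogram> ", length(x$hclust$labels), " populations, ",
      x$metric, " / ", x$method, " linkage\n", sep = "")
  cat(write_dendrogram(x), "\n")
  invisible(x)
}

#' Cophenetic distance matrix of a population dendrogram
#'
#' @param x A `pop_dendrogram`.
#' @return Symmetric matrix of merge heights at which population pairs join.
#' @export
cophenetic_distances <- function(x) {
  stopifnot(inherits(x, "pop_dendrogram"))
  x$cophenetic
}

#' Export a population dendrogram as newick
#'
#' @param x A `pop_dendrogram`.
#' @param path Optional file; `NULL` returns the newick string.
#' @export
write_dendrogram <- function(x, path = NULL) {
  nwk <- ape::write.tree(ape::as.phylo(x$hclust))
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' @export
#' @method as.phylo pop_dendrogram
as.phylo.pop_dendrogram <- function(x, ...) ape::as.phylo(x$hclust)

#' @export
#' @rdname cluster_populations
#' @param x A `pop_dendrogram`.
#' @param ... Unused.
#' @method tidy pop_dendrogram
tidy.pop_dendrogram <- function(x, ...) {
  hc <- x$hclust
  n <- length(hc$labels)
  member_labels <- function(i) {
    if (i < 0) return(hc$labels[-i])
    unlist(lapply(hc$merge[i, ], member_labels))
  }
  tibble::tibble(
    step = seq_len(nrow(hc$merge)),
    height = hc$height,
    members = vapply(seq_len(nrow(hc$merge)), function(i) {
      paste(sort(member_labels(i)), collapse = "|")
    }, character(1))
  )
}

#' @export
#' @rdname cluster_populations
#' @param object A `pop_dendrogram`.
#' @method glance pop_dendrogram
glance.pop_dendrogram <- function(x, ...) {
  tibble::tibble(
    n_populations = length(x$hclust$labels),
    metric = x$metric,
    method = x$method,
    max_height = max(x$hclust$height)
  )
}
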