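#' Nearest-neighbour type composition around a focal cell type
#'
#' For every focal cell (default P1, the CD24+CD29+ SSC) in each ROI, the
#' type of its single nearest other cell (Euclidean centroid distance,
#' ties broken by smallest cell id) is tallied; the likelihood that a
#' given type is the nearest neighbour of a focal cell is the tally
#' divided by the number of focal cells, so the probabilities over
#' neighbour types sum to 1 within each ROI.
#'
#' @param cells A tibble with columns `cell`, `roi`, `x`, `y`, `type`
#'   (e.g. an annotated `cell_tbl`).
#' @param focal_type The focal type (default `"P1"`).
#' @param types Neighbour types to report; defaults to all types present.
#' @return A tibble of class `neighbor_result`: per `(roi, neighbor_type)`
#'   the `count`, `prob` and `n_focal`. ROIs with fewer than 2 cells or no
#'   focal cell appear with `n_focal = 0` and are flagged
#'   (`degenerate = TRUE`).
#' @export
nearest_neighbor_composition <- function(cells, focal_type = "P1",
                                         types = NULL) {
  check_cell_coords(cells)
  if (is.null(types)) types <- sort(unique(cells$type))
  rois <- unique(cells$roi)
  out <- purrr::map_dfr(rois[!is.na(rois)], function(r) {
    cc <- cells[!is.na(cells$roi) & cells$roi == r, ]
    nn_tally(cc, focal_type, types, roi = r)
  })
  class(out) <- c("neighbor_result", class(out))
  out
}

check_cell_coords <- function(cells) {
  need <- c("cell", "roi", "x", "y", "type")
  if (!all(need %in% names(cells))) {
    abort(paste("cell table must have columns", paste(need, collapse = ", ")))
  }
}

# nearest-neighbour index for each cell within one ROI (cells sorted by id,
# so ties resolve to the smallest cell id)
nn_index <- function(cc) {
  D <- as.matrix(dist(cbind(cc$x, cc$y)))
  diag(D) <- Inf
  max.col(-D, ties.method = "first")
}

nn_tally <- function(cc, focal_type, types, roi) {
  cc <- cc[order(cc$cell), ]
  focal <- which(cc$type == focal_type)
  if (nrow(cc) < 2L || !length(focal)) {
    return(tibble::tibble(roi = roi, neighbor_type = types, count = 0L,
                          prob = NA_real_, n_focal = 0L, degenerate = TRUE))
  }
  nn <- nn_index(cc)
  tal <- table(factor(cc$type[nn[focal]], levels = types))
  tibble::tibble(roi = roi, neighbor_type = types,
                 count = as.integer(tal),
                 prob = as.integer(tal) / length(focal),
                 n_focal = length(focal), degenerate = FALSE)
}

#' Pool a nearest-neighbour composition across ROIs
#'
#' @param nr A `neighbor_result`.
#' @return One row per neighbour type with counts summed over ROIs and
#'   probabilities renormalised over all focal cells.
#' @export
pool_neighbors <- function(nr) {
  nr %>%
    dplyr::filter(!.data$degenerate) %>%
    dplyr::group_by(.data$neighbor_type) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::mutate(prob = .data$count / sum(.data$count),
                  n_focal = sum(.data$count))
}

#' Permutation enrichment of nearest-neighbour composition
#'
#' Tests, per ROI and neighbour type, whether the observed
#' nearest-neighbour count around focal cells exceeds what random
#' assignment of the observed type labels to the observed positions would
#' give: positions (and hence the nearest-neighbour graph) stay fixed,
#' type labels are shuffled within the ROI `K` times. Reports
#' `z = (obs - mean_perm) / sd_perm` (undefined and flagged when the
#' permutation sd is 0) and the empirical one-sided p-value
#' `(1 + #\{perm >= obs\}) / (K + 1)`. ROIs whose cells all share one type
#' are degenerate: every permutation is identical, so no z or p is
#' reported.
#'
#' @inheritParams nearest_neighbor_composition
#' @param K Number of permutations (at least 99; default 999).
#' @param seed RNG seed.
#' @return A tibble of class `neighbor_result` with additional columns
#'   `perm_mean`, `perm_sd`, `z`, `p`, `sd_zero` and `degenerate`.
#' @export
permutation_enrichment <- function(cells, focal_type = "P1", K = 999,
                                   seed = 1L, types = NULL) {
  check_cell_coords(cells)
  if (K < 99) abort("`K` must be at least 99")
  if (is.null(types)) types <- sort(unique(cells$type))
  rois <- unique(cells$roi)
  rois <- rois[!is.na(rois)]
  out <- with_seed(seed, purrr::map_dfr(rois, function(r) {
    cc <- cells[!is.na(cells$roi) & cells$roi == r, ]
    obs <- nn_tally(cc, focal_type, types, roi = r)
    if (obs$degenerate[1] || length(unique(cc$type)) < 2L) {
      obs$degenerate <- TRUE
      obs$perm_mean <- NA_real_; obs$perm_sd <- NA_real_
      obs$z <- NA_real_; obs$p <- NA_real_; obs$sd_zero <- NA
      return(obs)
    }
    cc <- cc[order(cc$cell), ]
    nn <- nn_index(cc)
    li <- match(cc$type, types)           # integer labels for fast tallies
    fi <- match(focal_type, types)
    perm_counts <- matrix(0L, K, length(types))
    for (k in seq_len(K)) {
      pl <- li[sample.int(length(li))]
      fc <- which(pl == fi)
      perm_counts[k, ] <- tabulate(pl[nn[fc]], nbins = length(types))
    }
    mu <- colMeans(perm_counts)
    sdv <- apply(perm_counts, 2, sd)
    obs$perm_mean <- mu
    obs$perm_sd <- sdv
    obs$sd_zero <- sdv == 0
    obs$z <- ifelse(sdv > 0, (obs$count - mu) / sdv, NA_real_)
    obs$p <- vapply(seq_along(types), function(j) {
      (1 + sum(perm_counts[, j] >= obs$count[j])) / (K + 1)
    }, numeric(1))
    obs
  }))
  class(out) <- c("neighbor_result", class(out))
  out
}
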