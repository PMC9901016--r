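#' Segment cells by nuclear-seeded watershed
#'
#' Standard pipeline for nucleus-based segmentation of multiplexed tissue
#' images: Gaussian smoothing of the nuclear channel, Otsu (or fixed)
#' thresholding, a distance-transform watershed to split touching nuclei,
#' and a fixed-radius expansion of each nuclear label into the surrounding
#' cytoplasm (nearest-nucleus assignment within `expand_radius`). Fully
#' deterministic.
#'
#' @param image A `marker_image` or width x height x channel array with
#'   channel dimnames.
#' @param nuclear_channel Name of the nuclear channel (default `"DNA"`).
#' @param sigma Gaussian smoothing sd in pixels.
#' @param threshold `"otsu"` or a numeric intensity cutoff.
#' @param watershed_tolerance Minimum object-height separation for the
#'   watershed to split two touching nuclei (maps to the minimum seed
#'   distance: higher merges more).
#' @param expand_radius Cytoplasm expansion radius in pixels.
#' @return An integer width x height label matrix; background is 0. A
#'   blank (constant) nuclear channel yields zero labels.
#' @export
segment_cells <- function(image, nuclear_channel = "DNA", sigma = 2,
                          threshold = "otsu", watershed_tolerance = 0.1,
                          expand_radius = 4) {
  arr <- if (inherits(image, "marker_image")) image$image else image
  if (!nuclear_channel %in% dimnames(arr)[[3]]) {
    abort(sprintf("no channel named '%s' in the image", nuclear_channel))
  }
  nuc <- arr[, , nuclear_channel]
  if (max(nuc) - min(nuc) < 1e-12) {
    return(matrix(0L, nrow(nuc), ncol(nuc)))
  }
  sm <- EBImage::gblur(EBImage::Image(nuc), sigma = sigma)
  thr <- if (identical(threshold, "otsu")) {
    # otsu() expects [0,1]
    rng <- range(sm)
    EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng))) * diff(rng) + rng[1]
  } else threshold
  mask <- sm > thr
  if (!any(mask)) return(matrix(0L, nrow(nuc), ncol(nuc)))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  if (expand_radius > 0) {
    d_bg <- EBImage::distmap(EBImage::Image(labels == 0))
    grow <- labels > 0 | d_bg <= expand_radius
    labels <- EBImage::propagate(
      EBImage::Image(matrix(0, nrow(nuc), ncol(nuc))),
      seeds = labels, mask = grow
    )
  }
  out <- matrix(as.integer(EBImage::imageData(labels)), nrow(nuc), ncol(nuc))
  out
}

#' Quantify segmented cells
#'
#' Per-cell area, centroid and mean intensity of every channel over the
#' (expanded) cell mask.
#'
#' @param image A `marker_image` or width x height x channel array.
#' @param labels Integer label matrix from [segment_cells()]; must match
#'   the image in the first two dimensions.
#' @param rois Optional named list of ROI polygons (see [read_rois()]);
#'   cells are assigned to the first polygon containing their centroid,
#'   `NA` outside all ROIs. Without ROIs every cell gets `roi = "image"`.
#' @return A tibble of class `cell_tbl`: `cell`, `roi`, `x`, `y`, `area`,
#'   one mean-intensity column per channel.
#' @export
quantify_cells <- function(image, labels, rois = NULL) {
  arr <- if (inherits(image, "marker_image")) image$image else image
  if (!identical(dim(arr)[1:2], dim(labels))) {
    abort("label map and image dimensions differ")
  }
  channels <- dimnames(arr)[[3]]
  idx <- which(labels > 0)
  if (!length(idx)) {
    out <- tibble::tibble(cell = integer(), roi = character(),
                          x = numeric(), y = numeric(), area = integer())
    for (ch in channels) out[[ch]] <- numeric()
    class(out) <- c("cell_tbl", class(out))
    return(out)
  }
  lab <- labels[idx]
  W <- dim(labels)[1]
  px <- (idx - 1L) %% W + 1L
  py <- (idx - 1L) %/% W + 1L
  area <- as.vector(table(lab))
  ids <- as.integer(names(table(lab)))
  out <- tibble::tibble(
    cell = ids,
    x = as.vector(rowsum(as.numeric(px), lab)) / area,
    y = as.vector(rowsum(as.numeric(py), lab)) / area,
    area = as.integer(area)
  )
  for (ch in channels) {
    v <- arr[, , ch][idx]
    out[[ch]] <- as.vector(rowsum(v, lab)) / area
  }
  out$roi <- if (is.null(rois)) "image" else assign_rois(out$x, out$y, rois)
  out <- dplyr::select(out, "cell", "roi", dplyr::everything())
  class(out) <- c("cell_tbl", class(out))
  out
}

#' Assign points to ROI polygons
#'
#' @param x,y Point coordinates (pixels).
#' @param rois Named list of polygons, each a 2-column matrix of vertices.
#' @return Character vector of ROI names (first containing polygon wins),
#'   `NA` for points outside every ROI.
#' @export
assign_rois <- function(x, y, rois) {
  out <- rep(NA_character_, length(x))
  pts <- cbind(x, y)
  for (nm in names(rois)) {
    poly <- as.matrix(rois[[nm]])
    inside <- mgcv::in.out(rbind(poly, poly[1, ]), pts)
    out[is.na(out) & inside] <- nm
  }
  out
}

#' Read / write ROI polygons (GeoJSON-style)
#'
#' ROIs are stored as a GeoJSON FeatureCollection of polygons with an
#' `id` property; growth-plate or other excluded regions are simply not
#' listed.
#'
#' @param path JSON file.
#' @return Named list of 2-column vertex matrices.
#' @export
read_rois <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- g$features
  out <- list()
  for (i in seq_len(nrow(feats))) {
    coords <- feats$geometry$coordinates[[i]]
    m <- matrix(unlist(coords), ncol = 2, byrow = FALSE)
    if (is.list(coords)) m <- do.call(rbind, lapply(coords, unlist))
    out[[feats$properties$id[i]]] <- m
  }
  out
}

#' @rdname read_rois
#' @param rois Named list of 2-column vertex matrices.
#' @export
write_rois <- function(rois, path) {
  feats <- lapply(names(rois), function(nm) {
    m <- as.matrix(rois[[nm]])
    list(type = "Feature",
         properties = list(id = nm),
         geometry = list(type = "Polygon",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(i) unname(m[i, ]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
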