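#' Marker gating schemes for cell-type annotation
#'
#' An ordered list of type definitions; each type requires a set of
#' markers above and a set below a per-channel positivity threshold. The
#' first matching type wins; cells matching none are `"unassigned"`.
#' Thresholds can be `"bimodal"` (default: a two-class 1-D split of each
#' channel's per-cell means, the midpoint of the two class centres; if the
#' centres are closer than `min_gap` the channel is called all-negative),
#' `"quantile"` (positive = top `1 - q` fraction of that channel in the
#' image), or `"absolute"` (fixed named thresholds).
#'
#' @param types Ordered list; each element a list with `label`, `above`
#'   (character vector of markers required positive) and `below`
#'   (markers required negative).
#' @param mode `"bimodal"`, `"quantile"` or `"absolute"`.
#' @param q Quantile for `mode = "quantile"` (default 0.75: positive is
#'   the top 25% of the channel).
#' @param thresholds Named numeric vector for `mode = "absolute"`.
#' @param min_gap Minimum distance between the two class centres for a
#'   `"bimodal"` channel to be considered to contain positives.
#' @return A list of class `gating_scheme`.
#' @export
gating_scheme <- function(types, mode = c("bimodal", "quantile", "absolute"),
                          q = 0.75, thresholds = NULL, min_gap = 0.1) {
  mode <- match.arg(mode)
  for (tp in types) {
    if (is.null(tp$label) || (is.null(tp$above) && is.null(tp$below))) {
      abort("each type needs a `label` and at least one `above`/`below` marker")
    }
  }
  if (mode == "absolute" && is.null(thresholds)) {
    abort("`thresholds` must be given for mode = 'absolute'")
  }
  structure(list(types = types, mode = mode, q = q,
                 thresholds = thresholds, min_gap = min_gap),
            class = "gating_scheme")
}

#' Default P1-P11 annotation scheme
#'
#' P1 encodes the CD24+CD29+ SSC: CD24, CD29 and CD200 positive on a
#' Lin- THY- 6C3- CD105- backbone. The remaining types mirror
#' [default_cell_signatures()]; beyond P1 they are a synthetic fixture
#' (the panel fixes only the SSC definition), each requiring its positive
#' markers and the absence of the other types' distinguishing markers.
#'
#' @inheritParams gating_scheme
#' @return A `gating_scheme`.
#' @export
default_gating_scheme <- function(mode = "bimodal", q = 0.75,
                                  thresholds = NULL, min_gap = 0.1) {
  sigs <- default_cell_signatures()
  markers <- names(sigs[[1]])
  types <- lapply(names(sigs), function(lbl) {
    pos <- names(sigs[[lbl]])[sigs[[lbl]] >= 0.5]
    list(label = lbl, above = pos, below = setdiff(markers, pos))
  })
  gating_scheme(types, mode = mode, q = q, thresholds = thresholds,
                min_gap = min_gap)
}

#' Annotate segmented cells with gated types
#'
#' @param cells A `cell_tbl` from [quantify_cells()] (or any tibble with
#'   per-cell mean marker intensities).
#' @param scheme A [gating_scheme()].
#' @return The cell table with a `type` column (first matching type label
#'   or `"unassigned"`). The per-channel thresholds used are attached as
#'   attribute `"thresholds"`.
#' @export
annotate_types <- function(cells, scheme = default_gating_scheme()) {
  stopifnot(inherits(scheme, "gating_scheme"))
  markers <- unique(unlist(lapply(scheme$types, function(tp) {
    c(tp$above, tp$below)
  })))
  missing_mk <- setdiff(markers, names(cells))
  if (length(missing_mk)) {
    abort(paste0("gating scheme references unknown channel(s): ",
                 paste(missing_mk, collapse = ", ")))
  }
  # background reference for unimodal channels: the lower decile of all
  # marker means pooled is background staining in any real panel, since
  # most markers are negative in most cells
  ref <- if (nrow(cells)) {
    quantile(unlist(lapply(markers, function(mk) cells[[mk]])), 0.1,
             names = FALSE)
  } else 0
  thr <- vapply(markers, function(mk) {
    channel_threshold(cells[[mk]], scheme, mk, ref)
  }, numeric(1))
  names(thr) <- markers
  pos <- vapply(markers, function(mk) cells[[mk]] >= thr[[mk]],
                logical(nrow(cells)))
  pos <- matrix(pos, nrow = nrow(cells),
                dimnames = list(NULL, markers))
  type <- rep("unassigned", nrow(cells))
  for (tp in rev(scheme$types)) {    # reversed so earlier types overwrite
    hit <- rep(TRUE, nrow(cells))
    for (mk in tp$above) hit <- hit & pos[, mk]
    for (mk in tp$below) hit <- hit & !pos[, mk]
    type[hit] <- tp$label
  }
  cells$type <- type
  attr(cells, "thresholds") <- thr
  cells
}

channel_threshold <- function(x, scheme, marker, ref = 0) {
  if (scheme$mode == "absolute") {
    if (!marker %in% names(scheme$thresholds)) {
      abort(sprintf("no absolute threshold given for marker '%s'", marker))
    }
    return(scheme$thresholds[[marker]])
  }
  if (!length(x)) return(Inf)
  if (scheme$mode == "quantile") return(quantile(x, scheme$q, names = FALSE))
  # bimodal: deterministic 1-D 2-means seeded at the channel extremes; a
  # unimodal channel (no gap) is all-positive when it sits well above the
  # pooled background reference, otherwise all-negative
  unimodal_cut <- function() if (stats::median(x) > 5 * ref) -Inf else Inf
  if (max(x) - min(x) < scheme$min_gap) return(unimodal_cut())
  km <- suppressWarnings(
    kmeans(x, centers = matrix(range(x), 2, 1), algorithm = "Lloyd",
           iter.max = 100)
  )
  cen <- sort(km$centers[, 1])
  # a genuine positive/negative split must separate the classes by more
  # than their internal spread, else the channel is one continuous mode
  within_sd <- vapply(1:2, function(k) {
    xs <- x[km$cluster == k]
    if (length(xs) > 1) sd(xs) else 0
  }, numeric(1))
  if (diff(cen) < scheme$min_gap ||
      diff(cen) < 0.45 * (max(x) - min(x)) ||
      diff(cen) < 3 * max(within_sd)) {
    return(unimodal_cut())
  }
  mean(cen)
}

#' Read / write a gating scheme as JSON
#'
#' @param scheme A `gating_scheme`; `path` a file path.
#' @export
write_gating_scheme <- function(scheme, path) {
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_gating_scheme
#' @param path JSON file.
#' @export
read_gating_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  types <- lapply(x$types, function(tp) {
    list(label = tp$label, above = unlist(tp$above), below = unlist(tp$below))
  })
  gating_scheme(types, mode = x$mode, q = x$q %||% 0.75,
                thresholds = if (length(x$thresholds))
                  unlist(x$thresholds) else NULL,
                min_gap = x$min_gap %||% 0.1)
}
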