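#' Marker signatures for the gated cell types P1-P11
#'
#' Mean marker intensities (arbitrary units in \[0, 1\]) for each annotated
#' type: positive markers at 1.0, negative at 0.05. P1 is the CD24+CD29+
#' SSC on the Lin- THY- 6C3- CD200+ CD105- backbone; P2-P4 are the other
#' CD24/CD29 subsets; P5-P8 the CD105/THY/6C3 derivatives; P9-P11 are
#' synthetic stand-ins for further marker-defined marrow types (Nestin+,
#' Endomucin+ endothelium, LepR+ CAR cells) since only P1's definition is
#' fixed by the flow panel.
#'
#' @return Named list: type -> named numeric vector of marker means.
#' @export
default_cell_signatures <- function() {
  markers <- c("Lin", "THY", "6C3", "CD200", "CD105", "CD24", "CD29",
               "Nestin", "Endomucin", "LepR", "CD36", "RUNX2")
  sig <- function(positive) {
    setNames(ifelse(markers %in% positive, 1.0, 0.05), markers)
  }
  list(
    P1 = sig(c("CD200", "CD24", "CD29")),
    P2 = sig(c("CD200", "CD24")),
    P3 = sig(c("CD200", "CD29")),
    P4 = sig(c("CD200")),
    P5 = sig(c("CD105")),
    P6 = sig(c("THY")),
    P7 = sig(c("6C3")),
    P8 = sig(c("THY", "6C3")),
    P9 = sig(c("Nestin")),
    P10 = sig(c("Endomucin")),
    P11 = sig(c("LepR", "CD36"))
  )
}

#' Layout configuration for the image simulator
#'
#' @param width,height Image size in pixels.
#' @param cell_counts Named integer vector: cells to place per type
#'   (names must exist in `signatures`).
#' @param signatures Per-type marker means (see
#'   [default_cell_signatures()]).
#' @param attraction Optional spatial attraction: a list with `type` (the
#'   attracted type), `to` (the anchor type, placed first), `strength`
#'   (probability in \[0, 1\] that an attracted cell is placed near an
#'   anchor rather than uniformly) and `sigma` (Gaussian displacement sd,
#'   pixels). `NULL` places every type uniformly at random.
#' @param nucleus_radius Length-2 range of nuclear radii (pixels).
#' @param cell_radius_factor Cytoplasm disk radius as a multiple of the
#'   nuclear radius.
#' @param noise_sd Gaussian channel noise sd added to every pixel.
#' @param min_sep Minimum centre-to-centre separation (pixels); default
#'   `2 * max(nucleus_radius) + 1`, i.e. non-overlapping nuclei.
#' @param max_tries Placement attempts per cell before declaring the
#'   layout infeasible.
#' @return A list of class `image_layout`.
#' @export
image_layout <- function(width = 256, height = 256,
                         cell_counts = c(P1 = 15, P2 = 15, P3 = 15, P4 = 15),
                         signatures = default_cell_signatures(),
                         attraction = NULL,
                         nucleus_radius = c(4, 5),
                         cell_radius_factor = 2.0,
                         noise_sd = 0.05,
                         min_sep = NULL,
                         max_tries = 500L) {
  stopifnot(width >= 8, height >= 8)
  if (length(cell_counts) && (is.null(names(cell_counts)) ||
                              !all(names(cell_counts) %in% names(signatures)))) {
    abort("`cell_counts` names must match `signatures`")
  }
  if (!is.null(attraction)) {
    stopifnot(all(c("type", "to", "strength", "sigma") %in% names(attraction)))
    assert_scalar_number(attraction$strength, "attraction$strength", 0, 1)
    assert_scalar_number(attraction$sigma, "attraction$sigma", lower = 0)
  }
  stopifnot(length(nucleus_radius) == 2L, all(nucleus_radius > 0))
  if (is.null(min_sep)) min_sep <- 2 * max(nucleus_radius) + 6
  structure(list(width = as.integer(width), height = as.integer(height),
                 cell_counts = cell_counts, signatures = signatures,
                 attraction = attraction, nucleus_radius = nucleus_radius,
                 cell_radius_factor = cell_radius_factor,
                 noise_sd = noise_sd, min_sep = min_sep,
                 max_tries = as.integer(max_tries)),
            class = "image_layout")
}

#' Simulate a multi-channel marker image with ground truth
#'
#' Renders a 13-channel image: a nuclear channel (`DNA`, Gaussian blobs at
#' each cell centre) plus 12 marker channels in which each cell
#' contributes its type's signature mean over a cytoplasmic disk, with
#' i.i.d. Gaussian pixel noise on every channel. Cell positions are
#' uniform, optionally with one type attracted toward another (mixture of
#' a Gaussian kernel around a random anchor cell and a uniform draw), and
#' respect a minimum separation.
#'
#' @param layout An [image_layout()].
#' @param seed RNG seed.
#' @return A list of class `marker_image`: `image` (array
#'   width x height x channel, with channel dimnames), `cells` (truth
#'   tibble: `cell`, `x`, `y`, `type`, `nucleus_radius`).
#' @export
simulate_image <- function(layout, seed = 1L) {
  stopifnot(inherits(layout, "image_layout"))
  with_seed(seed, simulate_image_impl(layout))
}

#' Simulate cell positions and types only
#'
#' The placement half of [simulate_image()]: returns the ground-truth cell
#' table (positions, types, nuclear radii) without rendering channels.
#' Useful for calibrating spatial statistics where only the point pattern
#' matters.
#'
#' @inheritParams simulate_image
#' @return A tibble: `cell`, `x`, `y`, `type`, `nucleus_radius`.
#' @export
simulate_cell_positions <- function(layout, seed = 1L) {
  stopifnot(inherits(layout, "image_layout"))
  with_seed(seed, place_cells(layout))
}

place_cells <- function(ly) {
  W <- ly$width; H <- ly$height
  margin <- max(ly$nucleus_radius) * ly$cell_radius_factor + 1
  types <- names(ly$cell_counts)
  att <- ly$attraction
  if (!is.null(att)) {
    # anchors must be placed before the attracted type
    types <- unique(c(setdiff(types, att$type), att$type))
  }
  n_total <- sum(ly$cell_counts)
  xs <- ys <- rads <- numeric(n_total)
  tps <- character(n_total)
  id <- 0L
  for (tp in types) {
    for (k in seq_len(ly$cell_counts[[tp]])) {
      ok <- FALSE
      for (try in seq_len(ly$max_tries)) {
        use_anchor <- !is.null(att) && tp == att$type &&
          runif(1) < att$strength && any(tps[seq_len(id)] == att$to)
        if (use_anchor) {
          anchors <- which(tps[seq_len(id)] == att$to)
          a <- anchors[sample.int(length(anchors), 1L)]
          x <- xs[a] + rnorm(1, 0, att$sigma)
          y <- ys[a] + rnorm(1, 0, att$sigma)
          x <- min(max(x, margin), W - margin)
          y <- min(max(y, margin), H - margin)
        } else {
          x <- runif(1, margin, W - margin)
          y <- runif(1, margin, H - margin)
        }
        if (id == 0L ||
            all((xs[seq_len(id)] - x)^2 + (ys[seq_len(id)] - y)^2 >=
                  ly$min_sep^2)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "could not place %d '%s' cells without overlap (min_sep = %.1f)",
          ly$cell_counts[[tp]], tp, ly$min_sep))
      }
      id <- id + 1L
      xs[id] <- x; ys[id] <- y; tps[id] <- tp
      rads[id] <- runif(1, ly$nucleus_radius[1], ly$nucleus_radius[2])
    }
  }
  tibble::tibble(cell = seq_len(n_total), x = xs, y = ys, type = tps,
                 nucleus_radius = rads)
}

simulate_image_impl <- function(ly) {
  W <- ly$width; H <- ly$height
  placed <- place_cells(ly)
  markers <- names(ly$signatures[[1]])
  channels <- c("DNA", markers)
  img <- array(0, dim = c(W, H, length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (i in seq_len(nrow(placed))) {
    rn <- placed$nucleus_radius[i]
    rc <- rn * ly$cell_radius_factor
    cx <- placed$x[i]; cy <- placed$y[i]
    win <- ceiling(rc) + 2L
    xs <- max(1L, floor(cx) - win):min(W, ceiling(cx) + win)
    ys <- max(1L, floor(cy) - win):min(H, ceiling(cy) + win)
    d2 <- outer((xs - cx)^2, (ys - cy)^2, "+")
    img[xs, ys, "DNA"] <- img[xs, ys, "DNA"] + exp(-d2 / (2 * rn^2))
    disk <- d2 <= rc^2
    sig <- ly$signatures[[placed$type[i]]]
    for (mk in markers) {
      if (sig[[mk]] > 0) {
        patch <- img[xs, ys, mk]
        patch[disk] <- pmax(patch[disk], sig[[mk]])
        img[xs, ys, mk] <- patch
      }
    }
  }
  if (ly$noise_sd > 0) {
    img <- img + array(rnorm(length(img), 0, ly$noise_sd), dim = dim(img))
    img[img < 0] <- 0
    dimnames(img) <- list(NULL, NULL, channels)
  }
  structure(list(image = img, cells = placed, layout = ly),
            class = "marker_image")
}

#' @export
print.marker_image <- function(x, ...) {
  d <- dim(x$image)
  cat("<marker_image> ", d[1], "x", d[2], " px, ", d[3], " channels, ",
      nrow(x$cells), " cells\n", sep = "")
  invisible(x)
}

#' Write / read a multi-channel image as TIFF
#'
#' One TIFF page per channel (32-bit float, values clamped to \[0, 1\]);
#' channel names travel in a small JSON sidecar next to the image
#' (`<path>.channels.json`) so that the stack remains self-describing.
#'
#' @param image A `marker_image` or a width x height x channel array with
#'   channel dimnames.
#' @param path Output `.tiff` path.
#' @export
write_marker_image <- function(image, path) {
  arr <- if (inherits(image, "marker_image")) image$image else image
  channels <- dimnames(arr)[[3]]
  pages <- lapply(seq_len(dim(arr)[3]), function(k) {
    # tiff expects row-major matrices (rows = image rows = y)
    m <- t(arr[, , k])
    m[m < 0] <- 0; m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(channels, paste0(path, ".channels.json"))
  invisible(path)
}

#' @rdname write_marker_image
#' @export
read_marker_image <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- tryCatch(
    unlist(jsonlite::read_json(paste0(path, ".channels.json"))),
    error = function(e) paste0("ch", seq_along(pages))
  )
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)),
               dimnames = list(NULL, NULL, channels))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  arr
}
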