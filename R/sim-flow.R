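#' Simulate flow-cytometry events as log-normal marker mixtures
#'
#' Draws `n_events` cells from a mixture of populations with fixed
#' fractions; each population has a per-marker log-normal intensity model
#' (location and scale on the log scale), mimicking uncompensated
#' cytometer fluorescence. The hidden true population of every event is
#' recorded for recovery tests.
#'
#' @param pop_fractions Named numeric vector of population fractions,
#'   summing to 1 (tolerance 1e-9).
#' @param marker_models Named list (one element per population, names
#'   matching `pop_fractions`); each element is a named list of markers
#'   mapping to `c(meanlog, sdlog)`.
#' @param n_events Number of events to draw.
#' @param seed RNG seed.
#' @return A tibble with one row per event: `event`, one raw intensity
#'   column per marker, and the hidden `true_pop` label. Apply
#'   [transform_flow()] before gating.
#' @examples
#' ev <- simulate_flow_events(c(A = 0.3, B = 0.7),
#'   list(A = list(CD24 = c(log(1200), 0.5)),
#'        B = list(CD24 = c(log(30), 0.5))),
#'   n_events = 100, seed = 1)
#' @export
simulate_flow_events <- function(pop_fractions, marker_models, n_events,
                                 seed = 1L) {
  if (is.null(names(pop_fractions)) || any(!nzchar(names(pop_fractions)))) {
    abort("`pop_fractions` must be a named vector")
  }
  if (abs(sum(pop_fractions) - 1) > 1e-9) {
    abort("`pop_fractions` must sum to 1 (tolerance 1e-9)")
  }
  if (!all(names(pop_fractions) %in% names(marker_models))) {
    abort("`marker_models` must have one entry per population")
  }
  marker_models <- marker_models[names(pop_fractions)]
  markers <- names(marker_models[[1]])
  ok <- vapply(marker_models, function(mm) setequal(names(mm), markers),
               logical(1))
  if (!all(ok)) abort("all populations must model the same marker set")
  assert_scalar_number(n_events, "n_events", lower = 0)

  with_seed(seed, {
    pops <- names(pop_fractions)
    truth <- if (n_events > 0) {
      sample(pops, n_events, replace = TRUE, prob = pop_fractions)
    } else character(0)
    out <- tibble::tibble(event = seq_len(n_events))
    for (mk in markers) {
      x <- numeric(n_events)
      for (p in pops) {
        idx <- which(truth == p)
        prm <- marker_models[[p]][[mk]]
        if (length(idx)) x[idx] <- rlnorm(length(idx), prm[1], prm[2])
      }
      out[[mk]] <- x
    }
    out$true_pop <- truth
    out
  })
}

#' Default marker intensity models for the four CD24/CD29 SSC subsets
#'
#' All four subsets share the SSC backbone (Lin- THY- 6C3- CD200+ CD105-)
#' and differ only in CD24/CD29. Positive markers are log-normal around
#' 1200 intensity units, negative around 30, both with log-scale sd 0.5 —
#' cleanly separated two-decade modes as on a well-compensated cytometer.
#'
#' @return Named list of per-population marker models suitable for
#'   [simulate_flow_events()].
#' @export
default_flow_model <- function() {
  markers <- c("Ter119", "CD45", "CD31", "THY", "6C3", "CD200", "CD105",
               "CD24", "CD29")
  model_for <- function(positive) {
    setNames(lapply(markers, function(mk) {
      if (mk %in% positive) c(log(1200), 0.5) else c(log(30), 0.5)
    }), markers)
  }
  list(
    "CD24+CD29+" = model_for(c("CD200", "CD24", "CD29")),
    "CD24+"      = model_for(c("CD200", "CD24")),
    "CD29+"      = model_for(c("CD200", "CD29")),
    "CD24-CD29-" = model_for(c("CD200"))
  )
}

#' Transform raw flow intensities for gating
#'
#' Applies the standard `asinh(x / cofactor)` transform to every marker
#' column and, when the lineage dump markers are present, adds a `Lin`
#' channel as their per-event maximum (Lineage- means Ter119-, CD45- and
#' CD31-).
#'
#' @param events Event tibble with raw intensities (e.g. from
#'   [simulate_flow_events()] or [read_flow_events()]).
#' @param cofactor asinh cofactor (default 150).
#' @param lin_markers Markers pooled into the `Lin` dump channel.
#' @return The tibble with transformed marker columns and a `Lin` column.
#' @export
transform_flow <- function(events, cofactor = 150,
                           lin_markers = c("Ter119", "CD45", "CD31")) {
  assert_scalar_number(cofactor, "cofactor", lower = 1e-12)
  reserved <- c("event", "sample", "true_pop")
  mk <- setdiff(names(events)[vapply(events, is.numeric, logical(1))],
                c(reserved, "Lin"))
  events <- dplyr::mutate(events,
                          dplyr::across(dplyr::all_of(mk), ~ asinh(.x / cofactor)))
  have_lin <- intersect(lin_markers, names(events))
  if (!"Lin" %in% names(events) && length(have_lin)) {
    events$Lin <- do.call(pmax, events[have_lin])
  }
  events
}

#' Read flow-cytometry events from CSV
#'
#' One row per event with named marker columns of raw intensities; an
#' optional `sample` column keeps multi-sample files apart. The asinh
#' transform and `Lin` dump channel are applied on load via
#' [transform_flow()].
#'
#' @param path CSV file.
#' @inheritParams transform_flow
#' @return A transformed event tibble.
#' @export
read_flow_events <- function(path, cofactor = 150,
                             lin_markers = c("Ter119", "CD45", "CD31")) {
  transform_flow(readr::read_csv(path, col_types = readr::cols()),
                 cofactor = cofactor, lin_markers = lin_markers)
}
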