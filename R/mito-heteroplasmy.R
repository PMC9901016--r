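#' Compute per-population heteroplasmy from allele counts
#'
#' Pools the two strands to the standard bulk allele fraction
#' `af = alt / (ref + alt)` (i.e. alt reads over total depth at the
#' position) per population and variant, and retains the per-strand
#' fractions `af_fwd` / `af_rev` for strand-concordance QC. Variants with
#' zero alt reads in every population carry no lineage information and are
#' dropped.
#'
#' @param counts A `basecount_tbl` (see [read_basecounts()],
#'   [simulate_clonal_hierarchy()]).
#' @return A tibble of class `heteroplasmy_tbl`, one row per
#'   `(population, variant)`, with columns `population`, `variant`,
#'   `position`, `ref`, `alt`, `af`, `depth`, `af_fwd`, `af_rev`,
#'   `depth_fwd`, `depth_rev`. Strand fractions are `NA` where the strand
#'   has zero depth. The population order of the input is kept in
#'   `attr(, "populations")`.
#' @export
compute_heteroplasmy <- function(counts) {
  counts <- validate_basecounts(counts)
  if (nrow(counts) == 0L) {
    abort("empty allele-count table: nothing to compute heteroplasmy from")
  }
  pops <- unique(counts$population)
  m <- counts %>%
    dplyr::mutate(variant = variant_key(.data$position, .data$ref, .data$alt)) %>%
    tidyr::pivot_wider(
      id_cols = c("population", "variant", "position", "ref", "alt"),
      names_from = "strand", values_from = c("count", "depth"),
      values_fill = 0L
    )
  for (col in c("count_+", "count_-", "depth_+", "depth_-")) {
    if (!col %in% names(m)) m[[col]] <- 0L
  }
  m <- m %>%
    dplyr::mutate(
      depth = .data$`depth_+` + .data$`depth_-`,
      af = dplyr::if_else(.data$depth > 0,
                          (.data$`count_+` + .data$`count_-`) / .data$depth, 0),
      af_fwd = dplyr::if_else(.data$`depth_+` > 0,
                              .data$`count_+` / .data$`depth_+`, NA_real_),
      af_rev = dplyr::if_else(.data$`depth_-` > 0,
                              .data$`count_-` / .data$`depth_-`, NA_real_)
    ) %>%
    dplyr::rename(depth_fwd = "depth_+", depth_rev = "depth_-") %>%
    dplyr::select("population", "variant", "position", "ref", "alt",
                  "af", "depth", "af_fwd", "af_rev", "depth_fwd", "depth_rev")
  keep <- m %>%
    dplyr::group_by(.data$variant) %>%
    dplyr::summarise(any_alt = any(.data$af > 0), .groups = "drop") %>%
    dplyr::filter(.data$any_alt) %>%
    dplyr::pull("variant")
  m <- m %>%
    dplyr::filter(.data$variant %in% keep) %>%
    dplyr::arrange(match(.data$population, pops), .data$position)
  new_heteroplasmy_tbl(m, pops)
}

new_heteroplasmy_tbl <- function(m, populations) {
  m <- tibble::as_tibble(m)
  attr(m, "populations") <- populations
  if (!inherits(m, "heteroplasmy_tbl")) {
    class(m) <- c("heteroplasmy_tbl", class(m))
  }
  m
}

#' Widen a heteroplasmy table into a populations x variants matrix
#'
#' @param m A `heteroplasmy_tbl`.
#' @param value Which column to spread (`"af"`, `"depth"`, `"af_fwd"`,
#'   `"af_rev"`).
#' @return Numeric matrix, rows = populations (input order), columns =
#'   variants; missing combinations are 0 for `af`/`depth` and `NA` for
#'   strand fractions.
#' @export
af_matrix <- function(m, value = "af") {
  stopifnot(value %in% names(m))
  pops <- attr(m, "populations") %||% unique(m$population)
  vars <- unique(m$variant[order(m$position)])
  fill <- if (value %in% c("af", "depth")) 0 else NA_real_
  out <- matrix(fill, length(pops), length(vars),
                dimnames = list(pops, vars))
  out[cbind(match(m$population, pops), match(m$variant, vars))] <- m[[value]]
  out
}

#' Write a heteroplasmy table to TSV
#'
#' @param m A `heteroplasmy_tbl`.
#' @param path Output file.
#' @export
write_heteroplasmy <- function(m, path) {
  readr::write_tsv(as.data.frame(m), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
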