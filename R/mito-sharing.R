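#' Variant sharing across sorted populations
#'
#' For each variant, the set of populations in which it is present
#' (allele fraction at or above `tau` with sufficient depth), and whether
#' that makes it private to one population or shared across several.
#' Clonal variants shared across specific population sets are the direct
#' evidence for common clonal origin of those populations.
#'
#' @param m A `heteroplasmy_tbl`.
#' @param tau Presence threshold on the allele fraction, in (0, 1).
#' @param min_depth Minimum depth for a population to count as assayed
#'   (default 100).
#' @return A tibble of class `sharing_tbl`: per variant, the number of
#'   populations present (`n_present`), the pipe-collapsed population set
#'   (`populations`), and the `class` (`"absent"`, `"private"`,
#'   `"shared"`).
#' @export
variant_sharing <- function(m, tau = 0.01, min_depth = 100) {
  if (!(tau > 0 && tau < 1)) abort("`tau` must be in (0, 1)")
  pops <- attr(m, "populations") %||% unique(m$population)
  out <- m %>%
    dplyr::mutate(present = .data$af >= tau & .data$depth >= min_depth) %>%
    dplyr::group_by(.data$variant, .data$position) %>%
    dplyr::summarise(
      n_present = sum(.data$present),
      populations = paste(
        .data$population[.data$present][
          order(match(.data$population[.data$present], pops))],
        collapse = "|"),
      .groups = "drop"
    ) %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$n_present == 0L ~ "absent",
      .data$n_present == 1L ~ "private",
      TRUE ~ "shared"
    )) %>%
    dplyr::arrange(.data$position)
  class(out) <- c("sharing_tbl", class(out))
  attr(out, "tau") <- tau
  out
}

#' Count variants per population set
#'
#' @param sharing A `sharing_tbl` from [variant_sharing()].
#' @return A tibble of population sets with the number of variants whose
#'   presence pattern is exactly that set, most frequent first.
#' @export
sharing_counts <- function(sharing) {
  sharing %>%
    dplyr::filter(.data$n_present > 0L) %>%
    dplyr::count(.data$populations, .data$class, name = "n_variants") %>%
    dplyr::arrange(dplyr::desc(.data$n_variants))
}
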