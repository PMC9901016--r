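#' Filtering thresholds for high-confidence mitochondrial variants
#'
#' Somatic mtDNA variants from bulk capture sequencing are kept for lineage
#' analysis only when they are well covered, sub-homoplasmic (homoplasmic
#' variants are germline background, not clonal marks), supported
#' concordantly by both strands, and outside any blacklisted region. The
#' defaults follow common mito-capture QC practice and are all exposed.
#'
#' @param min_depth Minimum total depth for a population to be *callable*
#'   for a variant (default 100 reads).
#' @param min_af_call Minimum allele fraction for a call (default 0.005).
#' @param homoplasmy_cap Variants at or above this fraction in every
#'   callable population are treated as germline/homoplasmic and removed
#'   (default 0.95).
#' @param strand_ratio_max_log2 Maximum absolute log2 ratio between
#'   forward- and reverse-strand allele fractions in any called population
#'   (default 2).
#' @param strand_corr_min Minimum cross-population Pearson correlation
#'   between the two strands' allele fractions, applied when the variant is
#'   callable in at least 3 populations (default 0.65).
#' @param blacklist Optional data frame of 1-based `start`, `end` position
#'   intervals to exclude (e.g. hypervariable or low-complexity regions);
#'   default none.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_depth = 100,
                          min_af_call = 0.005,
                          homoplasmy_cap = 0.95,
                          strand_ratio_max_log2 = 2.0,
                          strand_corr_min = 0.65,
                          blacklist = NULL) {
  assert_scalar_number(min_depth, "min_depth", lower = 0)
  assert_scalar_number(min_af_call, "min_af_call", lower = 0, upper = 1)
  assert_scalar_number(homoplasmy_cap, "homoplasmy_cap", lower = 0, upper = 1)
  if (!(min_af_call > 0 && min_af_call < homoplasmy_cap)) {
    abort("need 0 < min_af_call < homoplasmy_cap <= 1")
  }
  assert_scalar_number(strand_ratio_max_log2, "strand_ratio_max_log2", lower = 0)
  assert_scalar_number(strand_corr_min, "strand_corr_min", lower = -1, upper = 1)
  if (!is.null(blacklist)) {
    blacklist <- tibble::as_tibble(blacklist)
    stopifnot(all(c("start", "end") %in% names(blacklist)))
  }
  structure(list(min_depth = min_depth, min_af_call = min_af_call,
                 homoplasmy_cap = homoplasmy_cap,
                 strand_ratio_max_log2 = strand_ratio_max_log2,
                 strand_corr_min = strand_corr_min,
                 blacklist = blacklist),
            class = "filter_params")
}

#' Filter a heteroplasmy table to high-confidence variants
#'
#' A variant survives when all five rules hold:
#' \enumerate{
#'   \item `called`: allele fraction >= `min_af_call` with depth >=
#'     `min_depth` in at least one population;
#'   \item `not_homoplasmic`: not at or above `homoplasmy_cap` in every
#'     callable (depth-sufficient) population;
#'   \item `strand_balance`: in every population where called, both strands
#'     show the allele and their fractions agree within
#'     `strand_ratio_max_log2`;
#'   \item `strand_concordance`: across callable populations (when at
#'     least 3), the forward- and reverse-strand fractions correlate at
#'     >= `strand_corr_min` (Pearson); vacuously true with < 3 callable
#'     populations or when a strand has no variance;
#'   \item `not_blacklisted`: the position falls in no blacklist interval.
#' }
#'
#' @param m A `heteroplasmy_tbl` (see [compute_heteroplasmy()]).
#' @param params A [filter_params()].
#' @return The filtered `heteroplasmy_tbl`. A per-variant, per-rule audit
#'   trail is attached and retrievable with [filter_audit()].
#' @export
filter_high_confidence <- function(m, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  pops <- attr(m, "populations") %||% unique(m$population)
  per_var <- m %>%
    dplyr::mutate(
      deep = .data$depth >= params$min_depth,
      called = .data$deep & .data$af >= params$min_af_call,
      strand_ok = !is.na(.data$af_fwd) & !is.na(.data$af_rev) &
        .data$af_fwd > 0 & .data$af_rev > 0 &
        abs(log2(.data$af_fwd / .data$af_rev)) <= params$strand_ratio_max_log2
    ) %>%
    dplyr::group_by(.data$variant, .data$position) %>%
    dplyr::summarise(
      # each rule keeps its own name: summarise() evaluates sequentially and
      # reusing an input column's name would shadow it for later rules
      rule_called = any(.data$called),
      rule_homoplasmy = !any(.data$deep) ||
        !all(.data$af[.data$deep] >= params$homoplasmy_cap),
      rule_balance = all(.data$strand_ok[.data$called]),
      rule_concord = strand_concordant(
        .data$af_fwd[.data$deep], .data$af_rev[.data$deep],
        params$strand_corr_min
      ),
      .groups = "drop"
    ) %>%
    dplyr::rename(called = "rule_called", not_homoplasmic = "rule_homoplasmy",
                  strand_balance = "rule_balance",
                  strand_concordance = "rule_concord") %>%
    dplyr::mutate(
      not_blacklisted = !position_blacklisted(.data$position, params$blacklist),
      keep = .data$called & .data$not_homoplasmic & .data$strand_balance &
        .data$strand_concordance & .data$not_blacklisted
    )
  out <- m %>% dplyr::filter(.data$variant %in% per_var$variant[per_var$keep])
  out <- new_heteroplasmy_tbl(out, pops)
  attr(out, "audit") <- per_var
  attr(out, "filter_params") <- params
  out
}

# cross-population Pearson correlation of strand AFs; applied only when
# >= 3 called populations give both strand fractions and both vary
strand_concordant <- function(fwd, rev, corr_min) {
  ok <- !is.na(fwd) & !is.na(rev)
  if (sum(ok) < 3L) return(TRUE)
  if (sd(fwd[ok]) == 0 || sd(rev[ok]) == 0) return(TRUE)
  cor(fwd[ok], rev[ok]) >= corr_min
}

position_blacklisted <- function(position, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    return(rep(FALSE, length(position)))
  }
  vapply(position, function(p) {
    any(p >= blacklist$start & p <= blacklist$end)
  }, logical(1))
}

#' Retrieve the per-variant filter audit trail
#'
#' @param m The result of [filter_high_confidence()].
#' @return A tibble with one row per input variant and one logical column
#'   per filter rule, plus the overall `keep` decision.
#' @export
filter_audit <- function(m) {
  a <- attr(m, "audit")
  if (is.null(a)) abort("no audit attached; run `filter_high_confidence()` first")
  a
}
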