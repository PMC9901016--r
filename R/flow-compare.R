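#' Compare gated subset percentages across conditions
#'
#' Summarises per-sample subset percentages (of parent) by group: mean,
#' SD and a seeded bootstrap percentile 95% CI over samples, plus pairwise
#' between-group differences reported as effect sizes (difference of
#' means with a bootstrap CI) — no inferential testing. Groups with a
#' single sample are flagged: their SD is undefined and the CI is
#' suppressed.
#'
#' @param report A `subset_report` with a `sample` column (gate multiple
#'   samples at once by stacking events with a `sample` column).
#' @param grouping Named character vector mapping sample -> group.
#' @param B Bootstrap replicates (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return A list of class `condition_comparison` with tibbles `summary`
#'   (per group x node) and `differences` (per group pair x node).
#' @export
compare_conditions <- function(report, grouping, B = 2000, seed = 1L) {
  if (!"sample" %in% names(report)) {
    abort("`report` must carry a `sample` column (gate with a sample column)")
  }
  samples <- unique(report$sample)
  if (!all(samples %in% names(grouping))) {
    abort("`grouping` must name every sample in the report")
  }
  groups <- unique(unname(grouping[samples]))
  if (!length(groups)) abort("empty grouping")
  df <- report %>%
    dplyr::mutate(group = unname(grouping[.data$sample])) %>%
    dplyr::filter(!is.na(.data$pct_parent))

  boot_ci <- function(x, stat, B, lo = 0.025, hi = 0.975) {
    reps <- vapply(seq_len(B), function(b) {
      stat(x[sample.int(length(x), replace = TRUE)])
    }, numeric(1))
    quantile(reps, c(lo, hi), names = FALSE)
  }

  out <- with_seed(seed, {
    summary <- df %>%
      dplyr::group_by(.data$group, .data$node) %>%
      dplyr::summarise(
        n_samples = dplyr::n(),
        mean_pct = mean(.data$pct_parent),
        sd_pct = if (dplyr::n() > 1) sd(.data$pct_parent) else NA_real_,
        ci_lo = if (dplyr::n() > 1)
          boot_ci(.data$pct_parent, mean, B)[1] else NA_real_,
        ci_hi = if (dplyr::n() > 1)
          boot_ci(.data$pct_parent, mean, B)[2] else NA_real_,
        single_sample = dplyr::n() == 1L,
        .groups = "drop"
      )
    pairs <- if (length(groups) >= 2) utils::combn(groups, 2, simplify = FALSE)
             else list()
    differences <- purrr::map_dfr(pairs, function(pr) {
      purrr::map_dfr(unique(df$node), function(nd) {
        x1 <- df$pct_parent[df$group == pr[1] & df$node == nd]
        x2 <- df$pct_parent[df$group == pr[2] & df$node == nd]
        est <- mean(x2) - mean(x1)
        ci <- if (length(x1) > 1 && length(x2) > 1) {
          reps <- vapply(seq_len(B), function(b) {
            mean(x2[sample.int(length(x2), replace = TRUE)]) -
              mean(x1[sample.int(length(x1), replace = TRUE)])
          }, numeric(1))
          quantile(reps, c(0.025, 0.975), names = FALSE)
        } else c(NA_real_, NA_real_)
        tibble::tibble(group1 = pr[1], group2 = pr[2], node = nd,
                       diff_pct = est, ci_lo = ci[1], ci_hi = ci[2],
                       ci_suppressed = anyNA(ci))
      })
    })
    list(summary = summary, differences = differences)
  })
  structure(c(out, list(B = B, seed = seed)), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> ", nrow(x$summary), " group x node summaries, ",
      nrow(x$differences), " pairwise differences (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname compare_conditions
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @method tidy condition_comparison
tidy.condition_comparison <- function(x, ...) x$summary

#' @export
#' @rdname compare_conditions
#' @method glance condition_comparison
glance.condition_comparison <- function(x, ...) {
  tibble::tibble(n_groups = length(unique(x$summary$group)),
                 n_nodes = length(unique(x$summary$node)),
                 B = x$B)
}
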