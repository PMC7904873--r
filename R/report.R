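#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test with fixed margins. The two-sided p-value is
#' the probability-mass rule: the sum of probabilities of all tables (with
#' the observed margins) no more probable than the observed one. One-sided
#' alternatives sum the corresponding tail. Computed by direct enumeration
#' of the hypergeometric distribution.
#'
#' @param table 2x2 matrix (or something coercible) of non-negative integer
#'   counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`;
#'   sided alternatives refer to the odds ratio of the first cell.
#' @return The exact p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(15, 6, 15, 24), 2))                 # two-sided
#' fisher_exact_2x2(matrix(c(15, 6, 15, 24), 2), "greater")      # directional
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop_evoked("evoked_invalid", "need a 2x2 table")
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop_evoked("evoked_invalid", "cells must be non-negative integers")
  }
  if (sum(tab) == 0) stop_evoked("evoked_invalid", "at least one margin > 0")
  a <- tab[1, 1]
  m <- sum(tab[1, ])            # row 1 total (white balls)
  n <- sum(tab[2, ])            # row 2 total
  k <- sum(tab[, 1])            # column 1 total (draws)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  switch(alternative,
         two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
         greater = sum(probs[support >= a]),
         less = sum(probs[support <= a]))
}

#' Site-level responsiveness contrast between sleep and wakefulness
#'
#' Builds the 2x2 state-by-responsiveness table from per-site evoked-LFP
#' verdicts (one [rot_test()] verdict per site per state) and tests whether
#' the proportion of responsive sites differs between states with the Fisher
#' exact test. Both the directional p-value (sleep proportion higher — the
#' question the sites are compared on) and the two-sided p-value are
#' reported.
#'
#' @param site_results A tibble with columns `site`, `state`
#'   (`"SWS"`/`"WAKE"`) and either `responsive` (logical) or `p_value` plus
#'   `pair_mean` (verdicts then derived at `alpha`).
#' @param alpha Detection level used when deriving verdicts from p-values.
#' @return A list of class `site_summary`: `n_sites`, `n_responsive_sleep`,
#'   `n_responsive_wake`, `table`, `fisher_p_one_sided`,
#'   `fisher_p_two_sided`, `per_site` verdicts.
#' @export
site_proportion_report <- function(site_results, alpha = 0.05) {
  df <- as_tibble(site_results)
  if (!"responsive" %in% names(df)) {
    df$responsive <- df$pair_mean > 0 & df$p_value < alpha
  }
  wide <- tidyr::pivot_wider(df[, c("site", "state", "responsive")],
                             names_from = "state",
                             values_from = "responsive")
  for (st in c("SWS", "WAKE")) {
    if (!st %in% names(wide) || anyNA(wide[[st]])) {
      bad <- if (!st %in% names(wide)) "all"
             else paste(wide$site[is.na(wide[[st]])], collapse = ", ")
      stop_evoked("evoked_invalid",
                  sprintf("missing %s result for site(s): %s", st, bad))
    }
  }
  ns <- nrow(wide)
  rs <- sum(wide$SWS)
  rw <- sum(wide$WAKE)
  tab <- matrix(c(rs, ns - rs, rw, ns - rw), 2L, byrow = TRUE,
                dimnames = list(c("SWS", "WAKE"),
                                c("responsive", "non_responsive")))
  structure(
    list(n_sites = ns, n_responsive_sleep = rs, n_responsive_wake = rw,
         table = tab,
         fisher_p_one_sided = fisher_exact_2x2(tab, "greater"),
         fisher_p_two_sided = fisher_exact_2x2(tab, "two.sided"),
         per_site = wide),
    class = "site_summary"
  )
}

#' @export
print.site_summary <- function(x, ...) {
  cat(sprintf(
    "<site_summary> %d sites: %d responsive in sleep, %d in wakefulness\n  Fisher exact p = %.4g (one-sided), %.4g (two-sided)\n",
    x$n_sites, x$n_responsive_sleep, x$n_responsive_wake,
    x$fisher_p_one_sided, x$fisher_p_two_sided))
  invisible(x)
}

#' @export
glance.site_summary <- function(x, ...) {
  tibble(n_sites = x$n_sites, n_responsive_sleep = x$n_responsive_sleep,
         n_responsive_wake = x$n_responsive_wake,
         fisher_p_one_sided = x$fisher_p_one_sided,
         fisher_p_two_sided = x$fisher_p_two_sided)
}

#' Cell-category report with exact exclusivity tests
#'
#' Summarizes classified cells per group ([tabulate_cells()]) and tests, per
#' group, whether exclusively sleep-responsive cells outnumber exclusively
#' wake-responsive ones. The published construction of that exact test is
#' ambiguous, so two clearly labelled candidates are computed: an unpaired
#' Fisher test on exclusive counts out of all recorded cells
#' (`fisher_unpaired_p`), and an exact binomial test on the discordant pair
#' — among exclusively responsive cells, is the sleep share larger than 1/2
#' (`binomial_discordant_p`)? Both are one-sided in the sleep direction.
#'
#' @param categories Tibble with a `category` column (rows = cells).
#' @param group Optional per-cell group labels.
#' @return A tibble with one row per group: the count columns of
#'   [tabulate_cells()] plus the two exact p-values.
#' @export
cell_report <- function(categories, group = NULL) {
  counts <- tabulate_cells(categories, group)
  counts |>
    dplyr::rowwise() |>
    dplyr::mutate(
      fisher_unpaired_p = fisher_exact_2x2(
        matrix(c(.data$sleep_only, .data$recorded - .data$sleep_only,
                 .data$wake_only, .data$recorded - .data$wake_only),
               2L, byrow = TRUE), "greater"),
      binomial_discordant_p = if (.data$sleep_only + .data$wake_only > 0) {
        binom.test(.data$sleep_only, .data$sleep_only + .data$wake_only,
                   alternative = "greater")$p.value
      } else NA_real_) |>
    dplyr::ungroup()
}
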