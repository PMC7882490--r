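#' Paired t test between two belief items
#'
#' Classical paired Student t test on within-respondent differences
#' (`item_a - item_b`), after listwise deletion of records missing either
#' item. Unweighted, matching plain paired-test reporting; sidedness is
#' honored exactly.
#'
#' @param table Survey tibble.
#' @param item_a,item_b Item column names.
#' @param sidedness `"two_sided"`, `"one_sided_a_lt_b"` (alternative: a's
#'   mean is lower) or `"one_sided_a_gt_b"`.
#' @param wave Optional wave filter (1 or 2); default uses all rows.
#' @return One-row tibble: `item_a`, `item_b`, `wave`, `n_pairs`,
#'   `mean_difference` (a - b on the item scale), `t_statistic`,
#'   `p_value`, `sidedness`.
#' @export
paired_test <- function(table, item_a, item_b,
                        sidedness = c("two_sided", "one_sided_a_lt_b",
                                      "one_sided_a_gt_b"),
                        wave = NULL) {
  sidedness <- match.arg(sidedness)
  d <- complete_pairs(table, item_a, item_b, wave)
  if (nrow(d) < 2) {
    stop("insufficient data: need at least 2 complete pairs", call. = FALSE)
  }
  alt <- switch(sidedness, two_sided = "two.sided",
                one_sided_a_lt_b = "less", one_sided_a_gt_b = "greater")
  diff <- d$a - d$b
  if (sd(diff) == 0) {
    # degenerate paired data: constant differences; t is 0 or +/-Inf
    t_stat <- if (mean(diff) == 0) 0 else sign(mean(diff)) * Inf
    p <- switch(alt,
                two.sided = if (t_stat == 0) 1 else 0,
                less = if (t_stat == 0) 0.5 else if (t_stat < 0) 0 else 1,
                greater = if (t_stat == 0) 0.5 else if (t_stat > 0) 0 else 1)
  } else {
    ht <- t.test(d$a, d$b, paired = TRUE, alternative = alt)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  tibble::tibble(item_a = item_a, item_b = item_b,
                 wave = if (is.null(wave)) NA_integer_ else as.integer(wave),
                 n_pairs = nrow(d),
                 mean_difference = mean(diff),
                 t_statistic = t_stat,
                 p_value = p, sidedness = sidedness)
}

complete_pairs <- function(table, item_a, item_b, wave = NULL) {
  stopifnot(all(c(item_a, item_b) %in% names(table)))
  if (!is.null(wave)) table <- table[table$wave == wave, ]
  d <- tibble::tibble(a = table[[item_a]], b = table[[item_b]])
  d[complete.cases(d), ]
}

#' Classify respondent-level pairs as higher / equal / lower
#'
#' Counts, over listwise-complete pairs, how many respondents rated
#' `item_a` above, equal to and below `item_b`. Differences with absolute
#' value at most `tolerance` count as equal; the default 0 means exact
#' equality, the natural reading for integer-valued items.
#'
#' @inheritParams paired_test
#' @param tolerance Half-width of the equality band, in item-scale units.
#' @return One-row tibble: `n_higher`, `n_equal`, `n_lower`, `n_pairs`.
#' @export
classify_pairs <- function(table, item_a, item_b, tolerance = 0,
                           wave = NULL) {
  stopifnot(tolerance >= 0)
  d <- complete_pairs(table, item_a, item_b, wave)
  diff <- d$a - d$b
  tibble::tibble(n_higher = sum(diff > tolerance),
                 n_equal = sum(abs(diff) <= tolerance),
                 n_lower = sum(diff < -tolerance),
                 n_pairs = nrow(d))
}

#' No-intercept proportional slope between two items
#'
#' Linear regression of `item_y` on `item_x` without intercept over
#' complete pairs: `slope = sum(xy) / sum(x^2)`, standard error
#' `sqrt(sum((y - b x)^2) / (n - 1)) / sqrt(sum(x^2))`. Used to express
#' one rating as a multiple of another (e.g. perceived contagiousness of
#' one disease relative to another).
#'
#' @inheritParams paired_test
#' @param item_y,item_x Item column names.
#' @return List: `slope`, `standard_error`, `n_pairs`.
#' @export
proportional_slope <- function(table, item_y, item_x, wave = NULL) {
  d <- complete_pairs(table, item_y, item_x, wave)
  names(d) <- c("y", "x")
  if (nrow(d) < 2) {
    stop("insufficient data: need at least 2 complete pairs", call. = FALSE)
  }
  if (sum(d$x^2) == 0) {
    stop("undefined slope: all x values are zero", call. = FALSE)
  }
  fit <- lm(y ~ 0 + x, data = d)
  # summary warns on an exact proportional relationship (SE 0); that case
  # is well defined here
  s <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(s["x", "Estimate"]),
       standard_error = unname(s["x", "Std. Error"]),
       n_pairs = nrow(d))
}

#' Fold difference between two positive quantities
#'
#' Plain ratio `a / b`, used to compare reproduction numbers or rates
#' between diseases (e.g. an R0 of 1.78 against 1.3 is a 1.37-fold
#' difference).
#'
#' @param a,b Positive numbers.
#' @return `a / b`.
#' @export
fold_difference <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b), b > 0)
  a / b
}

#' Stratified gap between mean belief and an objective benchmark
#'
#' Compares the per-stratum mean of a 0-100 belief item with the
#' benchmark prevalence (per 100) of the same stratum:
#' `gap = mean belief - benchmark`, so a positive gap means the stratum
#' over-states its risk relative to the recorded rate.
#'
#' @param table Survey tibble.
#' @param item 0-100 item column.
#' @param bench Output of [compute_rates()] with a stratum column matching
#'   `strata`.
#' @param strata Name of the stratum column, present in both inputs
#'   (e.g. `"gender"`, `"age_category"`, `"region_tier"`).
#' @param use_weights Weight the belief means by `weight`.
#' @param wave Optional wave filter.
#' @return Tibble per stratum: `mean_belief`, `benchmark_prevalence`,
#'   `gap`, `n`, `comparable` (`FALSE` for survey strata absent from the
#'   benchmark, whose gap is `NA`).
#' @export
stratified_gap <- function(table, item, bench, strata,
                           use_weights = FALSE, wave = NULL) {
  stopifnot(strata %in% names(table), strata %in% names(bench),
            item %in% names(table),
            "prevalence_per100" %in% names(bench))
  if (!is.null(wave)) table <- table[table$wave == wave, ]
  w <- if (use_weights) table$weight else rep(1, nrow(table))
  ok <- !is.na(table[[item]])
  d <- tibble::tibble(stratum = table[[strata]][ok],
                      x = table[[item]][ok], w = w[ok])
  beliefs <- d %>%
    dplyr::group_by(.data$stratum) %>%
    dplyr::summarise(mean_belief = weighted.mean(.data$x, .data$w),
                     n = dplyr::n(), .groups = "drop")
  ref <- tibble::tibble(stratum = bench[[strata]],
                        benchmark_prevalence = bench$prevalence_per100)
  beliefs %>%
    dplyr::left_join(ref, by = "stratum") %>%
    dplyr::mutate(comparable = !is.na(.data$benchmark_prevalence),
                  gap = .data$mean_belief - .data$benchmark_prevalence) %>%
    dplyr::select(dplyr::all_of(c("stratum", "n", "mean_belief",
                                  "benchmark_prevalence", "gap",
                                  "comparable")))
}
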