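#' Comparative-optimism index
#'
#' Rescales the difference between expected population prevalence (q4) and
#' own risk to catch the disease (q2) to `[0, 1]`:
#' `index = (q4 - q2 + 100) / 200`, the unique affine map sending a
#' difference of -100 to 0, 0 to 0.5 and +100 to 1. Values above 0.5
#' indicate comparative optimism (own risk judged below the population
#' rate), below 0.5 comparative pessimism.
#'
#' @param q2,q4 Numeric vectors in `[0, 100]`; `NA` in either yields `NA`.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' optimism_index(q2 = 30, q4 = 50)  # optimism: 0.6
optimism_index <- function(q2, q4) {
  stopifnot(length(q2) == length(q4))
  bad <- !is.na(q2) & (q2 < 0 | q2 > 100) | !is.na(q4) & (q4 < 0 | q4 > 100)
  if (any(bad)) stop("q2 and q4 must lie in [0, 100]", call. = FALSE)
  (q4 - q2 + 100) / 200
}

#' Between-wave dynamics of comparative optimism
#'
#' For each wave, computes the mean within-respondent difference
#' `q2 - q4` over complete pairs with a two-sided paired t test, and the
#' mean optimism index. The wave contrast is estimated by a quasibinomial
#' logit GLM of the index on a wave indicator (via
#' [fit_quasibinomial()]), post-stratification-weighted by default, and
#' reported as the indicator's robust p-value.
#'
#' @param table Survey tibble with `q2_own_risk`, `q4_prevalence`,
#'   `wave`, `weight`.
#' @param use_weights Weight the GLM wave contrast.
#' @return List of class `optimism_result`: `per_wave` (tibble: `wave`,
#'   `n_pairs`, `mean_q2_minus_q4`, `p_value`, `index_mean`) and
#'   `wave_contrast` (list: `estimate` on the logit scale, `ame` on the
#'   index scale, `p_value`, `fit`), the latter `NULL` when only one wave
#'   has enough pairs.
#' @export
optimism_dynamics <- function(table, use_weights = TRUE) {
  stopifnot(all(c("q2_own_risk", "q4_prevalence", "wave") %in% names(table)))
  ok <- complete.cases(table[c("q2_own_risk", "q4_prevalence")])
  d <- table[ok, ]
  waves <- sort(unique(d$wave))
  per_wave <- purrr::map_dfr(waves, function(wv) {
    dw <- d[d$wave == wv, ]
    if (nrow(dw) < 2) {
      warning("wave ", wv, " has fewer than 2 complete pairs; skipped")
      return(tibble::tibble())
    }
    ht <- t.test(dw$q2_own_risk, dw$q4_prevalence, paired = TRUE)
    tibble::tibble(
      wave = wv, n_pairs = nrow(dw),
      mean_q2_minus_q4 = mean(dw$q2_own_risk - dw$q4_prevalence),
      p_value = ht$p.value,
      index_mean = mean(optimism_index(dw$q2_own_risk, dw$q4_prevalence)))
  })
  contrast <- NULL
  if (length(unique(per_wave$wave)) == 2) {
    d$opt_index <- optimism_index(d$q2_own_risk, d$q4_prevalence)
    d$wave <- factor(d$wave)
    fit <- fit_quasibinomial(d, outcome = "opt_index", terms = "wave",
                             use_weights = use_weights, outcome_scale = 1)
    est <- coef(fit)["wave2"]
    se <- sqrt(fit$covariance["wave2", "wave2"])
    ame <- average_marginal_effects(fit)
    contrast <- list(estimate = unname(est),
                     ame = ame$ame[ame$term == "wave"],
                     p_value = 2 * pnorm(-abs(est / se)), fit = fit)
  }
  structure(list(per_wave = per_wave, wave_contrast = contrast),
            class = "optimism_result")
}

#' @export
print.optimism_result <- function(x, ...) {
  cat("Comparative optimism by wave (q2 - q4, 0-100 points):\n")
  print(as.data.frame(x$per_wave), row.names = FALSE)
  if (!is.null(x$wave_contrast)) {
    cat(sprintf("Wave contrast (GLM on index): AME = %+0.4f, p = %.3g\n",
                x$wave_contrast$ame, x$wave_contrast$p_value))
  }
  invisible(x)
}
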