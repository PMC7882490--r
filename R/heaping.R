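#' Maximum-likelihood beta fit to bounded 0-100 responses
#'
#' Fits a beta distribution to item responses. Responses are mapped to
#' (0, 1) by `x / 100` and boundary-shrunk with the Smithson-Verkuilen
#' transform `x' = (x * (n - 1) + 0.5) / n`, which keeps exact 0s and 100s
#' in the sample at finite likelihood. Parameters maximize the beta
#' log-likelihood (BFGS on log-shape parameters, method-of-moments start);
#' the fit is deterministic given the input. A pure method-of-moments fit
#' is available via `method = "moments"`.
#'
#' @param responses Numeric vector of values in `[0, 100]`; `NA`s are
#'   dropped.
#' @param include_fifty Keep exact-50 responses in the fit (default). The
#'   heap itself is part of the observed distribution being modelled;
#'   excluding it is exposed for sensitivity analysis.
#' @param method `"mle"` (default) or `"moments"`.
#' @return List of class `beta_fit`: `alpha`, `beta`, `n_used`,
#'   `log_likelihood`, `method`.
#' @export
fit_beta <- function(responses, include_fifty = TRUE,
                     method = c("mle", "moments")) {
  method <- match.arg(method)
  x <- responses[!is.na(responses)]
  stopifnot(all(x >= 0 & x <= 100))
  if (!include_fifty) x <- x[x != 50]
  if (length(unique(x)) < 2) {
    stop("degenerate fit: need at least 2 distinct present values",
         call. = FALSE)
  }
  n <- length(x)
  xs <- (x / 100 * (n - 1) + 0.5) / n
  m <- mean(xs)
  v <- var(xs)
  phi <- max(m * (1 - m) / v - 1, 1e-3)
  par <- c(m * phi, (1 - m) * phi)
  if (method == "mle") {
    nll <- function(lp) -sum(dbeta(xs, exp(lp[1]), exp(lp[2]), log = TRUE))
    opt <- optim(log(par), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    par <- exp(opt$par)
    ll <- -opt$value
  } else {
    ll <- sum(dbeta(xs, par[1], par[2], log = TRUE))
  }
  structure(list(alpha = par[1], beta = par[2], n_used = n,
                 log_likelihood = ll, method = method),
            class = "beta_fit")
}

#' @export
print.beta_fit <- function(x, ...) {
  cat(sprintf("beta fit (%s): alpha = %.4f, beta = %.4f, n = %d, logLik = %.2f\n",
              x$method, x$alpha, x$beta, x$n_used, x$log_likelihood))
  invisible(x)
}

#' Excess mass of "50" answers over a fitted beta law
#'
#' The fifty-fifty blip statistic: the observed share of responses in the
#' closed 45-55 window minus the share the fitted beta distribution
#' predicts there, in percentage points (may be negative). Because
#' responses are integers, the window of recorded values 45..55
#' corresponds to latent values in `[44.5, 55.5)`; by default the expected
#' mass uses that half-unit continuity correction,
#' `I(0.555; a, b) - I(0.445; a, b)` with `I` the regularized incomplete
#' beta function. `continuity = FALSE` uses the uncorrected window
#' `I(0.55) - I(0.45)`.
#'
#' @inheritParams fit_beta
#' @param continuity Apply the half-unit continuity correction to the
#'   expected window mass (default `TRUE`).
#' @param fit Optional pre-computed [fit_beta()] result.
#' @return List of class `heaping_mass`: `observed_window_mass`,
#'   `expected_window_mass` (proportions), `excess_pct`
#'   (`100 * (observed - expected)`), `fit`.
#' @export
excess_fifty <- function(responses, include_fifty = TRUE,
                         method = "mle", continuity = TRUE, fit = NULL) {
  x <- responses[!is.na(responses)]
  if (is.null(fit)) {
    fit <- fit_beta(x, include_fifty = include_fifty, method = method)
  }
  lo <- if (continuity) 0.445 else 0.45
  hi <- if (continuity) 0.555 else 0.55
  observed <- mean(x >= 45 & x <= 55)
  expected <- pbeta(hi, fit$alpha, fit$beta) -
    pbeta(lo, fit$alpha, fit$beta)
  structure(list(observed_window_mass = observed,
                 expected_window_mass = expected,
                 excess_pct = 100 * (observed - expected), fit = fit),
            class = "heaping_mass")
}

#' Means with and without the "50" answers, and the indicator test
#'
#' Reports the item mean on the proportion scale (`x / 100`), the mean
#' excluding exact 50s, and the p-value of an ordinary least-squares
#' regression of the demeaned responses on an indicator of the "50"
#' answer (two-sided t test on the indicator coefficient) — algebraically
#' the pooled-variance two-sample t test of the 50-group against the rest.
#'
#' @param responses Numeric vector in `[0, 100]`; `NA`s dropped.
#' @return List: `mean_proportion`, `mean_without_50s`, `p_value` (`NA`
#'   when the sample contains no exact 50, in which case both means
#'   coincide), `n`, `n_fifty`.
#' @export
heaping_adjusted_means <- function(responses) {
  x <- responses[!is.na(responses)]
  stopifnot(length(x) >= 2)
  is50 <- x == 50
  if (all(is50)) {
    stop("all responses are exactly 50; mean without 50s undefined",
         call. = FALSE)
  }
  mean_prop <- mean(x) / 100
  mean_wo <- mean(x[!is50]) / 100
  p <- NA_real_
  if (any(is50)) {
    fit <- lm((x - mean(x)) ~ is50)
    p <- summary(fit)$coefficients["is50TRUE", "Pr(>|t|)"]
  }
  list(mean_proportion = mean_prop, mean_without_50s = mean_wo,
       p_value = p, n = length(x), n_fifty = sum(is50))
}

#' Heaping summary table for the belief items
#'
#' Runs [excess_fifty()] and [heaping_adjusted_means()] per item and wave
#' and assembles the per-item heaping report (excess-50 percentage, means
#' with and without 50s, indicator-test p-value). Computed unweighted:
#' heaping is a property of the raw response distribution, so
#' post-stratification is not applied here.
#'
#' @param table Survey tibble.
#' @param items Item columns (default: the four 0-100 belief items).
#' @param min_n Minimum present responses per item x wave to attempt a fit.
#' @inheritParams excess_fifty
#' @return Tibble: `item`, `wave`, `n`, `observed_window_mass`,
#'   `expected_window_mass`, `excess_pct`, `mean_proportion`,
#'   `mean_without_50s`, `p_value`, `alpha`, `beta`.
#' @export
heaping_table <- function(table, items = c("q1_ifr", "q2_own_risk",
                                           "q3_others_risk",
                                           "q4_prevalence"),
                          include_fifty = TRUE, continuity = TRUE,
                          min_n = 10) {
  stopifnot(all(items %in% names(table)))
  grid <- tidyr::expand_grid(item = items,
                             wave = sort(unique(table$wave)))
  purrr::pmap_dfr(grid, function(item, wave) {
    x <- table[[item]][table$wave == wave]
    x <- x[!is.na(x)]
    if (length(x) < min_n || length(unique(x)) < 2) {
      return(tibble::tibble(item = item, wave = wave, n = length(x),
                            observed_window_mass = NA_real_,
                            expected_window_mass = NA_real_,
                            excess_pct = NA_real_,
                            mean_proportion = NA_real_,
                            mean_without_50s = NA_real_,
                            p_value = NA_real_, alpha = NA_real_,
                            beta = NA_real_))
    }
    mass <- excess_fifty(x, include_fifty = include_fifty,
                         continuity = continuity)
    means <- heaping_adjusted_means(x)
    tibble::tibble(item = item, wave = wave, n = length(x),
                   observed_window_mass = mass$observed_window_mass,
                   expected_window_mass = mass$expected_window_mass,
                   excess_pct = mass$excess_pct,
                   mean_proportion = means$mean_proportion,
                   mean_without_50s = means$mean_without_50s,
                   p_value = means$p_value,
                   alpha = mass$fit$alpha, beta = mass$fit$beta)
  })
}
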