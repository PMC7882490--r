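#' Survey-weighted quasibinomial logit regression
#'
#' Fits a generalized linear model with logit link and quasibinomial
#' variance `phi * mu * (1 - mu)` to a proportion-scaled item. The
#' quasi-likelihood requires no integer support, so continuous 0-100
#' slider responses (divided by `outcome_scale`) are valid outcomes,
#' including exact 0s and 100s. Estimation is iteratively reweighted least
#' squares (via [stats::glm()]) with post-stratification weights
#' multiplying the working weights, run to a tight tolerance
#' (`epsilon = 1e-10`, at most 100 iterations). Records missing the
#' outcome, any model term or the weight are listwise deleted.
#'
#' The dispersion is the Pearson statistic over residual degrees of
#' freedom. The default covariance is a design-robust (sandwich, HC0)
#' estimator with weight-aware score contributions
#' `w_i (y_i - mu_i) x_i`; `vcov_type = "model"` gives the model-based
#' quasibinomial covariance instead.
#'
#' @param table Data frame of respondents.
#' @param outcome Column name of the outcome item.
#' @param terms Character vector of covariate column names (categorical
#'   columns are treated as factors in their codebook level order, first
#'   level = reference).
#' @param use_weights Multiply working weights by the `weight` column.
#' @param outcome_scale Divisor mapping the outcome to `[0, 1]` (100 for
#'   the belief sliders, 1 for an already-proportional outcome).
#' @param vcov_type `"robust"` (default) or `"model"`.
#' @return Object of class `qb_fit`: `coefficients`, `dispersion`,
#'   `covariance`, `n_used`, `converged`, `iterations`,
#'   `boundary_fitted` (any fitted probability at the 0/1 boundary,
#'   the separation flag), plus the underlying `glm`, the model frame
#'   `data`, `weights`, `terms`, `outcome`.
#' @export
fit_quasibinomial <- function(table, outcome, terms, use_weights = TRUE,
                              outcome_scale = 100,
                              vcov_type = c("robust", "model")) {
  vcov_type <- match.arg(vcov_type)
  stopifnot(outcome %in% names(table), all(terms %in% names(table)))
  cols <- c(outcome, terms, if (use_weights) "weight")
  d <- table[cols]
  d <- d[complete.cases(d), , drop = FALSE]
  d <- droplevels(as.data.frame(d))
  # codebook categorical columns become factors in codebook level order
  cb <- default_codebook()
  for (tm in terms) {
    if (is.character(d[[tm]])) {
      i <- match(tm, cb$column)
      lev <- if (is.na(i)) NULL else cb$levels[[i]]
      lev <- if (is.null(lev)) sort(unique(d[[tm]]))
             else intersect(lev, d[[tm]])
      d[[tm]] <- factor(d[[tm]], levels = lev)
    }
  }
  d$.y <- d[[outcome]] / outcome_scale
  if (any(d$.y < 0 | d$.y > 1)) {
    stop("outcome outside [0, 1] after rescaling; check outcome_scale",
         call. = FALSE)
  }
  d$.w <- if (use_weights) d$weight else rep(1, nrow(d))
  f <- reformulate(terms, response = ".y")
  for (tm in terms) {
    if (is.factor(d[[tm]]) && nlevels(droplevels(d[[tm]])) < 2) {
      stop("insufficient data: term '", tm,
           "' has fewer than 2 levels after listwise deletion",
           call. = FALSE)
    }
  }
  p <- ncol(model.matrix(f, d))
  if (nrow(d) < p + 2) {
    stop("insufficient data: need at least p + 2 complete records",
         call. = FALSE)
  }
  fit <- suppressWarnings(glm(
    f, family = quasibinomial(), data = d, weights = d$.w,
    control = glm.control(epsilon = 1e-10, maxit = 100)))
  if (!fit$converged) {
    warning("IRLS did not converge within 100 iterations")
  }
  mu <- fitted(fit)
  boundary <- any(mu < 1e-8 | mu > 1 - 1e-8)
  if (boundary) warning("fitted probabilities at the boundary; ",
                        "possible separation")
  X <- model.matrix(fit)
  w <- d$.w
  vmu <- pmax(mu * (1 - mu), 1e-10)
  pearson <- sum(w * (d$.y - mu)^2 / vmu)
  dispersion <- pearson / df.residual(fit)
  info <- crossprod(X, X * (w * vmu))  # expected information (logit link)
  bread <- solve(info)
  if (vcov_type == "robust") {
    scores <- X * (w * (d$.y - mu))
    covariance <- bread %*% crossprod(scores) %*% bread
  } else {
    covariance <- bread * dispersion
  }
  covariance <- (covariance + t(covariance)) / 2
  dimnames(covariance) <- list(colnames(X), colnames(X))
  structure(list(coefficients = coef(fit), dispersion = dispersion,
                 covariance = covariance, n_used = nrow(d),
                 converged = fit$converged, iterations = fit$iter,
                 boundary_fitted = boundary, glm = fit, data = d,
                 weights = w, terms = terms, outcome = outcome,
                 outcome_scale = outcome_scale, weighted = use_weights,
                 vcov_type = vcov_type, formula = f),
            class = "qb_fit")
}

#' @export
coef.qb_fit <- function(object, ...) object$coefficients

#' @export
vcov.qb_fit <- function(object, ...) object$covariance

#' @export
print.qb_fit <- function(x, ...) {
  cat(sprintf(
    "Quasibinomial logit fit: %s ~ %s\n  n = %d, dispersion = %.3f, %s covariance, converged: %s (%d iter)\n",
    x$outcome, paste(x$terms, collapse = " + "), x$n_used, x$dispersion,
    x$vcov_type, x$converged, x$iterations))
  se <- sqrt(diag(x$covariance))
  print(cbind(estimate = x$coefficients, se = se,
              z = x$coefficients / se))
  invisible(x)
}

#' Average marginal effects with delta-method standard errors
#'
#' For each categorical model term, the average marginal effect (AME) of a
#' non-reference level is the mean over the estimation records of the
#' fitted-probability contrast between that level and the reference,
#' holding every other covariate at its observed value; for a numeric
#' term it is the mean derivative of the fitted probability (central
#' difference, step `1e-6`). Means are weighted when the fit is weighted.
#' Standard errors come from the delta method: the Jacobian of each AME
#' with respect to the coefficients is computed by central finite
#' differences (step `1e-6`) and propagated through the fit's covariance;
#' p-values are two-sided normal.
#'
#' @param fit A [fit_quasibinomial()] result.
#' @param terms Subset of the fit's terms (default: all).
#' @return Tibble: `term`, `level` (contrast label, `"<level> - <ref>"`
#'   for factors, `"dy/dx"` for numeric terms), `ame` (proportion scale),
#'   `se`, `z`, `p_value`.
#' @export
average_marginal_effects <- function(fit, terms = NULL) {
  stopifnot(inherits(fit, "qb_fit"))
  if (is.null(terms)) terms <- fit$terms
  bad <- setdiff(terms, fit$terms)
  if (length(bad) > 0) {
    stop("term(s) not in the model: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d <- fit$data
  w <- fit$weights / sum(fit$weights)
  beta <- fit$coefficients

  ame_fun <- function(b, term, level = NULL) {
    if (!is.null(level)) {
      d1 <- d; d1[[term]][] <- level
      d0 <- d; d0[[term]][] <- levels(d[[term]])[1]
      X1 <- model.matrix(fit$formula, d1)
      X0 <- model.matrix(fit$formula, d0)
      sum(w * (plogis(X1 %*% b) - plogis(X0 %*% b)))
    } else {
      h <- 1e-6
      d1 <- d; d1[[term]] <- d1[[term]] + h / 2
      d0 <- d; d0[[term]] <- d0[[term]] - h / 2
      X1 <- model.matrix(fit$formula, d1)
      X0 <- model.matrix(fit$formula, d0)
      sum(w * (plogis(X1 %*% b) - plogis(X0 %*% b))) / h
    }
  }

  delta_se <- function(term, level) {
    h <- 1e-6
    jac <- vapply(seq_along(beta), function(j) {
      bp <- beta; bp[j] <- bp[j] + h
      bm <- beta; bm[j] <- bm[j] - h
      (ame_fun(bp, term, level) - ame_fun(bm, term, level)) / (2 * h)
    }, numeric(1))
    sqrt(drop(t(jac) %*% fit$covariance %*% jac))
  }

  rows <- purrr::map_dfr(terms, function(tm) {
    if (is.factor(d[[tm]])) {
      lev <- levels(d[[tm]])
      purrr::map_dfr(lev[-1], function(lv) {
        tibble::tibble(term = tm,
                       level = paste(lv, "-", lev[1]),
                       ame = ame_fun(beta, tm, lv),
                       se = delta_se(tm, lv))
      })
    } else {
      tibble::tibble(term = tm, level = "dy/dx",
                     ame = ame_fun(beta, tm), se = delta_se(tm, NULL))
    }
  })
  rows %>%
    dplyr::mutate(z = .data$ame / .data$se,
                  p_value = 2 * pnorm(-abs(.data$z)))
}
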