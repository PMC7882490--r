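suppressPackageStartupMessages(library(dplyr))

# Independent oracles used across the suite. These deliberately share no
# code with the package: the IRLS oracle is a textbook Fisher-scoring loop,
# the t oracles are the closed-form formulas.

# quasibinomial logit IRLS from first principles
irls_oracle <- function(X, y, w = rep(1, length(y)), tol = 1e-12,
                        maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    beta_new <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}

# pooled-variance two-sample t-test p-value
pooled_t_p <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  ss <- function(g) if (length(g) > 1) (length(g) - 1) * var(g) else 0
  sp2 <- (ss(g1) + ss(g2)) / (n1 + n2 - 2)
  t <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), n1 + n2 - 2)
}

# paired t statistic from the definition
paired_t_stat <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# small survey fixture with known structure, built in code
small_survey <- function(n = 60, seed = 101, waves = c(1L, 2L)) {
  cfg <- generator_config(
    n_per_wave = c(if (1L %in% waves) n else 0L,
                   if (2L %in% waves) n else 0L),
    seed = seed)
  generate_survey(cfg)$table
}

# two-covariate regression fixture with survey-style weights
reg_acceptance_fixture <- function(n, seed) {
  set.seed(seed)
  d <- tibble::tibble(
    x1 = rnorm(n),
    x2 = factor(sample(c("a", "b"), n, replace = TRUE)),
    weight = runif(n, 0.5, 2))
  eta <- -0.3 + 0.8 * d$x1 + 0.5 * (d$x2 == "b")
  d$y100 <- 100 * plogis(eta + rnorm(n, 0, 0.8))
  d
}

# generator configuration for a single heaped item with no covariate
# effects and no missingness: the study conditions of the heaping
# recovery checks (wave-1 moments of the own-risk item)
single_item_config <- function(n, pi50, seed, mean = 0.345, sd = 0.265) {
  precision <- mean * (1 - mean) / sd^2 - 1
  items <- tibble::tibble(
    item = "q2_own_risk", scale = 100, mean = mean, precision = precision,
    pi50 = pi50, b_male = 0, b_age = 0, b_tier = 0, wave_shift = 0)
  generator_config(n_per_wave = c(n, 0L), seed = seed, items = items,
                   missingness = default_missingness()[0, ])
}
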