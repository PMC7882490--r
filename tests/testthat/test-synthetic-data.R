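test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(margins = list(gender = c(f = 0.6, m = 0.5))),
               "sum to 1")
  bad_items <- default_item_params()
  bad_items$precision[1] <- -1
  expect_error(generator_config(items = bad_items), "precision")
  bad_items <- default_item_params()
  bad_items$pi50[1] <- 1
  expect_error(generator_config(items = bad_items), "pi50")
})

test_that("identical seed gives an identical table; n = 0 gives an empty one", {
  a <- generate_survey(generator_config(n_per_wave = c(50L, 40L), seed = 9))
  b <- generate_survey(generator_config(n_per_wave = c(50L, 40L), seed = 9))
  expect_identical(a$table, b$table)
  cfg0 <- generator_config(n_per_wave = c(0L, 0L), seed = 1)
  expect_identical(nrow(generate_survey(cfg0)$table), 0L)
})

test_that("item means match the configured latent mean at large n", {
  # pi50 = 0, no missingness, mean 0.35 -> empirical mean within 3 SE of 35
  cfg <- single_item_config(n = 1e5, pi50 = 0, seed = 5, mean = 0.35)
  x <- generate_survey(cfg)$table$q2_own_risk
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 35), max(3 * se, 0.5))
})

test_that("exact-50 share matches the heap mass plus the beta rounding cell", {
  cfg <- single_item_config(n = 2e4, pi50 = 0.15, seed = 6)
  x <- generate_survey(cfg)$table$q2_own_risk
  it <- cfg$items
  a <- it$mean * it$precision
  b <- (1 - it$mean) * it$precision
  cell <- pbeta(0.505, a, b) - pbeta(0.495, a, b)
  p50 <- 0.15 + (1 - 0.15) * cell
  se <- sqrt(p50 * (1 - p50) / length(x))
  expect_lt(abs(mean(x == 50) - p50), 3 * se)
})

test_that("configured wave shifts are recovered from wave mean differences", {
  items <- default_item_params()
  items$pi50 <- 0  # isolate the shift mechanism from heaping distortion
  cfg <- generator_config(n_per_wave = c(4000L, 4000L), seed = 11,
                          items = items)
  tab <- generate_survey(cfg)$table
  s <- summarize_items(tab)
  for (it in c("q2_own_risk", "q4_prevalence")) {
    shift <- items$wave_shift[items$item == it]
    si <- s[s$item == it, ]
    obs <- si$mean[si$wave == 2] - si$mean[si$wave == 1]
    se <- sqrt(sum(si$sd^2 / si$n_present))
    expect_lt(abs(obs - shift), 3 * se, label = it)
  }
})

test_that("weights are positive, mean 1, and reproduce the target margins", {
  cfg <- generator_config(n_per_wave = c(1005L, 0L), seed = 3)
  tab <- generate_survey(cfg)$table
  expect_true(all(tab$weight > 0))
  expect_equal(mean(tab$weight), 1)
  m <- cfg$margins
  target <- outer(m$gender, m$age_category)
  got <- tapply(tab$weight / nrow(tab),
                list(factor(tab$gender, names(m$gender)),
                     factor(tab$age_category, names(m$age_category))),
                sum)
  nonempty <- !is.na(got)
  # weighted cell mass equals the product target exactly on non-empty cells,
  # up to the mean-1 normalization constant
  ratio <- got[nonempty] / target[nonempty]
  expect_lt(diff(range(ratio)), 1e-10)
})

test_that("missingness rates are honored and wave-1-only items blank in wave 2", {
  cfg <- generator_config(n_per_wave = c(5000L, 200L), seed = 13)
  tab <- generate_survey(cfg)$table
  w1 <- tab[tab$wave == 1, ]
  rate <- mean(is.na(w1$q1_ifr))
  target <- 280 / 1005
  expect_lt(abs(rate - target),
            3 * sqrt(target * (1 - target) / nrow(w1)))
  w2 <- tab[tab$wave == 2, ]
  expect_true(all(is.na(w2$q1bis_flu_ifr)))
  expect_true(all(is.na(w2$health_status)))
})

test_that("stratum counts follow the binomial cascade and recover the IFR", {
  strata <- tibble::tibble(stratum = "all", population = 1e6L,
                           prevalence = 0.001, ifr = 0.1)
  ifrs <- vapply(1:200, function(s) {
    counts <- generate_stratum_counts(strata, seed = s)
    counts$deaths / counts$diagnosed
  }, numeric(1))
  se <- sd(ifrs) / sqrt(length(ifrs))
  expect_lt(abs(mean(ifrs) - 0.1), 3 * se)

  zero <- generate_stratum_counts(
    tibble::tibble(stratum = "none", population = 100L, prevalence = 0,
                   ifr = 0.5), seed = 1)
  expect_identical(zero$diagnosed, 0L)
  expect_identical(zero$deaths, 0L)

  expect_error(generate_stratum_counts(
    tibble::tibble(stratum = "x", population = 10L, prevalence = 1.5,
                   ifr = 0.1), seed = 1), "config error")
})

test_that("a quarantined-ship-sized stratum yields the expected diagnosed count", {
  strata <- tibble::tibble(stratum = "ship", population = 3711L,
                           prevalence = 0.19, ifr = 0.01)
  diag <- vapply(1:100, function(s) {
    generate_stratum_counts(strata, seed = s)$diagnosed
  }, integer(1))
  expected <- 3711 * 0.19  # ~705
  se_mean <- sqrt(3711 * 0.19 * 0.81) / sqrt(100)
  expect_lt(abs(mean(diag) - expected), 3 * se_mean)
})
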