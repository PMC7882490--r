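make_pair_table <- function(a, b, wave = 1L) {
  tab <- small_survey(n = length(a), waves = wave)
  tab$q1_ifr <- a
  tab$q4_prevalence <- b
  tab
}

test_that("paired test matches the closed-form t on tiny fixtures", {
  # a = {1,2,3}, b = {0,0,0}: dbar = 2, sd = 1, t = 2*sqrt(3)
  tab <- make_pair_table(c(1, 2, 3), c(0, 0, 0))
  r <- paired_test(tab, "q1_ifr", "q4_prevalence")
  expect_equal(r$t_statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-2 * sqrt(3), 2), tolerance = 1e-12)
  expect_equal(r$mean_difference, 2)
  expect_equal(r$n_pairs, 3L)
  expect_equal(r$t_statistic, paired_t_stat(c(1, 2, 3), c(0, 0, 0)))
})

test_that("identical vectors give zero difference and two-sided p = 1", {
  tab <- make_pair_table(c(4, 7, 9, 2), c(4, 7, 9, 2))
  r <- paired_test(tab, "q1_ifr", "q4_prevalence")
  expect_equal(r$mean_difference, 0)
  expect_equal(r$p_value, 1)
})

test_that("two-sided p equals twice the smaller one-sided p", {
  set.seed(41)
  for (i in 1:5) {
    tab <- make_pair_table(round(runif(30, 0, 100)), round(runif(30, 0, 100)))
    p2 <- paired_test(tab, "q1_ifr", "q4_prevalence")$p_value
    plt <- paired_test(tab, "q1_ifr", "q4_prevalence",
                       "one_sided_a_lt_b")$p_value
    pgt <- paired_test(tab, "q1_ifr", "q4_prevalence",
                       "one_sided_a_gt_b")$p_value
    expect_equal(p2, 2 * min(plt, pgt), tolerance = 1e-12)
  }
})

test_that("listwise deletion and the minimum-pairs error are honored", {
  tab <- make_pair_table(c(1, 2, NA, 4), c(0, NA, 3, 1))
  r <- paired_test(tab, "q1_ifr", "q4_prevalence")
  expect_equal(r$n_pairs, 2L)
  tab2 <- make_pair_table(c(1, NA), c(NA, 2))
  expect_error(paired_test(tab2, "q1_ifr", "q4_prevalence"),
               "insufficient data")
})

test_that("pair classification counts higher/equal/lower with tolerance", {
  tab <- make_pair_table(c(5, 3, 1), c(1, 3, 5))
  r <- classify_pairs(tab, "q1_ifr", "q4_prevalence")
  expect_equal(unlist(r[c("n_higher", "n_equal", "n_lower")]),
               c(n_higher = 1L, n_equal = 1L, n_lower = 1L))
  expect_equal(r$n_higher + r$n_equal + r$n_lower, r$n_pairs)

  same <- make_pair_table(c(2, 2, 2), c(2, 2, 2))
  expect_equal(classify_pairs(same, "q1_ifr", "q4_prevalence")$n_equal, 3L)

  wide <- classify_pairs(tab, "q1_ifr", "q4_prevalence", tolerance = 4)
  expect_equal(wide$n_equal, 3L)

  # counts invariant under joint permutation of pairs
  perm <- make_pair_table(c(1, 5, 3), c(5, 1, 3))
  expect_equal(classify_pairs(perm, "q1_ifr", "q4_prevalence"), r)
})

test_that("no-intercept slope matches the normal-equation formula", {
  # x = {1,2}, y = {2,3}: slope = 8/5
  tab <- small_survey(n = 2, waves = 1L)
  tab$q7_contagious <- c(2L, 3L)
  tab$q7bis_contagious_flu <- c(1L, 2L)
  r <- proportional_slope(tab, "q7_contagious", "q7bis_contagious_flu")
  expect_equal(r$slope, 8 / 5, tolerance = 1e-12)

  # y = c * x exactly -> slope c, SE 0
  tab2 <- small_survey(n = 5, waves = 1L)
  tab2$q7bis_contagious_flu <- 1:5
  for (c_true in c(0.5, 2)) {
    tab2$q7_contagious <- c_true * tab2$q7bis_contagious_flu
    r2 <- proportional_slope(tab2, "q7_contagious", "q7bis_contagious_flu")
    expect_equal(r2$slope, c_true, tolerance = 1e-12)
    expect_equal(r2$standard_error, 0, tolerance = 1e-10)
  }

  tab2$q7bis_contagious_flu <- 0L
  expect_error(proportional_slope(tab2, "q7_contagious",
                                  "q7bis_contagious_flu"),
               "undefined slope")
})

test_that("fold difference reproduces the reproduction-number comparison", {
  expect_equal(round(fold_difference(1.78, 1.3), 2), 1.37)
  expect_error(fold_difference(1, 0))
})

test_that("stratified gaps equal mean belief minus benchmark prevalence", {
  tab <- small_survey(n = 200, waves = 1L)
  bench <- compute_rates(tibble::tibble(
    region_tier = c("lowest", "medium", "highest"),
    deaths = c(0, 0, 0), diagnosed = c(47, 80, 180),
    population = c(1e5, 1e5, 1e5)))
  g <- stratified_gap(tab, "q2_own_risk", bench, "region_tier")
  ok <- !is.na(tab$q2_own_risk)
  hand <- tapply(tab$q2_own_risk[ok], tab$region_tier[ok], mean)
  expect_equal(g$mean_belief, as.vector(hand[g$stratum]))
  expect_equal(g$gap, g$mean_belief - g$benchmark_prevalence)
  expect_true(all(g$comparable))

  # survey stratum missing from the benchmark is listed as uncomparable
  g2 <- stratified_gap(tab, "q2_own_risk", bench[1:2, ], "region_tier")
  expect_false(g2$comparable[g2$stratum == "highest"])
  expect_true(is.na(g2$gap[g2$stratum == "highest"]))
})

test_that("gaps vanish when belief means are generated equal to benchmarks", {
  # one tier, belief mean generated at 35 points, benchmark prevalence 35
  cfg <- single_item_config(n = 4000, pi50 = 0, seed = 55, mean = 0.35)
  tab <- generate_survey(cfg)$table
  bench <- compute_rates(tibble::tibble(
    region_tier = tier_levels(), deaths = 0,
    diagnosed = c(35000, 35000, 35000), population = c(1e5, 1e5, 1e5)))
  g <- stratified_gap(tab, "q2_own_risk", bench, "region_tier")
  se <- 26.5 / sqrt(min(g$n))
  expect_true(all(abs(g$gap) < 3 * se))
})
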