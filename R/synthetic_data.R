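#' Configuration of the synthetic survey generator
#'
#' Defines the generating process for a two-wave belief survey: demographic
#' margins, per-item beta laws on the latent (0,1) scale with covariate
#' effects on the logit of the mean, a point mass of exact "50" answers
#' (heaping), item-level missingness rates per wave, wave shifts on the
#' native item scale, and post-stratification weights. The defaults
#' reproduce the study conditions of the two French lockdown surveys:
#' sample sizes 1005 and 1004, the published demographic margins, item
#' means/SDs matched by beta moments, missingness at the published per-item
#' rates, a +11.5-point wave shift for own risk (q2) and a -11.1-point
#' shift for expected prevalence (q4).
#'
#' @param n_per_wave Integer vector of length 2, respondents per wave.
#' @param seed Integer seed; identical configuration and seed give an
#'   identical table.
#' @param margins Named list of demographic margins (named probability
#'   vectors summing to 1); see [default_margins()].
#' @param items Item parameter tibble; see [default_item_params()].
#' @param missingness Tibble `item`, `wave`, `rate`; see
#'   [default_missingness()]. Items absent from the tibble get rate 0.
#' @param heap_anchor Value at which heaped responses are placed
#'   (native 0-100 scale).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_wave = c(1005L, 1004L), seed = 1L,
                             margins = default_margins(),
                             items = default_item_params(),
                             missingness = default_missingness(),
                             heap_anchor = 50) {
  stopifnot(length(n_per_wave) == 2, all(n_per_wave >= 0),
            length(seed) == 1, is.finite(seed))
  for (m in names(margins)) {
    if (abs(sum(margins[[m]]) - 1) > 1e-9) {
      stop("margin '", m, "' must sum to 1", call. = FALSE)
    }
    if (any(margins[[m]] < 0)) stop("negative margin in '", m, "'")
  }
  if (any(items$precision <= 0)) {
    stop("config error: beta precision must be > 0", call. = FALSE)
  }
  if (any(items$mean <= 0 | items$mean >= 1)) {
    stop("config error: latent item means must lie in (0,1)", call. = FALSE)
  }
  if (any(items$pi50 < 0 | items$pi50 >= 1)) {
    stop("config error: heaping mass pi50 must lie in [0,1)", call. = FALSE)
  }
  if (any(missingness$rate < 0 | missingness$rate > 1)) {
    stop("config error: missingness rates must lie in [0,1]", call. = FALSE)
  }
  structure(list(n_per_wave = as.integer(n_per_wave), seed = as.integer(seed),
                 margins = margins, items = items,
                 missingness = missingness, heap_anchor = heap_anchor),
            class = "generator_config")
}

#' Default demographic margins
#'
#' Wave-1 sample margins of the study population: gender, seven age bands,
#' marital status, three education levels, five labor-market statuses and
#' income (with explicit item nonresponse as a category). Region incidence
#' tiers use approximate metropolitan population shares of the three tier
#' groups, which the source tables do not print.
#'
#' @return Named list of named probability vectors.
#' @export
default_margins <- function() {
  list(
    gender = c(female = 0.524, male = 0.476),
    age_category = setNames(
      c(0.023, 0.121, 0.190, 0.173, 0.184, 0.139, 0.170), age_levels()),
    marital = c(single = 0.317, couple = 0.683),
    education = setNames(c(0.510, 0.154, 0.336), education_levels()),
    labor_status = setNames(c(0.417, 0.351, 0.102, 0.055, 0.075),
                            labor_levels()),
    income = c(low = 341 / 1005, middle = 412 / 1005, high = 130 / 1005,
               missing = 122 / 1005),
    region_tier = c(lowest = 0.34, medium = 0.39, highest = 0.27)
  )
}

#' Default item generating parameters
#'
#' One row per item: latent beta mean and precision (`a = mean *
#' precision`, `b = (1 - mean) * precision`) matched by moments to the
#' published wave-1 means and SDs; heaping mass `pi50` set from the
#' published excess-50 percentages (0-100 items only); covariate effects
#' on the logit of the beta mean (`b_male` for male vs female, `b_age` per
#' age band away from the 40-49 center, `b_tier` per incidence-tier step
#' away from medium), small values with the signs the study reports; and
#' the wave-2 shift in mean on the native scale (+11.5 points for own
#' risk, -11.1 for expected prevalence, +18 weeks for expected duration).
#'
#' @return Tibble with columns `item`, `scale`, `mean`, `precision`,
#'   `pi50`, `b_male`, `b_age`, `b_tier`, `wave_shift`.
#' @export
default_item_params <- function() {
  p <- function(item, scale, mean, sd, pi50 = 0, b_male = 0, b_age = 0,
                b_tier = 0, wave_shift = 0) {
    precision <- mean * (1 - mean) / sd^2 - 1
    tibble::tibble(item = item, scale = scale, mean = mean,
                   precision = precision, pi50 = pi50, b_male = b_male,
                   b_age = b_age, b_tier = b_tier, wave_shift = wave_shift)
  }
  dplyr::bind_rows(
    p("q1_ifr", 100, 0.165, 0.222, pi50 = 0, b_male = -0.15, b_age = -0.05),
    p("q1bis_flu_ifr", 100, 0.127, 0.205),
    p("q2_own_risk", 100, 0.345, 0.265, pi50 = 0.12, b_male = -0.05,
      b_age = -0.05, b_tier = 0.10, wave_shift = 11.5),
    p("q3_others_risk", 100, 0.479, 0.239, pi50 = 0.15, b_tier = 0.05),
    p("q4_prevalence", 100, 0.450, 0.251, pi50 = 0.02, b_male = -0.15,
      b_age = -0.05, wave_shift = -11.1),
    p("q5_relative_risk", 10, 0.560, 0.237),
    p("q6_worry", 10, 0.606, 0.264),
    p("q7_contagious", 10, 0.817, 0.186),
    p("q7bis_contagious_flu", 10, 0.674, 0.198),
    p("q8_serious", 10, 0.815, 0.184),
    p("q8bis_serious_flu", 10, 0.648, 0.204),
    p("expected_duration_weeks", 52, 0.251, 0.174, wave_shift = 18)
  )
}

#' Default per-item missingness rates
#'
#' Published counts of missing answers per item and wave, expressed as
#' rates of the wave sample sizes (1005 and 1004). Wave-1-only items carry
#' no wave-2 row; the generator sets them fully missing in wave 2.
#'
#' @return Tibble `item`, `wave`, `rate`.
#' @export
default_missingness <- function() {
  m <- function(item, n1, n2 = NA) {
    out <- tibble::tibble(item = item, wave = 1L, rate = n1 / 1005)
    if (!is.na(n2)) {
      out <- dplyr::bind_rows(
        out, tibble::tibble(item = item, wave = 2L, rate = n2 / 1004))
    }
    out
  }
  dplyr::bind_rows(
    m("q1_ifr", 280, 263), m("q1bis_flu_ifr", 347),
    m("q2_own_risk", 291, 274), m("q3_others_risk", 373, 381),
    m("q4_prevalence", 276, 308), m("q5_relative_risk", 175, 69),
    m("q6_worry", 58, 39), m("q7_contagious", 59, 44),
    m("q7bis_contagious_flu", 96), m("q8_serious", 39, 51),
    m("q8bis_serious_flu", 75), m("confidence_q2", 291),
    m("confidence_q3", 373), m("chronic_illness", 30)
  )
}

#' Generate a two-wave synthetic survey table
#'
#' Demographics are drawn independently from the configured margins. For
#' each item present on a respondent, the response equals the heap anchor
#' (50) with probability `pi50`, otherwise `scale * X` with
#' `X ~ Beta(a, b)` where `logit(mean)` is the respondent's linear
#' predictor; in wave 2 the configured wave shift (points on the native
#' scale) is added to the beta mean directly, so the shift in the
#' generated item mean equals the configured value by construction.
#' Responses are rounded to integers. Missingness is applied
#' independently per item at the configured rates (MCAR). Weights are
#' computed by post-stratification on gender x age cells against the
#' configured margins and normalized to mean 1.
#'
#' @param config A [generator_config()].
#' @return A list with `table` (validated survey tibble) and `params`
#'   (class `true_params`: the realized generating values, for recovery
#'   tests).
#' @export
generate_survey <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  waves <- purrr::map(1:2, function(wv) {
    generate_wave(config$n_per_wave[wv], wv, config)
  })
  table <- dplyr::bind_rows(waves)
  params <- structure(
    list(seed = config$seed, n_per_wave = config$n_per_wave,
         margins = config$margins, items = config$items,
         missingness = config$missingness,
         heap_anchor = config$heap_anchor),
    class = "true_params")
  if (nrow(table) > 0) table <- validate_survey(table)
  list(table = table, params = params)
}

generate_wave <- function(n, wave, config) {
  cb <- default_codebook()
  if (n == 0) {
    empty <- purrr::map(seq_len(nrow(cb)), function(i) {
      switch(cb$type[i], id = character(), integer = integer(),
             numeric = numeric(), categorical = character(),
             logical = logical())
    })
    return(tibble::as_tibble(setNames(empty, cb$column)))
  }
  mg <- config$margins
  draw <- function(m) sample(names(m), n, replace = TRUE, prob = m)
  tab <- tibble::tibble(
    respondent_id = sprintf("w%d_%05d", wave, seq_len(n)),
    wave = as.integer(wave),
    gender = draw(mg$gender),
    age_category = draw(mg$age_category),
    marital = draw(mg$marital),
    education = draw(mg$education),
    labor_status = draw(mg$labor_status),
    income = draw(mg$income),
    region_tier = draw(mg$region_tier)
  )
  tab$weight <- poststratify_weights(tab, mg)

  age_idx <- match(tab$age_category, age_levels())
  tier_idx <- match(tab$region_tier, tier_levels())
  male <- as.numeric(tab$gender == "male")

  for (i in seq_len(nrow(config$items))) {
    it <- config$items[i, ]
    lp <- qlogis(it$mean) +
      it$b_male * male + it$b_age * (age_idx - 4) +
      it$b_tier * (tier_idx - 2)
    mu <- plogis(lp)
    if (wave == 2 && it$wave_shift != 0) {
      # shift is stated in points on the native scale: apply it to the
      # mean directly so the configured shift is exact by construction
      mu <- pmin(pmax(mu + it$wave_shift / it$scale, 0.005), 0.995)
    }
    x <- round(it$scale * rbeta(n, mu * it$precision,
                                (1 - mu) * it$precision))
    if (it$pi50 > 0) {
      heap <- runif(n) < it$pi50
      x[heap] <- config$heap_anchor
    }
    if (it$item %in% c("q5_relative_risk", "q6_worry", "q7_contagious",
                       "q7bis_contagious_flu", "q8_serious",
                       "q8bis_serious_flu")) {
      x <- as.integer(x)
    }
    tab[[it$item]] <- x
  }

  # items not in the config (custom subsets) exist as all-missing columns
  for (col in setdiff(item_columns(), names(tab))) {
    tab[[col]] <- if (col %in% item_columns(10)) NA_integer_ else NA_real_
  }

  # categorical / logical extras, distributions matching the wave-1 sample
  tab$confidence_q2 <- sample(confidence_levels(), n, replace = TRUE,
                              prob = c(0.063, 0.301, 0.539, 0.063, 0.034))
  tab$confidence_q3 <- sample(confidence_levels(), n, replace = TRUE,
                              prob = c(0.050, 0.278, 0.556, 0.102, 0.014))
  tab$health_status <- sample(c("very_good", "good", "bad_or_very_bad"), n,
                              replace = TRUE, prob = c(0.208, 0.656, 0.136))
  tab$chronic_illness <- runif(n) < 0.297
  tab$diagnosed_covid <- runif(n) < if (wave == 1) 0.011 else 0.028
  tab$relative_ill <- runif(n) < if (wave == 1) 0.243 else 0.257

  # MCAR missingness per item, then blank wave-1-only items in wave 2
  miss <- config$missingness[config$missingness$wave == wave, ]
  for (j in seq_len(nrow(miss))) {
    col <- miss$item[j]
    if (!col %in% names(tab)) next
    tab[[col]][runif(n) < miss$rate[j]] <- NA
  }
  if (wave == 2) {
    w1_only <- cb$column[!vapply(cb$waves, function(w) 2L %in% w, logical(1))]
    for (col in w1_only) tab[[col]] <- tab[[col]][NA]
  }
  tab[cb$column]
}

#' Post-stratification weights on gender x age cells
#'
#' Cell weight = target proportion / observed proportion, where the target
#' is the product of the configured gender and age margins; weights are
#' normalized to mean 1. With these weights the weighted gender x age cell
#' proportions equal the target exactly (for non-empty cells).
#'
#' @param tab Data frame with `gender` and `age_category`.
#' @param margins Named list with `gender` and `age_category` margins.
#' @return Numeric vector of positive weights, mean 1.
#' @export
poststratify_weights <- function(tab, margins = default_margins()) {
  n <- nrow(tab)
  if (n == 0) return(numeric())
  target <- outer(margins$gender, margins$age_category)
  cell_g <- match(tab$gender, names(margins$gender))
  cell_a <- match(tab$age_category, names(margins$age_category))
  obs <- table(factor(cell_g, seq_along(margins$gender)),
               factor(cell_a, seq_along(margins$age_category))) / n
  w <- target[cbind(cell_g, cell_a)] / pmax(obs[cbind(cell_g, cell_a)], 1e-12)
  w / mean(w)
}

#' Generate a stratified count table from true rates
#'
#' Inverts the benchmark computation: given per-stratum populations, true
#' prevalence and true infection fatality ratio, draws
#' `diagnosed ~ Binomial(population, prevalence)` then
#' `deaths ~ Binomial(diagnosed, ifr)`.
#'
#' @param strata Tibble with one row per stratum: arbitrary key columns
#'   plus `population` (positive integers), `prevalence` and `ifr` (both
#'   in `[0, 1]`).
#' @param seed Integer seed.
#' @param date_label Text label recorded on every row.
#' @return The input key columns plus `deaths`, `diagnosed`, `population`
#'   and `date_label` — a valid input to [compute_rates()].
#' @export
generate_stratum_counts <- function(strata, seed = 1L,
                                    date_label = "synthetic") {
  stopifnot(all(c("population", "prevalence", "ifr") %in% names(strata)))
  if (any(strata$prevalence < 0 | strata$prevalence > 1) ||
      any(strata$ifr < 0 | strata$ifr > 1)) {
    stop("config error: prevalence and ifr must lie in [0,1]", call. = FALSE)
  }
  stopifnot(all(strata$population > 0),
            all(strata$population == round(strata$population)))
  set.seed(seed)
  diagnosed <- rbinom(nrow(strata), strata$population, strata$prevalence)
  deaths <- rbinom(nrow(strata), diagnosed, strata$ifr)
  strata %>%
    dplyr::mutate(deaths = deaths, diagnosed = diagnosed,
                  date_label = date_label) %>%
    dplyr::select(-dplyr::all_of(c("prevalence", "ifr")))
}

#' Generator-implied true excess-50 for an item
#'
#' The estimand of [excess_fifty()] under the generator: the probability
#' that an integer response falls in the 45-55 window minus the window
#' mass of the uncontaminated beta law, i.e.
#' `100 * pi50 * (1 - m)` with `m` the beta mass of the rounding-corrected
#' window. Used by recovery tests and the acceptance script.
#'
#' @param mean,precision Latent beta parameters (population values, i.e.
#'   at the reference covariates the caller generated with).
#' @param pi50 Heaping mass.
#' @return True excess, in percentage points.
#' @export
true_excess_fifty <- function(mean, precision, pi50) {
  a <- mean * precision
  b <- (1 - mean) * precision
  m <- pbeta(0.555, a, b) - pbeta(0.445, a, b)
  100 * pi50 * (1 - m)
}
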