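#' Objective rates from a stratified count table
#'
#' Computes, per stratum, the infection fatality ratio (IFR) as deaths
#' over diagnosed cases and the prevalence as diagnosed cases over
#' population, both per 100. With hospital-only diagnoses the IFR is an
#' upper bound of the population IFR and the prevalence a lower bound of
#' the population infection risk; the functions make no adjustment.
#'
#' @param counts Tibble with columns `deaths`, `diagnosed`, `population`
#'   (any other columns are carried through as stratum keys).
#' @return The input plus `ifr_pct` (`NA` when `diagnosed == 0`, flagged
#'   by `ifr_defined`) and `prevalence_per100`.
#' @export
#' @examples
#' compute_rates(tibble::tibble(stratum = "ship", deaths = 7,
#'                              diagnosed = 705, population = 3711))
compute_rates <- function(counts) {
  check_counts(counts)
  counts %>%
    dplyr::mutate(
      ifr_defined = .data$diagnosed > 0,
      ifr_pct = ifelse(.data$diagnosed > 0,
                       100 * .data$deaths / .data$diagnosed, NA_real_),
      prevalence_per100 = 100 * .data$diagnosed / .data$population
    )
}

check_counts <- function(counts) {
  need <- c("deaths", "diagnosed", "population")
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    stop("count table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- with(counts, deaths < 0 | deaths > diagnosed |
                diagnosed > population)
  if (any(bad)) {
    stop("input error: need 0 <= deaths <= diagnosed <= population; ",
         "violated in row(s) ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  invisible(counts)
}

#' Odds ratios of strata against a reference stratum
#'
#' Expresses each stratum's rate relative to a reference case (the
#' prototypical lowest-risk stratum) as a true odds ratio on the
#' proportion scale: `OR(s) = [p_s / (1 - p_s)] / [p_ref / (1 - p_ref)]`
#' with `p` the rate divided by 100. The reference maps to exactly 1. At
#' the small rates typical of these tables OR and rate ratio nearly
#' coincide.
#'
#' @param bench Output of [compute_rates()].
#' @param reference Value of `stratum_col` identifying the reference row.
#' @param measure `"prevalence"` or `"ifr"`.
#' @param stratum_col Name of the column labelling strata.
#' @return Tibble `stratum`, `rate`, `odds_ratio` (`NA`, flagged by
#'   `or_defined`, where the rate is 100 or undefined).
#' @export
odds_ratio_table <- function(bench, reference,
                             measure = c("prevalence", "ifr"),
                             stratum_col = "stratum") {
  measure <- match.arg(measure)
  stopifnot(stratum_col %in% names(bench))
  rate <- bench[[if (measure == "ifr") "ifr_pct" else "prevalence_per100"]]
  labels <- bench[[stratum_col]]
  ref_i <- which(labels == reference)
  if (length(ref_i) != 1) {
    stop("reference stratum '", reference, "' not found exactly once",
         call. = FALSE)
  }
  p_ref <- rate[ref_i] / 100
  if (is.na(p_ref) || p_ref <= 0 || p_ref >= 1) {
    stop("reference stratum rate must be defined and in (0, 100)",
         call. = FALSE)
  }
  p <- rate / 100
  defined <- !is.na(p) & p < 1
  or <- ifelse(defined, (p / (1 - p)) / (p_ref / (1 - p_ref)), NA_real_)
  or[ref_i] <- 1
  tibble::tibble(stratum = labels, rate = rate, odds_ratio = or,
                 or_defined = defined, reference = labels == reference)
}

#' Aggregate strata of a count table
#'
#' Sums deaths, diagnosed and population within groups (e.g. 13 raw
#' regions into 3 incidence tiers). Rates must always be recomputed from
#' the pooled counts, never averaged across strata; feeding the result to
#' [compute_rates()] does exactly that.
#'
#' @param counts Count table.
#' @param mapping Named character vector: names are values of
#'   `stratum_col`, values are group labels. Every observed stratum must
#'   be mapped.
#' @param stratum_col Column holding the stratum labels.
#' @return Count table with one row per group (column `stratum_col` now
#'   holds group labels).
#' @export
aggregate_strata <- function(counts, mapping, stratum_col = "stratum") {
  check_counts(counts)
  stopifnot(stratum_col %in% names(counts))
  labels <- counts[[stratum_col]]
  unmapped <- setdiff(unique(labels), names(mapping))
  if (length(unmapped) > 0) {
    stop("mapping error: unmapped stratum(s): ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  counts[[stratum_col]] <- unname(mapping[labels])
  counts %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(stratum_col))) %>%
    dplyr::summarise(deaths = sum(.data$deaths),
                     diagnosed = sum(.data$diagnosed),
                     population = sum(.data$population),
                     .groups = "drop")
}
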