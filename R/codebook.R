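#' Default survey codebook
#'
#' The codebook maps column names of a respondent-level survey table to
#' item definitions: storage type, valid range or level set, and the waves
#' in which the item was fielded. [read_survey()] validates every file
#' against a codebook, so a deposited dataset with different column names
#' can be absorbed by editing the `column` field rather than the code.
#'
#' Items are stored on their native scales (0-100 for the four belief
#' sliders, 0-10 for the opinion scales, 0-52 weeks for expected epidemic
#' duration); any rescaling to proportions happens in the analysis
#' functions. Missing responses are encoded as empty cells in files and as
#' `NA` in memory — never as a sentinel value inside the valid range.
#'
#' Several items were fielded in wave 1 only (the influenza replications
#' `q1bis_flu_ifr`, `q7bis_contagious_flu`, `q8bis_serious_flu`, the two
#' confidence ratings, self-rated health and chronic illness); wave-2
#' records may lack those, never the converse.
#'
#' @return A tibble with one row per column: `column`, `type` (`"id"`,
#'   `"integer"`, `"numeric"`, `"categorical"`, `"logical"`), `min`,
#'   `max`, `levels` (list-column of valid level sets), `waves`
#'   (list-column of wave numbers in which the item exists), `required`
#'   (must be non-missing for every record of the waves it belongs to).
#' @export
#' @examples
#' default_codebook()
default_codebook <- function() {
  cb <- function(column, type, min = NA_real_, max = NA_real_,
                 levels = list(NULL), waves = list(c(1L, 2L)),
                 required = FALSE) {
    tibble::tibble(column = column, type = type, min = min, max = max,
                   levels = levels, waves = waves, required = required)
  }
  dplyr::bind_rows(
    cb("respondent_id", "id", required = TRUE),
    cb("wave", "integer", 1, 2, required = TRUE),
    cb("gender", "categorical", levels = list(c("female", "male")),
       required = TRUE),
    cb("age_category", "categorical", levels = list(age_levels()),
       required = TRUE),
    cb("marital", "categorical", levels = list(c("single", "couple")),
       required = TRUE),
    cb("education", "categorical", levels = list(education_levels()),
       required = TRUE),
    cb("labor_status", "categorical", levels = list(labor_levels()),
       required = TRUE),
    cb("income", "categorical",
       levels = list(c("low", "middle", "high", "missing")),
       required = TRUE),
    cb("region_tier", "categorical", levels = list(tier_levels()),
       required = TRUE),
    cb("weight", "numeric", 1e-12, Inf, required = TRUE),
    cb("q1_ifr", "numeric", 0, 100),
    cb("q1bis_flu_ifr", "numeric", 0, 100, waves = list(1L)),
    cb("q2_own_risk", "numeric", 0, 100),
    cb("q3_others_risk", "numeric", 0, 100),
    cb("q4_prevalence", "numeric", 0, 100),
    cb("q5_relative_risk", "integer", 0, 10),
    cb("q6_worry", "integer", 0, 10),
    cb("q7_contagious", "integer", 0, 10),
    cb("q7bis_contagious_flu", "integer", 0, 10, waves = list(1L)),
    cb("q8_serious", "integer", 0, 10),
    cb("q8bis_serious_flu", "integer", 0, 10, waves = list(1L)),
    cb("confidence_q2", "categorical", levels = list(confidence_levels()),
       waves = list(1L)),
    cb("confidence_q3", "categorical", levels = list(confidence_levels()),
       waves = list(1L)),
    cb("expected_duration_weeks", "numeric", 0, 52),
    cb("health_status", "categorical",
       levels = list(c("very_good", "good", "bad_or_very_bad")),
       waves = list(1L)),
    cb("chronic_illness", "logical", waves = list(1L)),
    cb("diagnosed_covid", "logical"),
    cb("relative_ill", "logical")
  )
}

# level sets, in the order the descriptive tables list them (the first
# level is the reference level of downstream regressions)
age_levels <- function() {
  c("<=19", "20-29", "30-39", "40-49", "50-59", "60-69", "70+")
}
education_levels <- function() {
  c("below_high_school", "bachelor_or_higher", "high_school_to_below_bachelor")
}
labor_levels <- function() {
  c("inactive", "employee_private", "employee_public", "self_employed",
    "unemployed")
}
tier_levels <- function() c("lowest", "medium", "highest")
confidence_levels <- function() {
  c("very_high", "high", "moderate", "low", "very_low")
}

#' Names of the belief and opinion items
#'
#' @param scale Optional filter: `100` for the 0-100 sliders, `10` for the
#'   0-10 opinion scales, `52` for the expected-duration item.
#' @return Character vector of item column names.
#' @export
item_columns <- function(scale = NULL) {
  items <- c(
    q1_ifr = 100, q1bis_flu_ifr = 100, q2_own_risk = 100,
    q3_others_risk = 100, q4_prevalence = 100,
    q5_relative_risk = 10, q6_worry = 10, q7_contagious = 10,
    q7bis_contagious_flu = 10, q8_serious = 10, q8bis_serious_flu = 10,
    expected_duration_weeks = 52
  )
  if (is.null(scale)) return(names(items))
  names(items)[items == scale]
}

#' Map raw French metropolitan regions to incidence tiers
#'
#' Downstream analyses operate on three groups of regions by recorded
#' incidence: lowest (western regions), highest (the Paris region and the
#' north-east), and medium (the rest). Matching is tolerant to case,
#' accents, spaces and hyphens.
#'
#' @param region Character vector of region names.
#' @return Factor-like character vector with values `"lowest"`,
#'   `"medium"`, `"highest"`.
#' @export
#' @examples
#' region_to_tier(c("Bretagne", "Ile-de-France", "Corse"))
region_to_tier <- function(region) {
  norm <- function(x) {
    x <- tolower(x)
    x <- chartr("éèêîô", "eeeio", x)
    gsub("[^a-z]", "", x)
  }
  tiers <- c(
    normandie = "lowest", bretagne = "lowest", paysdelaloire = "lowest",
    nouvelleaquitaine = "lowest", occitanie = "lowest",
    hautsdefrance = "medium", bourgognefranchecomte = "medium",
    auvergnerhonealpes = "medium", corse = "medium",
    provencealpescotedazur = "medium", centrevaldeloire = "medium",
    iledefrance = "highest", grandest = "highest"
  )
  key <- norm(region)
  unknown <- unique(region[!key %in% names(tiers) & !is.na(region)])
  if (length(unknown) > 0) {
    stop("unknown region(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(tiers[key])
}
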