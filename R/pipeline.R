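#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; each stage derives its own substream seed so
#'   toggling stages does not change the results of the others.
#' @param stages Stages to run, in dependency order; any subset of
#'   `"simulate"`, `"summarize"`, `"benchmarks"`, `"heaping"`,
#'   `"calibrate"`, `"optimism"`, `"regress"`.
#' @param generator [generator_config()] used by the simulate stage (its
#'   seed is overridden by the simulate substream seed).
#' @param survey_path,counts_path Optional input files; required when the
#'   corresponding stage runs without `"simulate"`.
#' @param use_weights Named logical toggles per weighted stage
#'   (`summarize`, `optimism`, `regress`).
#' @param regress_outcome,regress_terms Model of the regress stage.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "summarize",
                                       "benchmarks", "heaping",
                                       "calibrate", "optimism", "regress"),
                            generator = generator_config(),
                            survey_path = NULL, counts_path = NULL,
                            use_weights = list(summarize = TRUE,
                                               optimism = TRUE,
                                               regress = TRUE),
                            regress_outcome = "q2_own_risk",
                            regress_terms = c("gender", "age_category",
                                              "region_tier", "wave")) {
  known <- c("simulate", "summarize", "benchmarks", "heaping",
             "calibrate", "optimism", "regress")
  stopifnot(all(stages %in% known), length(seed) == 1, is.finite(seed))
  for (p in c(survey_path, counts_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = stages[order(match(stages, known))],
                 generator = generator, survey_path = survey_path,
                 counts_path = counts_path, use_weights = use_weights,
                 regress_outcome = regress_outcome,
                 regress_terms = regress_terms),
            class = "run_config")
}

stage_seed <- function(seed, stage) {
  idx <- match(stage, c("simulate", "summarize", "benchmarks", "heaping",
                        "calibrate", "optimism", "regress"))
  (abs(seed) %% 20000000L) * 100L + idx
}

write_stage_table <- function(df, path, stage, seed) {
  writeLines(sprintf("# stage=%s seed=%d", stage, seed), path)
  suppressWarnings(readr::write_csv(df, path, na = "", append = TRUE,
                                    col_names = TRUE))
  invisible(path)
}

#' Run the survey analysis pipeline
#'
#' Executes the configured stages in dependency order: simulate (or load)
#' a survey table and stratum counts, then item summaries, objective
#' benchmarks with odds ratios, the heaping report, calibration
#' comparisons, optimism dynamics and the weighted regression with average
#' marginal effects. Every output table is a CSV whose first line names
#' the generating stage and its substream seed; identical configuration
#' and seed give byte-identical numeric outputs. A stage failure aborts
#' the stages downstream of it and is recorded in the run report.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `report` (tibble of stage statuses),
#'   `outputs` (named file paths) and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  state$outputs <- character()
  state$results <- list()
  report <- list()
  failed_upstream <- FALSE

  log_line <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "")
    msg
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(NULL)
    if (failed_upstream) {
      report[[stage]] <<- "skipped (upstream failure)"
      return(NULL)
    }
    res <- tryCatch({
      fun(stage_seed(config$seed, stage))
      report[[stage]] <<- "ok"
    }, error = function(e) {
      report[[stage]] <<- paste("failed:", conditionMessage(e))
      failed_upstream <<- TRUE
      log_line("stage %s failed: %s", stage, conditionMessage(e))
    })
    invisible(res)
  }
  out <- function(name) file.path(config$out_dir, name)
  emit <- function(df, name, stage, seed) {
    write_stage_table(df, out(name), stage, seed)
    state$outputs[name] <- out(name)
  }
  get_survey <- function() {
    if (!is.null(state$results$survey)) return(state$results$survey)
    if (is.null(config$survey_path)) {
      stop("no survey available: run the simulate stage or give survey_path")
    }
    state$results$survey <- read_survey(config$survey_path)
    state$results$survey
  }
  get_counts <- function() {
    if (!is.null(state$results$counts)) return(state$results$counts)
    if (is.null(config$counts_path)) {
      stop("no counts available: run the simulate stage or give counts_path")
    }
    state$results$counts <- readr::read_csv(
      config$counts_path, comment = "#", show_col_types = FALSE)
    state$results$counts
  }

  run_stage("simulate", function(seed) {
    gen <- config$generator
    gen$seed <- seed
    sim <- generate_survey(gen)
    state$results$survey <- sim$table
    state$results$true_params <- sim$params
    emit(sim$table, "survey.csv", "simulate", seed)
    strata <- tibble::tibble(
      stratum = tier_levels(), population = c(22000000L, 25000000L,
                                              18000000L),
      prevalence = c(0.0004, 0.0008, 0.0018),
      ifr = c(0.09, 0.10, 0.12))
    counts <- generate_stratum_counts(strata, seed = seed + 1L)
    state$results$counts <- counts
    emit(counts, "stratum_counts.csv", "simulate", seed)
    emit(gen$items, "true_params.csv", "simulate", seed)
  })
  run_stage("summarize", function(seed) {
    smry <- summarize_items(get_survey(),
                            use_weights = isTRUE(config$use_weights$summarize))
    state$results$summary <- smry
    emit(smry, "item_summary.csv", "summarize", seed)
  })
  run_stage("benchmarks", function(seed) {
    bench <- compute_rates(get_counts())
    state$results$bench <- bench
    emit(bench, "benchmarks.csv", "benchmarks", seed)
    ref <- bench$stratum[which.min(bench$prevalence_per100)]
    ors <- odds_ratio_table(bench, reference = ref)
    emit(ors, "odds_ratios.csv", "benchmarks", seed)
  })
  run_stage("heaping", function(seed) {
    hp <- heaping_table(get_survey())
    state$results$heaping <- hp
    emit(hp, "heaping.csv", "heaping", seed)
  })
  run_stage("calibrate", function(seed) {
    tab <- get_survey()
    rows <- dplyr::bind_rows(
      paired_test(tab, "q1_ifr", "q4_prevalence",
                  sidedness = "one_sided_a_lt_b", wave = 1),
      paired_test(tab, "q1_ifr", "q1bis_flu_ifr", wave = 1)
    )
    cls <- classify_pairs(tab, "q1_ifr", "q1bis_flu_ifr", wave = 1)
    slp <- proportional_slope(tab, "q7_contagious",
                              "q7bis_contagious_flu", wave = 1)
    state$results$calibration <- list(tests = rows, pairs = cls,
                                      slope = slp)
    emit(rows, "calibration_tests.csv", "calibrate", seed)
    emit(cls, "pair_classification.csv", "calibrate", seed)
    emit(tibble::tibble(slope = slp$slope, se = slp$standard_error,
                        n_pairs = slp$n_pairs),
         "contagiousness_slope.csv", "calibrate", seed)
    if (!is.null(state$results$bench) &&
        "stratum" %in% names(state$results$bench)) {
      bench <- dplyr::rename(state$results$bench,
                             region_tier = "stratum")
      gaps <- stratified_gap(tab, "q2_own_risk", bench, "region_tier")
      emit(gaps, "stratified_gaps.csv", "calibrate", seed)
    }
  })
  run_stage("optimism", function(seed) {
    opt <- optimism_dynamics(get_survey(),
                             use_weights = isTRUE(config$use_weights$optimism))
    state$results$optimism <- opt
    pw <- opt$per_wave
    if (!is.null(opt$wave_contrast)) {
      pw$wave_contrast_p <- opt$wave_contrast$p_value
    }
    emit(pw, "optimism.csv", "optimism", seed)
  })
  run_stage("regress", function(seed) {
    tab <- get_survey()
    tab$wave <- factor(tab$wave)
    fit <- fit_quasibinomial(tab, config$regress_outcome,
                             config$regress_terms,
                             use_weights = isTRUE(config$use_weights$regress))
    ame <- average_marginal_effects(fit)
    state$results$regression <- list(fit = fit, ame = ame)
    emit(ame, "marginal_effects.csv", "regress", seed)
  })

  report_df <- tibble::tibble(stage = names(report),
                              status = unlist(report))
  state$results$report <- report_df
  lines <- c(
    sprintf("run seed: %d", config$seed),
    sprintf("stages: %s", paste(config$stages, collapse = ", ")),
    "analysis choices: heaping window [45,55] closed, continuity-corrected",
    "  expected mass; beta fit MLE including 50s; pair tolerance 0;",
    sprintf("  weights: summarize=%s optimism=%s regress=%s",
            isTRUE(config$use_weights$summarize),
            isTRUE(config$use_weights$optimism),
            isTRUE(config$use_weights$regress)),
    sprintf("%s: %s", report_df$stage, report_df$status)
  )
  writeLines(lines, file.path(config$out_dir, "run_report.txt"))
  invisible(list(report = report_df, outputs = state$outputs,
                 results = as.list(state$results)))
}
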