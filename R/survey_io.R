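#' Read a respondent-level survey table
#'
#' Reads a comma-separated file with a header row, validates it against a
#' codebook and returns a tibble of respondent records. Empty cells become
#' explicit `NA`; out-of-range or off-level values are reported with row
#' and column, never silently coerced.
#'
#' @param path Path to a CSV file. Lines starting with `#` are ignored
#'   (run metadata headers written by [run_pipeline()]).
#' @param codebook Item definitions; see [default_codebook()].
#' @return A validated survey tibble (one row per respondent).
#' @seealso [validate_survey()], [write_survey()]
#' @export
read_survey <- function(path, codebook = default_codebook()) {
  stopifnot(file.exists(path))
  col_types <- setNames(lapply(codebook$type, function(t) {
    switch(t,
      id = readr::col_character(),
      integer = readr::col_integer(),
      numeric = readr::col_double(),
      categorical = readr::col_character(),
      logical = readr::col_logical()
    )
  }), codebook$column)
  tab <- readr::read_csv(path, na = "", comment = "#",
                         col_types = do.call(readr::cols, col_types),
                         show_col_types = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    stop("parse failure at row ", probs$row[1], ", column ", probs$col[1],
         ": expected ", probs$expected[1], call. = FALSE)
  }
  validate_survey(tab, codebook)
}

#' Write a survey table to CSV
#'
#' Missing values are written as empty cells, the encoding
#' [read_survey()] expects; a survey table round-trips through
#' `write_survey()`/`read_survey()` with item values unchanged.
#'
#' @param table Survey tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Validate a survey table against a codebook
#'
#' Checks the schema (exactly the codebook's columns), value ranges and
#' level sets, required fields, uniqueness of `respondent_id` within wave,
#' and that no wave-1-only item is present (non-missing) in wave 2.
#'
#' @inheritParams read_survey
#' @param table A data frame of respondent records.
#' @return The table, as a tibble, invisibly validated.
#' @export
validate_survey <- function(table, codebook = default_codebook()) {
  table <- tibble::as_tibble(table)
  missing_cols <- setdiff(codebook$column, names(table))
  if (length(missing_cols) > 0) {
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(table), codebook$column)
  if (length(extra) > 0) {
    stop("schema error: unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  table <- table[codebook$column]
  if (nrow(table) == 0) return(table)

  fail <- function(col, rows, what) {
    stop("validation error: column ", col, ", row(s) ",
         paste(head(rows, 5), collapse = ", "),
         if (length(rows) > 5) ", ..." else "", ": ", what, call. = FALSE)
  }
  for (i in seq_len(nrow(codebook))) {
    def <- codebook[i, ]
    x <- table[[def$column]]
    if (def$type %in% c("numeric", "integer") && is.finite(def$max)) {
      bad <- which(!is.na(x) & (x < def$min | x > def$max))
      if (length(bad) > 0) {
        fail(def$column, bad,
             sprintf("value outside [%g, %g]", def$min, def$max))
      }
    }
    if (def$type == "categorical") {
      lev <- def$levels[[1]]
      bad <- which(!is.na(x) & !x %in% lev)
      if (length(bad) > 0) {
        fail(def$column, bad,
             paste0("value not in {", paste(lev, collapse = ", "), "}"))
      }
    }
    if (isTRUE(def$required)) {
      bad <- which(is.na(x))
      if (length(bad) > 0) fail(def$column, bad, "required value missing")
    }
    waves_in <- def$waves[[1]]
    if (!2L %in% waves_in) {
      bad <- which(table$wave == 2L & !is.na(x))
      if (length(bad) > 0) {
        fail(def$column, bad, "wave-1-only item present in wave 2")
      }
    }
  }
  if (!all(table$wave %in% c(1L, 2L))) {
    fail("wave", which(!table$wave %in% c(1L, 2L)), "wave must be 1 or 2")
  }
  dup <- table %>%
    dplyr::group_by(.data$wave, .data$respondent_id) %>%
    dplyr::filter(dplyr::n() > 1) %>%
    dplyr::ungroup()
  if (nrow(dup) > 0) {
    stop("uniqueness error: duplicated respondent_id within wave: ",
         paste(unique(dup$respondent_id), collapse = ", "), call. = FALSE)
  }
  table
}

#' Descriptive summary of belief items by wave
#'
#' For every item and wave, counts missing responses and computes the mean
#' and standard deviation over present responses only. With
#' `use_weights = TRUE`, weights are renormalized over the non-missing
#' respondents of each item so they sum to the number of present
#' responses, and the SD keeps its n-1 denominator; equal weights
#' therefore reproduce the unweighted summary exactly.
#'
#' @param table Survey tibble.
#' @param use_weights Use the post-stratification `weight` column.
#' @param items Item columns to summarize (default: all of
#'   [item_columns()] present in the table).
#' @return Tibble with `item`, `wave`, `n_missing`, `n_present`, `mean`,
#'   `sd`. Items with no present response in a wave carry `NA` mean/sd
#'   (the defined "undefined" marker) rather than raising an error.
#' @export
summarize_items <- function(table, use_weights = FALSE, items = NULL) {
  stopifnot(nrow(table) > 0)
  if (is.null(items)) items <- intersect(item_columns(), names(table))
  stopifnot(all(items %in% names(table)))
  w_all <- if (use_weights) table$weight else rep(1, nrow(table))
  purrr::map_dfr(sort(unique(table$wave)), function(wv) {
    in_wave <- table$wave == wv
    purrr::map_dfr(items, function(it) {
      x <- table[[it]][in_wave]
      w <- w_all[in_wave]
      ok <- !is.na(x)
      n_p <- sum(ok)
      if (n_p == 0) {
        return(tibble::tibble(item = it, wave = wv,
                              n_missing = sum(in_wave), n_present = 0L,
                              mean = NA_real_, sd = NA_real_))
      }
      wr <- w[ok] * n_p / sum(w[ok])  # renormalize over non-missing
      m <- sum(wr * x[ok]) / n_p
      s <- if (n_p > 1) sqrt(sum(wr * (x[ok] - m)^2) / (n_p - 1)) else NA_real_
      tibble::tibble(item = it, wave = wv, n_missing = sum(!ok),
                     n_present = n_p, mean = m, sd = s)
    })
  })
}
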