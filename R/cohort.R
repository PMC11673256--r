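#' Construct and validate a cohort of hospitalization records
#'
#' A cohort is a tibble with one row per hospitalization and columns
#' `record_id` (unique string), `sex` (`"male"`/`"female"`), `age`
#' (integer years), `admission_year` (integer), `city` (string, may be
#' `NA`) and two list-columns `diagnoses` and `comorbidities`, each
#' holding a character vector of canonical terms. Term vectors behave as
#' sets: they are trimmed, empties dropped and duplicates removed.
#'
#' @param records A data frame with the columns above. `diagnoses` and
#'   `comorbidities` may be either list-columns or `";"`-separated
#'   strings.
#' @return A validated cohort tibble (class `comorb_cohort`).
#' @examples
#' cohort <- new_cohort(tibble::tibble(
#'   record_id = c("r1", "r2"),
#'   sex = c("male", "female"),
#'   age = c(63L, 71L),
#'   admission_year = c(2015L, 2018L),
#'   city = "Nanning",
#'   diagnoses = c("Unstable Angina", "Stable Angina"),
#'   comorbidities = c("Hypertension;Dyslipidemia", "Hypertension")
#' ))
#' cohort_vocabulary(cohort, "comorbidity")
#' @export
new_cohort <- function(records) {
  if (inherits(records, "comorb_cohort")) return(records)
  required <- c("record_id", "sex", "age", "admission_year",
                "diagnoses", "comorbidities")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required field(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "comorbnet_parse_error")
  }
  records <- as_tibble(records)
  if (!"city" %in% names(records)) records$city <- NA_character_

  if (!is.list(records$diagnoses)) {
    records$diagnoses <- split_terms(as.character(records$diagnoses))
  } else {
    records$diagnoses <- clean_term_list(records$diagnoses)
  }
  if (!is.list(records$comorbidities)) {
    records$comorbidities <- split_terms(as.character(records$comorbidities))
  } else {
    records$comorbidities <- clean_term_list(records$comorbidities)
  }

  records$record_id <- as.character(records$record_id)
  records$sex <- tolower(as.character(records$sex))
  records$age <- as.integer(records$age)
  records$admission_year <- as.integer(records$admission_year)
  records$city <- as.character(records$city)

  dup <- records$record_id[duplicated(records$record_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate record_id: ", paste(unique(dup), collapse = ", ")),
          class = "comorbnet_parse_error")
  }
  bad_sex <- which(!records$sex %in% c("male", "female"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex token in row(s) ",
                 paste(bad_sex, collapse = ", "),
                 " (expected 'male' or 'female')"),
          class = "comorbnet_parse_error")
  }
  if (nrow(records) > 0) {
    bad_age <- which(is.na(records$age) | records$age < 18 | records$age > 120)
    if (length(bad_age) > 0) {
      abort(paste0("age outside [18, 120] in row(s) ",
                   paste(bad_age, collapse = ", ")),
            class = "comorbnet_parse_error")
    }
    bad_year <- which(is.na(records$admission_year) |
                        records$admission_year < 1990 |
                        records$admission_year > 2100)
    if (length(bad_year) > 0) {
      abort(paste0("admission_year outside [1990, 2100] in row(s) ",
                   paste(bad_year, collapse = ", ")),
            class = "comorbnet_parse_error")
    }
  }
  cols <- c("record_id", "sex", "age", "admission_year", "city",
            "diagnoses", "comorbidities")
  out <- records[, cols]
  class(out) <- c("comorb_cohort", class(tibble()))
  out
}

#' Read a cohort from CSV or JSON Lines
#'
#' CSV files carry one record per row with `";"`-separated term lists in
#' the `diagnoses` and `comorbidities` columns; JSON Lines files carry
#' one JSON object per line with term arrays. Both are UTF-8.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension
#'   by default.
#' @return A cohort tibble (see [new_cohort()]).
#' @export
read_cohort <- function(path, format = c("guess", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) {
      df <- tibble(record_id = character(), sex = character(),
                   age = integer(), admission_year = integer(),
                   city = character(),
                   diagnoses = list(), comorbidities = list())
    } else {
      recs <- purrr::map(lines, jsonlite::fromJSON)
      df <- tibble(
        record_id = purrr::map_chr(recs, ~ as.character(.x$record_id %||% NA)),
        sex = purrr::map_chr(recs, ~ as.character(.x$sex %||% NA)),
        age = purrr::map_int(recs, ~ as.integer(.x$age %||% NA)),
        admission_year = purrr::map_int(recs, ~ as.integer(.x$admission_year %||% NA)),
        city = purrr::map_chr(recs, ~ as.character(.x$city %||% NA)),
        diagnoses = purrr::map(recs, ~ as.character(.x$diagnoses %||% character())),
        comorbidities = purrr::map(recs, ~ as.character(.x$comorbidities %||% character()))
      )
    }
  }
  new_cohort(df)
}

#' Write a cohort to CSV or JSON Lines
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p), ...)`
#' reproduces `x` for both formats.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  cohort <- new_cohort(cohort)
  if (format == "csv") {
    flat <- cohort
    flat$diagnoses <- join_terms(flat$diagnoses)
    flat$comorbidities <- join_terms(flat$comorbidities)
    readr::write_csv(as_tibble(flat), path, progress = FALSE)
  } else {
    lines <- purrr::map_chr(seq_len(nrow(cohort)), function(i) {
      jsonlite::toJSON(list(
        record_id = cohort$record_id[i],
        sex = cohort$sex[i],
        age = cohort$age[i],
        admission_year = cohort$admission_year[i],
        city = cohort$city[i],
        diagnoses = cohort$diagnoses[[i]],
        comorbidities = cohort$comorbidities[[i]]
      ), auto_unbox = TRUE, na = "null")
    })
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Vocabulary of canonical terms used in a cohort
#'
#' @param cohort A cohort tibble.
#' @param category `"diagnosis"` or `"comorbidity"`.
#' @return Sorted character vector of distinct terms.
#' @export
cohort_vocabulary <- function(cohort, category = c("diagnosis", "comorbidity")) {
  category <- match.arg(category)
  col <- if (category == "diagnosis") "diagnoses" else "comorbidities"
  sort(unique(unlist(cohort[[col]])))
}

term_column <- function(category) {
  switch(category, diagnosis = "diagnoses", comorbidity = "comorbidities",
         abort(paste0("unknown category: ", category)))
}
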