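#' Read a term-normalization mapping table
#'
#' The mapping table is a CSV with columns `raw_term`, `canonical_term`
#' and `category` (`"diagnosis"` or `"comorbidity"`). It plays the role
#' of the manual synonym resolution step in EMR preprocessing: free-text
#' variants such as "triple vessel disease" or "hypertension stage 3
#' very high-risk group" are consolidated under one canonical term.
#' Matching is case-insensitive after whitespace trimming; the canonical
#' output keeps the table's casing.
#'
#' @param path CSV path.
#' @return A tibble with columns `raw_term`, `canonical_term`,
#'   `category` (class `comorb_term_map`).
#' @export
read_term_map <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  new_term_map(df)
}

#' @rdname read_term_map
#' @param entries Data frame with columns `raw_term`, `canonical_term`,
#'   `category`.
#' @export
new_term_map <- function(entries) {
  required <- c("raw_term", "canonical_term", "category")
  missing_cols <- setdiff(required, names(entries))
  if (length(missing_cols) > 0) {
    abort(paste0("term map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "comorbnet_parse_error")
  }
  entries <- as_tibble(entries)[, required]
  entries$raw_term <- stringr::str_squish(entries$raw_term)
  entries$canonical_term <- stringr::str_squish(entries$canonical_term)
  if (any(!nzchar(entries$canonical_term))) {
    abort("term map has empty canonical terms", class = "comorbnet_parse_error")
  }
  bad <- which(!entries$category %in% c("diagnosis", "comorbidity"))
  if (length(bad) > 0) {
    abort(paste0("invalid category in term map row(s) ",
                 paste(bad, collapse = ", ")),
          class = "comorbnet_parse_error")
  }
  key <- tolower(entries$raw_term)
  dup <- duplicated(paste(key, entries$category))
  if (any(dup)) {
    abort(paste0("term map is not deterministic; duplicate raw term(s): ",
                 paste(unique(entries$raw_term[dup]), collapse = ", ")),
          class = "comorbnet_parse_error")
  }
  class(entries) <- c("comorb_term_map", class(tibble()))
  entries
}

#' Apply a term map to a cohort
#'
#' Replaces every raw diagnosis/comorbidity term with its canonical
#' form. Terms that collapse to the same canonical form within one
#' record are deduplicated. Terms absent from the map pass through
#' unchanged unless `strict = TRUE`, in which case all unmapped terms
#' are reported in one error.
#'
#' @param cohort A cohort tibble.
#' @param term_map A term map from [read_term_map()]/[new_term_map()].
#' @param strict Error on unmapped terms instead of passing them
#'   through.
#' @return The normalized cohort tibble.
#' @export
apply_term_map <- function(cohort, term_map, strict = FALSE) {
  cohort <- new_cohort(cohort)
  term_map <- new_term_map(term_map)
  if (nrow(term_map) == 0) abort("term map is empty")

  lookup_for <- function(category) {
    sub <- term_map[term_map$category == category, ]
    setNames(sub$canonical_term, tolower(sub$raw_term))
  }
  maps <- list(diagnosis = lookup_for("diagnosis"),
               comorbidity = lookup_for("comorbidity"))

  unmapped <- character()
  map_terms <- function(terms, category) {
    lk <- maps[[category]]
    key <- tolower(terms)
    hit <- key %in% names(lk)
    out <- terms
    out[hit] <- unname(lk[key[hit]])
    if (strict && any(!hit)) unmapped <<- c(unmapped, terms[!hit])
    unique(out)
  }

  cohort$diagnoses <- purrr::map(cohort$diagnoses, map_terms, "diagnosis")
  cohort$comorbidities <- purrr::map(cohort$comorbidities, map_terms, "comorbidity")

  if (strict && length(unmapped) > 0) {
    abort(paste0("unmapped term(s): ",
                 paste(sort(unique(unmapped)), collapse = ", ")),
          class = "comorbnet_unmapped_error")
  }
  cohort
}

#' Summarise vocabulary collapse caused by normalization
#'
#' Compares distinct term counts per category before and after a
#' mapping step (e.g. 57 raw diagnosis descriptions collapsing to 32
#' canonical ones).
#'
#' @param before,after Cohort tibbles before and after
#'   [apply_term_map()].
#' @return A tibble with columns `category`, `n_terms_before`,
#'   `n_terms_after`.
#' @export
vocab_summary <- function(before, after) {
  tibble(
    category = c("diagnosis", "comorbidity"),
    n_terms_before = c(length(cohort_vocabulary(before, "diagnosis")),
                       length(cohort_vocabulary(before, "comorbidity"))),
    n_terms_after = c(length(cohort_vocabulary(after, "diagnosis")),
                      length(cohort_vocabulary(after, "comorbidity")))
  )
}
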