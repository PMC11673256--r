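#' Reference detection counts for the CAD case-study cohort
#'
#' Sex-specific detection counts of the twenty most frequent diagnoses
#' and twenty most frequent comorbidities in the 195-patient coronary
#' artery disease reference cohort (138 male, 57 female hospitalizations)
#' that the package's defaults are calibrated to. `male_count` /
#' `female_count` are the numbers of records of each sex containing the
#' term; overall detection rates follow as `100 * count / 195`.
#'
#' @return A tibble with columns `term`, `category`, `male_count`,
#'   `female_count`.
#' @seealso [cad_cohort_config()] which calibrates a synthetic-cohort
#'   configuration to these counts.
#' @export
cad_reference_counts <- function() {
  diag <- tibble::tribble(
    ~term, ~male_count, ~female_count,
    "Unstable Angina", 55L, 27L,
    "Braunwald Class II B", 32L, 13L,
    "Stable Angina", 30L, 8L,
    "Myocardial Infarction", 23L, 5L,
    "CCS Angina class II", 20L, 7L,
    "KILLIP Class I", 20L, 0L,
    "Braunwald Class III B", 13L, 6L,
    "Coronary Atherosclerosis", 9L, 7L,
    "CCS Angina class I", 7L, 0L,
    "Post-Percutaneous Coronary Intervention", 3L, 3L,
    "Acute Coronary Syndrome", 5L, 1L,
    "Myocardial Bridging", 3L, 3L,
    "NYHA Class III", 3L, 2L,
    "NYHA Class II", 3L, 2L,
    "KILLIP Class II", 4L, 1L,
    "CCS Angina class III", 4L, 1L,
    "Multiple Vessel Disease", 2L, 2L,
    "Braunwald Class I B", 3L, 1L,
    "KILLIP Classification IV", 1L, 2L,
    "Coronary Atherosclerotic Heart Disease", 3L, 0L
  )
  com <- tibble::tribble(
    ~term, ~male_count, ~female_count,
    "Hypertension", 81L, 39L,
    "Metabolic Diseases", 35L, 8L,
    "Dyslipidemia", 23L, 18L,
    "Diabetes and Its Complications", 28L, 10L,
    "Fatty Liver Disease", 29L, 6L,
    "Cardiac Arrhythmias", 23L, 5L,
    "Renal Cysts", 21L, 2L,
    "Post PCI", 18L, 4L,
    "Renal Dysfunction", 13L, 5L,
    "Pulmonary Infections", 11L, 5L,
    "Hematologic Diseases", 8L, 7L,
    "Gastrointestinal Diseases", 9L, 6L,
    "Atherosclerosis and Stenotic", 11L, 4L,
    "Cerebral Infarction", 9L, 5L,
    "Gallbladder Diseases", 8L, 4L,
    "Tobacco dependence", 12L, 0L,
    "Myocardial Infarction", 11L, 0L,
    "Liver Cystic Lesions", 10L, 1L,
    "Skeletal Diseases", 5L, 5L,
    "Valvular Heart Diseases", 7L, 2L
  )
  dplyr::bind_rows(
    dplyr::mutate(diag, category = "diagnosis", .after = "term"),
    dplyr::mutate(com, category = "comorbidity", .after = "term")
  )
}

# cohort margins of the reference cohort
cad_reference_margins <- function() {
  list(n_total = 195L, n_male = 138L, n_female = 57L)
}
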