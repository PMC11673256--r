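#' Configure a synthetic EMR cohort
#'
#' The simulator draws, per hospitalization record, a sex
#' (Bernoulli(`p_male`)), an integer age from a sex-specific truncated
#' normal, an admission year, and the presence of each configured
#' condition from a logistic model with a shared latent frailty:
#' \deqn{P(\mathrm{cond}_c \mid \mathrm{sex}, z) =
#'   \mathrm{logit}^{-1}\!\big(\mathrm{logit}(p_c) + s_c\,[\mathrm{male}]
#'   + \lambda_c z\big), \quad z \sim N(0, \sigma_f^2)}
#' where \eqn{p_c} is the female-reference base prevalence, \eqn{s_c}
#' the sex log odds ratio, \eqn{\lambda_c} the frailty loading and
#' \eqn{\sigma_f} = `frailty_sd`. One Gaussian frailty shared across
#' conditions induces positive pairwise co-occurrence concentrated on
#' high-loading, high-prevalence conditions — the hub structure seen in
#' real comorbidity networks. With `frailty_sd = 0` conditions are
#' independent given sex.
#'
#' @param n_patients Number of hospitalization records.
#' @param p_male Probability of male sex.
#' @param age_model Data frame with columns `sex`, `mean`, `sd`, `min`,
#'   `max` (truncated-normal age parameters per sex, years).
#' @param conditions Data frame with columns `term`, `category`
#'   (`"diagnosis"`/`"comorbidity"`), `base_prevalence` (in (0,1),
#'   female reference), `sex_log_or`, `frailty_loading`.
#' @param frailty_sd Standard deviation of the shared latent frailty
#'   (0 = conditional independence given sex).
#' @param admission_years Integer vector to sample admission years from,
#'   uniformly.
#' @param cities Optional named numeric vector of city sampling
#'   probabilities.
#' @param seed Integer seed making [generate_cohort()] deterministic.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients,
                          p_male = 0.5,
                          age_model = default_age_model(),
                          conditions,
                          frailty_sd = 0,
                          admission_years = 2013:2020,
                          cities = c(Nanning = 0.66, Other = 0.34),
                          seed = 1L) {
  stopifnot(n_patients >= 0, p_male >= 0, p_male <= 1, frailty_sd >= 0)
  conditions <- as_tibble(conditions)
  required <- c("term", "category", "base_prevalence", "sex_log_or",
                "frailty_loading")
  missing_cols <- setdiff(required, names(conditions))
  if (length(missing_cols) > 0) {
    abort(paste0("conditions is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(conditions$base_prevalence <= 0 | conditions$base_prevalence >= 1)) {
    abort("base_prevalence must lie strictly in (0, 1)")
  }
  if (anyDuplicated(paste(conditions$term, conditions$category))) {
    abort("condition terms must be unique within a category")
  }
  age_model <- as_tibble(age_model)
  stopifnot(all(c("sex", "mean", "sd", "min", "max") %in% names(age_model)),
            all(age_model$min < age_model$max))
  structure(list(
    n_patients = as.integer(n_patients),
    p_male = p_male,
    age_model = age_model,
    conditions = conditions[, required],
    frailty_sd = frailty_sd,
    admission_years = as.integer(admission_years),
    cities = cities,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_age_model <- function() {
  # male hospitalizations peak near 60, female later (60-70);
  # truncation [30, 89] matches the decade bins of the stratified tables
  tibble(sex = c("male", "female"),
         mean = c(60, 65), sd = c(11, 10),
         min = c(30, 30), max = c(89, 89))
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo - 0.5, mean, sd), pnorm(hi + 0.5, mean, sd))
  pmin(pmax(as.integer(round(qnorm(u, mean, sd))), lo), hi)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`: the same configuration always
#' yields an identical cohort. The global RNG state is left untouched.
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble (see [new_cohort()]).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  empty <- tibble(record_id = character(), sex = character(),
                  age = integer(), admission_year = integer(),
                  city = character(), diagnoses = list(),
                  comorbidities = list())
  if (n == 0) return(new_cohort(empty))

  withr::with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$p_male, "male", "female")
    age <- integer(n)
    for (s in unique(sex)) {
      am <- config$age_model[config$age_model$sex == s, ]
      idx <- which(sex == s)
      age[idx] <- rtruncnorm_int(length(idx), am$mean, am$sd, am$min, am$max)
    }
    year <- sample(config$admission_years, n, replace = TRUE)
    city <- sample(names(config$cities), n, replace = TRUE,
                   prob = config$cities)
    z <- rnorm(n, 0, config$frailty_sd)
    male <- as.numeric(sex == "male")

    cond <- config$conditions
    present <- matrix(FALSE, n, nrow(cond))
    for (j in seq_len(nrow(cond))) {
      eta <- qlogis(cond$base_prevalence[j]) +
        cond$sex_log_or[j] * male +
        cond$frailty_loading[j] * z
      present[, j] <- runif(n) < plogis(eta)
    }

    is_dx <- cond$category == "diagnosis"
    diagnoses <- purrr::map(seq_len(n), ~ cond$term[is_dx & present[.x, ]])
    comorbidities <- purrr::map(seq_len(n), ~ cond$term[!is_dx & present[.x, ]])

    new_cohort(tibble(
      record_id = sprintf("S%05d", seq_len(n)),
      sex = sex, age = age, admission_year = year, city = city,
      diagnoses = diagnoses, comorbidities = comorbidities
    ))
  })
}

# mixture-averaged prevalence under the logit-normal frailty model
frailty_marginal <- function(b, loading, frailty_sd) {
  if (frailty_sd == 0 || loading == 0) return(plogis(b))
  stats::integrate(function(z) plogis(b + loading * z) * dnorm(z, 0, frailty_sd),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# solve the logit intercept whose frailty-averaged marginal hits `target`
solve_intercept <- function(target, loading, frailty_sd) {
  stats::uniroot(function(b) frailty_marginal(b, loading, frailty_sd) - target,
                 lower = -20, upper = 20, tol = 1e-10)$root
}

#' Cohort configuration calibrated to the CAD reference cohort
#'
#' Builds a [cohort_config()] with `n_patients = 195`,
#' `p_male = 138/195`, and one condition per row of
#' [cad_reference_counts()]. For each condition and sex the logit-scale
#' intercept is solved numerically so that the frailty-averaged marginal
#' prevalence equals the reference detection rate of that sex; the
#' female intercept becomes `base_prevalence` and the male-female
#' intercept difference becomes `sex_log_or`. Sexes with a zero count
#' use the continuity-corrected rate `0.5 / (n_sex + 1)`. The two hub
#' conditions (hypertension, unstable angina) carry a larger frailty
#' loading so that co-occurrence concentrates on them.
#'
#' @param frailty_sd Shared frailty scale (default 0.8).
#' @param hub_loading,base_loading Frailty loadings for hub and non-hub
#'   conditions.
#' @param n_patients,seed Overrides for cohort size and seed.
#' @return A `cohort_config`.
#' @export
cad_cohort_config <- function(frailty_sd = 0.8, hub_loading = 1.5,
                              base_loading = 1, n_patients = 195L,
                              seed = 1L) {
  counts <- cad_reference_counts()
  m <- cad_reference_margins()
  hubs <- c("Hypertension", "Unstable Angina")
  counts$frailty_loading <- ifelse(counts$term %in% hubs,
                                   hub_loading, base_loading)

  corrected_rate <- function(count, n) {
    ifelse(count == 0, 0.5 / (n + 1), count / n)
  }
  rate_m <- corrected_rate(counts$male_count, m$n_male)
  rate_f <- corrected_rate(counts$female_count, m$n_female)

  b_m <- purrr::map2_dbl(rate_m, counts$frailty_loading,
                         ~ solve_intercept(.x, .y, frailty_sd))
  b_f <- purrr::map2_dbl(rate_f, counts$frailty_loading,
                         ~ solve_intercept(.x, .y, frailty_sd))

  conditions <- tibble(
    term = counts$term,
    category = counts$category,
    base_prevalence = plogis(b_f),
    sex_log_or = b_m - b_f,
    frailty_loading = counts$frailty_loading
  )
  cohort_config(
    n_patients = n_patients,
    p_male = m$n_male / m$n_total,
    conditions = conditions,
    frailty_sd = frailty_sd,
    seed = seed
  )
}

#' Expected marginal prevalences implied by a configuration
#'
#' Averages the frailty-integrated per-sex prevalences over the sex
#' mixture, i.e. the detection rates a very large generated cohort
#' converges to.
#'
#' @param config A `cohort_config`.
#' @return Tibble with `term`, `category`, `expected_rate`,
#'   `expected_rate_male`, `expected_rate_female` (proportions).
#' @export
expected_marginals <- function(config) {
  cond <- config$conditions
  pm <- purrr::pmap_dbl(cond, function(term, category, base_prevalence,
                                       sex_log_or, frailty_loading) {
    frailty_marginal(qlogis(base_prevalence) + sex_log_or, frailty_loading,
                     config$frailty_sd)
  })
  pf <- purrr::pmap_dbl(cond, function(term, category, base_prevalence,
                                       sex_log_or, frailty_loading) {
    frailty_marginal(qlogis(base_prevalence), frailty_loading,
                     config$frailty_sd)
  })
  tibble(term = cond$term, category = cond$category,
         expected_rate = config$p_male * pm + (1 - config$p_male) * pf,
         expected_rate_male = pm, expected_rate_female = pf)
}

#' Serialize / read a cohort configuration as YAML or JSON
#'
#' @param config A `cohort_config`.
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$age_model <- as.data.frame(x$age_model)
  x$conditions <- as.data.frame(x$conditions)
  x$cities <- as.list(x$cities)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cohort_config(
    n_patients = x$n_patients,
    p_male = x$p_male,
    age_model = as_tibble(as.data.frame(x$age_model)),
    conditions = as_tibble(as.data.frame(x$conditions)),
    frailty_sd = x$frailty_sd,
    admission_years = unlist(x$admission_years),
    cities = unlist(x$cities),
    seed = x$seed
  )
}
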