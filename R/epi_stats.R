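#' Detection rate of a condition
#'
#' The detection rate (DR) of a diagnosis or comorbidity is the
#' percentage of cohort records that contain it:
#' `DR = 100 * n_term / n_total`. A Wilson score (default) or Wald
#' confidence interval for the underlying proportion is attached, on
#' the percent scale and clipped to \[0, 100\].
#'
#' @param n_term Number of records containing the term.
#' @param n_total Total number of records (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"wilson"` (default), `"wald"` or `"none"`.
#' @return One-row tibble: `numerator`, `denominator`, `rate`,
#'   `ci_low`, `ci_high`, `ci_method` (percent scale).
#' @examples
#' detection_rate(82, 195)   # 42.05%
#' detection_rate(120, 195)  # 61.54%
#' @export
detection_rate <- function(n_term, n_total, conf_level = 0.95,
                           ci_method = c("wilson", "wald", "none")) {
  ci_method <- match.arg(ci_method)
  if (n_total <= 0) abort("n_total must be positive")
  if (n_term < 0 || n_term > n_total) abort("n_term must lie in [0, n_total]")
  rate <- 100 * n_term / n_total
  if (ci_method == "none") {
    ci <- c(NA_real_, NA_real_)
  } else {
    ci <- rate_confidence_interval(n_term, n_total, conf_level, ci_method)
  }
  tibble(numerator = as.integer(n_term), denominator = as.integer(n_total),
         rate = rate, ci_low = ci[1], ci_high = ci[2], ci_method = ci_method)
}

#' Confidence interval for a detection rate
#'
#' Wilson score interval (via `stats::prop.test` without continuity
#' correction) or the normal-approximation Wald interval, on the
#' percent scale, clipped to \[0, 100\].
#'
#' @inheritParams detection_rate
#' @param method `"wilson"` or `"wald"`.
#' @return Numeric vector `c(low, high)` in percent.
#' @export
rate_confidence_interval <- function(n_term, n_total, conf_level = 0.95,
                                     method = c("wilson", "wald")) {
  method <- match.arg(method)
  if (n_total <= 0) abort("n_total must be positive")
  p <- n_term / n_total
  if (method == "wilson") {
    ci <- stats::prop.test(n_term, n_total, conf.level = conf_level,
                           correct = FALSE)$conf.int
  } else {
    z <- qnorm(1 - (1 - conf_level) / 2)
    half <- z * sqrt(p * (1 - p) / n_total)
    ci <- c(p - half, p + half)
  }
  pmin(pmax(100 * as.numeric(ci), 0), 100)
}

#' Sex-by-condition 2x2 contingency table
#'
#' Cell `a` counts male records containing the term, `b` male records
#' without it; `c` and `d` are the female analogues.
#'
#' @param cohort A cohort tibble.
#' @param term Canonical term.
#' @param category `"diagnosis"` or `"comorbidity"`.
#' @return One-row tibble: `term`, `category`, `a`, `b`, `c`, `d`.
#' @export
sex_table <- function(cohort, term, category = c("diagnosis", "comorbidity")) {
  category <- match.arg(category)
  cohort <- new_cohort(cohort)
  if (!term %in% cohort_vocabulary(cohort, category)) {
    abort(paste0("term not in ", category, " vocabulary: ", term))
  }
  col <- term_column(category)
  has <- purrr::map_lgl(cohort[[col]], ~ term %in% .x)
  male <- cohort$sex == "male"
  tibble(term = term, category = category,
         a = sum(has & male), b = sum(!has & male),
         c = sum(has & !male), d = sum(!has & !male))
}

#' Odds ratio with Haldane-Anscombe correction and Wald CI
#'
#' Computes the male-vs-female odds ratio of a 2x2 table. By default
#' 0.5 is added to **every** cell (Haldane-Anscombe) before both the
#' estimate and the log-scale Wald interval
#' \deqn{\exp\left(\ln\widehat{OR} \pm z\sqrt{\tfrac1{a+.5}+\tfrac1{b+.5}
#'   +\tfrac1{c+.5}+\tfrac1{d+.5}}\right).}
#' When one sex has zero events the estimate is reported as a sentinel
#' instead of a finite corrected value: `"INF"` if no female events,
#' `"ZERO"` if no male events, `"UNDEFINED"` if neither sex has events;
#' sentinels carry no confidence interval.
#'
#' @param a,b,c,d Cell counts (males with/without, females
#'   with/without), or `a` may be a one-row tibble from [sex_table()].
#' @param correct Apply the +0.5 correction to all cells (default
#'   `TRUE`; `FALSE` gives the crude cross-product ratio).
#' @param conf_level Confidence level for the Wald interval.
#' @return One-row tibble: `a`-`d`, `estimate`, `conf_low`,
#'   `conf_high`, `sentinel` (`"finite"`, `"INF"`, `"ZERO"` or
#'   `"UNDEFINED"`) and `corrected`.
#' @examples
#' odds_ratio(23, 115, 5, 52)   # 1.94 (0.73, 5.20)
#' odds_ratio(20, 118, 0, 57)   # INF
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, correct = TRUE,
                       conf_level = 0.95) {
  if (is.data.frame(a)) {
    tab <- a
    stopifnot(all(c("a", "b", "c", "d") %in% names(tab)), nrow(tab) == 1)
    b <- tab$b; c <- tab$c; d <- tab$d; a <- tab$a
  }
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0)) abort("cell counts must be non-negative")
  if (a + b <= 0 || c + d <= 0) abort("both sex groups must be non-empty")

  sentinel <- if (a == 0 && c == 0) "UNDEFINED"
  else if (c == 0) "INF"
  else if (a == 0) "ZERO"
  else "finite"

  if (sentinel != "finite") {
    est <- switch(sentinel, INF = Inf, ZERO = 0, UNDEFINED = NA_real_)
    return(tibble(a = a, b = b, c = c, d = d, estimate = est,
                  conf_low = NA_real_, conf_high = NA_real_,
                  sentinel = sentinel, corrected = correct))
  }
  shift <- if (correct) 0.5 else 0
  aa <- a + shift; bb <- b + shift; cc <- c + shift; dd <- d + shift
  est <- (aa * dd) / (bb * cc)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  tibble(a = a, b = b, c = c, d = d, estimate = est,
         conf_low = exp(log(est) - z * se),
         conf_high = exp(log(est) + z * se),
         sentinel = "finite", corrected = correct)
}

#' Decade age bin label
#'
#' Bins ages into the decade intervals used by the stratified tables:
#' \[30, 40) -> `"30–39"`, ... \[80, 90) -> `"80–89"`. Ages
#' outside \[30, 90) get the label `"other"`.
#'
#' @param age Integer vector of ages in years (>= 0).
#' @return Character vector of bin labels.
#' @export
age_bin <- function(age) {
  if (any(age < 0, na.rm = TRUE)) abort("age must be non-negative")
  lo <- (age %/% 10) * 10
  lab <- paste0(lo, "–", lo + 9)
  ifelse(age >= 30 & age < 90, lab, "other")
}

#' Detection-rate and odds-ratio table per condition
#'
#' One row per canonical term of a category, mirroring the layout of a
#' top-k detection table: overall count and rate, per-sex counts and
#' rates, and the sex odds ratio with its Wald interval. Rows are
#' ordered by descending count (ties alphabetical).
#'
#' @param cohort A cohort tibble.
#' @param category `"diagnosis"` or `"comorbidity"`.
#' @param top_n Keep only the `top_n` most frequent terms (default all).
#' @param conf_level Confidence level for intervals.
#' @param correct Haldane-Anscombe correction flag passed to
#'   [odds_ratio()].
#' @return Tibble: `term`, `count`, `rate`, `male_count`, `male_rate`,
#'   `female_count`, `female_rate`, `or`, `or_low`, `or_high`,
#'   `or_sentinel`.
#' @export
condition_table <- function(cohort, category = c("diagnosis", "comorbidity"),
                            top_n = Inf, conf_level = 0.95, correct = TRUE) {
  category <- match.arg(category)
  cohort <- new_cohort(cohort)
  vocab <- cohort_vocabulary(cohort, category)
  n_male <- sum(cohort$sex == "male")
  n_female <- sum(cohort$sex == "female")
  n_total <- nrow(cohort)
  rows <- purrr::map_dfr(vocab, function(term) {
    tab <- sex_table(cohort, term, category)
    orr <- odds_ratio(tab, correct = correct, conf_level = conf_level)
    tibble(term = term,
           count = tab$a + tab$c,
           rate = 100 * (tab$a + tab$c) / n_total,
           male_count = tab$a,
           male_rate = if (n_male > 0) 100 * tab$a / n_male else NA_real_,
           female_count = tab$c,
           female_rate = if (n_female > 0) 100 * tab$c / n_female else NA_real_,
           or = orr$estimate, or_low = orr$conf_low, or_high = orr$conf_high,
           or_sentinel = orr$sentinel)
  })
  if (nrow(rows) == 0) {
    return(tibble(term = character(), count = integer(), rate = double(),
                  male_count = integer(), male_rate = double(),
                  female_count = integer(), female_rate = double(),
                  or = double(), or_low = double(), or_high = double(),
                  or_sentinel = character()))
  }
  rows <- dplyr::arrange(rows, dplyr::desc(.data$count), .data$term)
  head(rows, top_n)
}

#' Stratified top-k condition rankings
#'
#' Ranks terms within each stratum (decade age bin, sex, or admission
#' year) by descending record count, ties broken alphabetically.
#' Strata with fewer than `k` distinct terms are padded with the
#' explicit empty marker `"/"`.
#'
#' @param cohort A cohort tibble.
#' @param stratifier `"age_bin"`, `"sex"` or `"admission_year"`.
#' @param category `"diagnosis"` or `"comorbidity"`.
#' @param k Number of ranks per stratum (>= 0).
#' @param pad Marker used to pad short strata.
#' @return Tibble: `stratum`, `rank`, `term`, `count` (`count` is `NA`
#'   on padded rows).
#' @export
stratified_top_k <- function(cohort,
                             stratifier = c("age_bin", "sex", "admission_year"),
                             category = c("diagnosis", "comorbidity"),
                             k = 5, pad = "/") {
  stratifier <- match.arg(stratifier)
  category <- match.arg(category)
  stopifnot(k >= 0)
  cohort <- new_cohort(cohort)
  strata <- switch(stratifier,
                   age_bin = age_bin(cohort$age),
                   sex = cohort$sex,
                   admission_year = as.character(cohort$admission_year))
  col <- term_column(category)
  levels <- sort(unique(strata))
  purrr::map_dfr(levels, function(s) {
    terms <- unlist(cohort[[col]][strata == s])
    ranked <- if (length(terms) == 0) {
      tibble(term = character(), count = integer())
    } else {
      counts <- table(terms)
      tibble(term = names(counts), count = as.integer(counts)) |>
        dplyr::arrange(dplyr::desc(.data$count), .data$term)
    }
    ranked <- head(ranked, k)
    n_pad <- k - nrow(ranked)
    if (n_pad > 0) {
      ranked <- dplyr::bind_rows(
        ranked, tibble(term = rep(pad, n_pad), count = rep(NA_integer_, n_pad)))
    }
    if (k == 0) return(tibble(stratum = character(), rank = integer(),
                              term = character(), count = integer()))
    tibble(stratum = s, rank = seq_len(k),
           term = ranked$term, count = ranked$count)
  })
}

#' Render a condition table with the 2-decimal conventions
#'
#' Formats [condition_table()] output the way the printed tables do:
#' rates and odds ratios rounded half-up to 2 decimals, `INF` /
#' `ZERO` / `UNDEFINED` sentinels rendered literally, the OR column as
#' `"est (low, high)"`.
#'
#' @param x Output of [condition_table()].
#' @return Tibble of character columns ready for CSV export.
#' @export
render_condition_table <- function(x) {
  fmt <- function(v) sprintf("%.2f", round_half_up(v, 2))
  or_txt <- ifelse(
    x$or_sentinel == "finite",
    paste0(fmt(x$or), " (", fmt(x$or_low), ", ", fmt(x$or_high), ")"),
    x$or_sentinel
  )
  tibble(term = x$term,
         count = as.character(x$count),
         rate = fmt(x$rate),
         male = paste0(x$male_count, " (", fmt(x$male_rate), ")"),
         female = paste0(x$female_count, " (", fmt(x$female_rate), ")"),
         or_ci = or_txt)
}
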