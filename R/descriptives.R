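#' Round half away from zero
#'
#' Published report-summary tables round percentages half-up (so 0.125
#' prints as 0.13), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

age_band_levels <- c("<18", "18-45", "45-65", "65-75", ">=75", "unknown")
tto_band_levels <- c("<7", "7-28", "28-60", ">=60", "unknown")

#' Age bands used in report summaries
#'
#' Half-open bands `[lo, hi)` with the last band closed above, so a
#' 65-year-old falls in `65-75`.
#'
#' @param age_years Numeric ages in years (NA allowed).
#' @return Character vector over `<18`, `18-45`, `45-65`, `65-75`, `>=75`,
#'   `unknown`.
#' @export
age_band <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years < 45 ~ "18-45",
    age_years < 65 ~ "45-65",
    age_years < 75 ~ "65-75",
    .default = ">=75"
  )
}

#' Time-to-onset band for one or more cases
#'
#' Whole days from therapy start to adverse-event onset, binned as in
#' report summaries. Missing, imprecise (partial-date) or negative
#' intervals fall in `unknown`.
#'
#' @param therapy_start,event_date Date vectors.
#' @param imprecise Logical vector flagging intervals computed from
#'   partial dates.
#' @return Character vector over `<7`, `7-28`, `28-60`, `>=60`, `unknown`.
#' @export
time_to_onset_band <- function(therapy_start, event_date, imprecise = FALSE) {
  days <- as.numeric(event_date - therapy_start)
  imprecise <- rep_len(imprecise, length(days))
  dplyr::case_when(
    is.na(days) | imprecise | days < 0 ~ "unknown",
    days < 7 ~ "<7",
    days < 28 ~ "7-28",
    days < 60 ~ "28-60",
    .default = ">=60"
  )
}

#' Percentages within a factor
#'
#' Each category's share of the factor's own total (the convention of
#' published report-demographics tables, whose factors have different
#' denominators), rounded half-up to 2 decimals.
#'
#' @param counts Named numeric vector of category counts.
#' @return Tibble with columns `category`, `count`, `pct`.
#' @export
factor_percentages <- function(counts) {
  total <- sum(counts)
  pct <- if (total > 0) round_half_up(100 * counts / total, 2) else
    rep(0, length(counts))
  tibble::tibble(category = names(counts), count = unname(counts),
                 pct = unname(pct))
}

#' Descriptive summary of selected cases
#'
#' Category counts and percentages per factor: report year, gender, age
#' band, reporter occupation, country, administration route, serious
#' outcomes and time-to-onset band. Outcomes count one row per (case,
#' outcome); all other factors count cases, and percentages use each
#' factor's own denominator.
#'
#' @param cases Output of [case_table()].
#' @param outc The `outc` table for the same cases (optional).
#' @return Tibble with columns `factor`, `category`, `count`, `pct`.
#' @export
summarize_cases <- function(cases, outc = NULL) {
  tab <- function(x, levels = NULL) {
    x <- as.character(x)
    if (is.null(levels)) levels <- sort(unique(x))
    counts <- table(factor(x, levels = levels))
    setNames(as.numeric(counts), levels)
  }
  pieces <- list(
    year = tab(format(cases$fda_date, "%Y")),
    gender = tab(cases$gender, c("female", "male", "unknown")),
    age = tab(age_band(cases$age_years), age_band_levels),
    reporter = tab(cases$reporter,
                   c("physician", "pharmacist", "consumer",
                     "other health professional", "unknown")),
    country = tab(cases$country),
    route = tab(cases$route,
                c("intravenous", "other", "intravenous drip")),
    time_to_onset = tab(
      time_to_onset_band(cases$therapy_start, cases$event_date,
                         cases$event_date_imprecise |
                           cases$therapy_start_imprecise),
      tto_band_levels)
  )
  if (!is.null(outc) && nrow(outc) > 0) {
    outcome_names <- c(HO = "hospitalization", OT = "other serious",
                       DE = "death", LT = "life-threatening",
                       DS = "disability", RI = "required intervention",
                       CA = "congenital anomaly")
    rows <- dplyr::distinct(tibble::as_tibble(outc), .data$primaryid,
                            .data$outc_cod)
    lab <- outcome_names[rows$outc_cod]
    lab[is.na(lab)] <- "other serious"
    pieces$outcome <- tab(lab)
  }
  if (nrow(cases) == 0) {
    pieces <- lapply(pieces, function(x) x[0])
  }
  dplyr::bind_rows(lapply(pieces, factor_percentages), .id = "factor")
}

#' Quarterly report counts
#'
#' Calendar-quarter histogram of receipt dates, zero-filled over the
#' observed range.
#'
#' @param dates Date vector (NA dropped).
#' @return Tibble with columns `quarter` (e.g. `"2022Q1"`) and `n`.
#' @export
quarterly_counts <- function(dates) {
  dates <- dates[!is.na(dates)]
  if (length(dates) == 0) {
    return(tibble::tibble(quarter = character(), n = integer()))
  }
  to_q <- function(d) {
    as.integer(format(d, "%Y")) * 4L + (as.integer(format(d, "%m")) - 1L) %/% 3L
  }
  q <- to_q(dates)
  all_q <- seq(min(q), max(q))
  counts <- table(factor(q, levels = all_q))
  tibble::tibble(
    quarter = paste0(all_q %/% 4L, "Q", all_q %% 4L + 1L),
    n = as.integer(counts)
  )
}
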