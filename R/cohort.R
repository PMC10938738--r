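#' Define the open-cohort follow-up window
#'
#' @param start_year First calendar year of follow-up (default 2006).
#' @param end_year Last calendar year of follow-up (default 2017); follow-up
#'   ends December 31 of this year.
#' @param min_age Entry age: persons enter January 1 of the calendar year
#'   they turn this age (default 51).
#' @param washout Two-element year range of the fracture look-back window
#'   used to restrict to first fractures (default 1994-2005).
#' @param score_years Year range for which lagged exposure scores exist
#'   (default 2005-2016; follow-up year `t` uses the score of `t - 1`).
#' @return A list of class `cohort_definition`.
#' @export
cohort_definition <- function(start_year = 2006L, end_year = 2017L,
                              min_age = 51L, washout = c(1994L, 2005L),
                              score_years = c(2005L, 2016L)) {
  stopifnot(end_year >= start_year, start_year > score_years[1])
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 min_age = as.integer(min_age),
                 washout = as.integer(washout),
                 score_years = as.integer(score_years)),
            class = "cohort_definition")
}

#' Exclude persons with a fracture in the washout window
#'
#' Persons with any history fracture (`is_history = TRUE`, i.e. an event in
#' the pre-follow-up look-back window) are removed entirely, including any
#' later in-follow-up fracture they may have, so that only first fractures
#' remain in the analysis.
#'
#' @param persons Persons table.
#' @param fractures Fractures table with an `is_history` flag.
#' @return Filtered persons `data.table`; the number removed is reported
#'   with a message.
#' @export
apply_washout <- function(persons, fractures) {
  p <- as.data.table(persons)
  f <- as.data.table(fractures)
  excluded <- unique(f[is_history == TRUE, person_id])
  out <- p[!person_id %in% excluded]
  message(length(excluded), " person(s) excluded by fracture washout; ",
          nrow(out), " retained")
  out[]
}

#' Restrict to persons with at least one dispensing
#'
#' The population at risk is defined as persons who filled at least one
#' prescription (index or not) during the dispensing years; persons never
#' seen at a pharmacy are not part of the cohort.
#'
#' @param persons Persons table.
#' @param dispensings Dispensings table.
#' @return Filtered persons `data.table`.
#' @export
require_any_dispensing <- function(persons, dispensings) {
  p <- as.data.table(persons)
  d <- as.data.table(dispensings)
  p[person_id %in% unique(d$person_id)][]
}

#' Band an Rx-Risk score into the analysis categories
#'
#' @param x Integer score vector; `NA` means no score that year.
#' @param collapse_over_15 If `TRUE`, use the latency-analysis banding where
#'   all scores above 15 form a single `">15"` category.
#' @return Factor with levels `"<=0"`, `"1-5"`, `"6-10"`, `"11-15"`,
#'   `"16-20"`, `"21-25"`, `">25"`, `"missing"` (or the collapsed set).
#' @export
band_rx_risk <- function(x, collapse_over_15 = FALSE) {
  if (collapse_over_15) {
    levs <- c("<=0", "1-5", "6-10", "11-15", ">15", "missing")
    idx <- findInterval(x, c(-Inf, 1, 6, 11, 16))
  } else {
    levs <- c("<=0", "1-5", "6-10", "11-15", "16-20", "21-25", ">25", "missing")
    idx <- findInterval(x, c(-Inf, 1, 6, 11, 16, 21, 26))
  }
  out <- levs[idx]
  out[is.na(x)] <- "missing"
  factor(out, levels = levs)
}

#' Group attained age into the analysis age bands
#'
#' @param attained_age Integer vector of attained ages (calendar year minus
#'   birth year); all must be at least the cohort entry age of 51.
#' @return Factor with levels `"51-65"`, `"66-80"`, `">80"`.
#' @export
age_group <- function(attained_age) {
  if (any(is.na(attained_age)) || any(attained_age < 51)) {
    stop("attained_age below cohort entry age (51)")
  }
  levs <- c("51-65", "66-80", ">80")
  factor(levs[findInterval(attained_age, c(-Inf, 66, 81))], levels = levs)
}

#' Build one risk interval per person per calendar year
#'
#' Constructs the open cohort: each person contributes one exposure slice
#' per calendar year in which they are alive, in the country, fracture-free
#' at the year's start, and at least the entry age. Follow-up runs from
#' January 1 of `max(start_year, year turning min_age)` to the earliest of
#' first fracture, death, emigration, or the study end. Dates have month
#' resolution; an event or censoring in month `m` contributes `m/12`
#' person-years to that year (the event month counts as time at risk).
#' The exposure attached to year `t` is the Rx-Risk score of year `t - 1`;
#' an absent score is carried as the `missing` band.
#'
#' @param persons Persons table (after [apply_washout()] and
#'   [require_any_dispensing()]).
#' @param scores Score table from [compute_scores()].
#' @param fractures Fractures table; must contain no history fractures for
#'   the persons supplied (run [apply_washout()] first).
#' @param definition A [cohort_definition()].
#' @return `data.table` of slices: `person_id`, `calendar_year`, `sex`,
#'   `birth_year`, `attained_age`, `rx_risk_value`, `rx_risk_band`,
#'   `person_time` (years), `event` (0/1 first fracture in the interval).
#' @export
build_slices <- function(persons, scores, fractures,
                         definition = cohort_definition()) {
  stopifnot(inherits(definition, "cohort_definition"))
  p <- as.data.table(persons)
  s <- as.data.table(scores)
  f <- as.data.table(fractures)
  f <- f[person_id %in% p$person_id]
  if (nrow(f) && any(f$is_history)) {
    stop("fracture history records present for cohort persons; ",
         "run apply_washout() first")
  }
  first_fx <- if (nrow(f)) {
    f[, .(fx_ym = min(year * 12L + month)), by = person_id]
  } else {
    data.table(person_id = p$person_id[0], fx_ym = integer())
  }
  p <- first_fx[p, on = "person_id"]
  end_ym_study <- definition$end_year * 12L + 12L
  p[, entry_year := pmax(definition$start_year, birth_year + definition$min_age)]
  p[, death_ym := ifelse(is.na(death_year), NA_integer_,
                         death_year * 12L + death_month)]
  p[, emig_ym := ifelse(is.na(emig_year), NA_integer_,
                        emig_year * 12L + emig_month)]
  p[, exit_ym := pmin(end_ym_study, death_ym, emig_ym, fx_ym, na.rm = TRUE)]
  p[, event := as.integer(!is.na(fx_ym) & fx_ym == exit_ym)]
  early <- p[!is.na(fx_ym) & (fx_ym - 1L) %/% 12L < entry_year]
  if (nrow(early)) {
    stop("fracture before cohort entry for person(s) ",
         paste(head(early$person_id, 5L), collapse = ", "),
         "; washout/entry rules violated")
  }
  p[, exit_year := (exit_ym - 1L) %/% 12L]
  p[, exit_month := exit_ym - exit_year * 12L]
  p <- p[exit_year >= entry_year]
  if (nrow(p) == 0L) {
    stop("no person contributes follow-up time under this cohort definition")
  }
  slices <- p[, .(calendar_year = entry_year:exit_year),
              by = .(person_id, sex, birth_year, entry_year, exit_year,
                     exit_month, event)]
  slices[, person_time := ifelse(calendar_year < exit_year, 1,
                                 exit_month / 12)]
  slices[, event := as.integer(event == 1L & calendar_year == exit_year)]
  slices[, attained_age := calendar_year - birth_year]
  ## lagged exposure
  s_lag <- s[, .(person_id, calendar_year = year + 1L, rx_risk_value = rx_risk)]
  slices <- s_lag[slices, on = c("person_id", "calendar_year")]
  covered <- definition$score_years[1]:definition$score_years[2]
  absent <- setdiff(intersect(unique(slices$calendar_year) - 1L, covered),
                    unique(s$year))
  if (length(absent)) {
    warning("no scores supplied for exposure year(s) ",
            paste(absent, collapse = ", "), "; exposure set to missing")
  }
  slices[, rx_risk_band := band_rx_risk(rx_risk_value)]
  out <- slices[, .(person_id, calendar_year, sex, birth_year, attained_age,
                    rx_risk_value, rx_risk_band, person_time, event)]
  setkey(out, person_id, calendar_year)
  out[]
}
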