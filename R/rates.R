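#' Aggregate exposure slices into analysis cells
#'
#' Sums events and person-years over sex, birth year, calendar year and
#' exposure (either the Rx-Risk band, or the exact lagged score for
#' continuous-trend models). Totals are conserved exactly: the cell sums
#' equal the slice sums.
#'
#' @param slices Slices from [build_slices()].
#' @param exposure `"band"` (default) or `"score"`.
#' @return `data.table` of cells with `sex`, `birth_year`, `calendar_year`,
#'   `age_group`, the exposure column (`rx_risk_band` or `rx_risk_value`),
#'   `events` and `person_years`.
#' @export
aggregate_slices <- function(slices, exposure = c("band", "score")) {
  exposure <- match.arg(exposure)
  sl <- as.data.table(slices)
  expo_col <- if (exposure == "band") "rx_risk_band" else "rx_risk_value"
  cells <- sl[, .(events = sum(event), person_years = sum(person_time)),
              by = c("sex", "birth_year", "calendar_year", expo_col)]
  cells[, age_group := age_group(calendar_year - birth_year)]
  setcolorder(cells, c("sex", "birth_year", "calendar_year", "age_group",
                       expo_col, "events", "person_years"))
  setkeyv(cells, c("sex", "birth_year", "calendar_year", expo_col))
  cells[]
}

#' Directly standardized incidence rates per 10,000 person-years
#'
#' Computes, for each group defined by `by` (default sex x age group x
#' Rx-Risk band), the weighted mean of stratum-specific rates over birth
#' year x calendar year strata, using a fixed standard distribution. The
#' default standard is the whole supplied population's person-time
#' distribution over those strata. Confidence intervals use the normal
#' approximation on the rate scale with Poisson stratum variances.
#'
#' @param cells Cells from [aggregate_slices()].
#' @param by Character vector of grouping columns.
#' @param standard Optional `data.table` with `birth_year`, `calendar_year`
#'   and `weight` columns; defaults to the person-time distribution of
#'   `cells`.
#' @param per Rate denominator scale (default 10,000 person-years).
#' @return `data.table` with the `by` columns plus `events`, `person_years`,
#'   `rate`, `ci_low`, `ci_high` (rates per `per` person-years).
#' @export
standardized_rates <- function(cells,
                               by = c("sex", "age_group", "rx_risk_band"),
                               standard = NULL, per = 1e4) {
  cl <- as.data.table(cells)
  if (is.null(standard)) {
    standard <- cl[, .(weight = sum(person_years)),
                   by = .(birth_year, calendar_year)]
    standard[, weight := weight / sum(weight)]
  }
  standard <- as.data.table(standard)
  stopifnot(all(c("birth_year", "calendar_year", "weight") %in% names(standard)))
  grp <- cl[, .(events = sum(events), person_years = sum(person_years)),
            by = c(by, "birth_year", "calendar_year")]
  grp <- standard[grp, on = c("birth_year", "calendar_year")]
  grp[is.na(weight), weight := 0]
  empty <- grp[person_years <= 0 & weight > 0]
  if (nrow(empty)) {
    warning(nrow(empty), " standard stratum(s) with zero person-time ",
            "skipped and weights renormalized")
    grp <- grp[person_years > 0]
  } else {
    grp <- grp[person_years > 0]
  }
  out <- grp[, {
    w <- weight / sum(weight)
    r <- events / person_years
    v <- sum(w^2 * events / person_years^2)
    rate <- sum(w * r) * per
    half <- qnorm(0.975) * sqrt(v) * per
    .(events = sum(events), person_years = sum(person_years),
      rate = rate, ci_low = max(0, rate - half), ci_high = rate + half)
  }, by = by]
  setkeyv(out, by)
  out[]
}

#' Mood's median test for two samples
#'
#' Non-parametric equality-of-medians test: counts of observations above
#' versus at-or-below the pooled median form a 2x2 table tested with a
#' continuity-corrected chi-square.
#'
#' @param values_a,values_b Numeric vectors.
#' @return The two-sided p-value.
#' @export
median_test <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (!length(values_a) || !length(values_b)) stop("both samples must be non-empty")
  m <- median(c(values_a, values_b))
  tab <- rbind(c(sum(values_a > m), sum(values_a <= m)),
               c(sum(values_b > m), sum(values_b <= m)))
  if (any(colSums(tab) == 0L)) {
    warning("no variation around the pooled median; p = 1")
    return(1)
  }
  suppressWarnings(chisq.test(tab, correct = TRUE)$p.value)
}

#' Descriptive characteristics of the cohort for one calendar year
#'
#' Summarizes, by sex, attained-age group and fracture status within the
#' chosen year: the number of individuals, their person-years, and the
#' median (IQR) attained age and lagged Rx-Risk.
#'
#' @param slices Slices from [build_slices()].
#' @param year Calendar year inside follow-up.
#' @return `data.table`, one row per sex x age group x fracture status.
#' @export
describe_slices <- function(slices, year) {
  sl <- as.data.table(slices)
  if (!year %in% unique(sl$calendar_year)) {
    stop("year ", year, " not inside follow-up")
  }
  yr <- year
  sl <- sl[calendar_year == yr]
  sl[, fracture := factor(ifelse(event == 1L, "fracture", "no fracture"),
                          levels = c("fracture", "no fracture"))]
  qt <- function(x, p) as.double(quantile(x, p, na.rm = TRUE, names = FALSE))
  out <- sl[, .(
    n_individuals = .N,
    person_years = sum(person_time),
    median_age = as.double(median(attained_age)),
    age_q1 = qt(attained_age, 0.25), age_q3 = qt(attained_age, 0.75),
    median_rx_risk = as.double(median(rx_risk_value, na.rm = TRUE)),
    rx_q1 = qt(rx_risk_value, 0.25), rx_q3 = qt(rx_risk_value, 0.75)
  ), by = .(sex, age_group = age_group(attained_age), fracture)]
  setkey(out, sex, age_group, fracture)
  out[]
}
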