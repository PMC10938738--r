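## Negative-binomial count model with log person-time offset.
##
## Uses the quadratic-variance parameterization Var = mu * (1 + alpha * mu)
## (alpha = 1/theta in MASS terms). When the data are equidispersed the
## theta iteration diverges towards +Inf; in that case the fit collapses to
## the Poisson limit, which is returned with alpha = 0.
fit_count_model <- function(formula, data, family = c("nb", "poisson")) {
  family <- match.arg(family)
  if (family == "poisson") {
    fit <- glm(formula, family = poisson(), data = data)
    if (!fit$converged) stop("Poisson fit did not converge; last deviance ",
                             format(fit$deviance))
    return(list(fit = fit, family = "poisson",
                alpha = 0, alpha_ci = c(0, 0)))
  }
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(formula, data = data,
                                  control = glm.control(maxit = 100))),
    error = function(e) e)
  theta_big <- !inherits(fit, "error") &&
    (!is.finite(fit$theta) || fit$theta > 1e7)
  if (inherits(fit, "error") || theta_big) {
    ## Poisson limit: equidispersed data, theta unbounded
    pfit <- glm(formula, family = poisson(), data = data)
    if (!pfit$converged) {
      stop("negative-binomial fit failed and Poisson fallback did not ",
           "converge; last deviance ", format(pfit$deviance))
    }
    return(list(fit = pfit, family = "poisson_limit",
                alpha = 0, alpha_ci = c(0, 0)))
  }
  if (!fit$converged) stop("negative-binomial fit did not converge; ",
                           "last deviance ", format(fit$deviance))
  alpha <- 1 / fit$theta
  se_log_alpha <- fit$SE.theta / fit$theta   # delta method on log scale
  alpha_ci <- alpha * exp(c(-1, 1) * qnorm(0.975) * se_log_alpha)
  list(fit = fit, family = "nb", alpha = alpha, alpha_ci = alpha_ci)
}

wald_irr <- function(fit, terms_regex) {
  sm <- summary(fit)$coefficients
  rows <- grep(terms_regex, rownames(sm), value = TRUE)
  est <- sm[rows, "Estimate"]
  se <- sm[rows, "Std. Error"]
  data.table(term = rows, irr = exp(est),
             ci_low = exp(est - qnorm(0.975) * se),
             ci_high = exp(est + qnorm(0.975) * se))
}

adjust_terms <- function(adjust, year_terms) {
  if (!length(adjust)) return(character())
  if (year_terms == "factor") paste0("factor(", adjust, ")") else adjust
}

new_irr_result <- function(irr, model, reference = NA_character_,
                           n_events = NA_real_, person_years = NA_real_) {
  structure(list(irr = irr, alpha = model$alpha, alpha_ci = model$alpha_ci,
                 family = model$family, reference = reference,
                 n_events = n_events, person_years = person_years,
                 fit = model$fit),
            class = "rxrisk_irr")
}

#' @export
print.rxrisk_irr <- function(x, digits = 3, ...) {
  cat("Incidence rate ratios (", x$family, " fit",
      if (!is.na(x$reference)) paste0(", reference: ", x$reference), ")\n",
      sep = "")
  print(x$irr[, .(term, irr = round(irr, digits),
                  ci_low = round(ci_low, digits),
                  ci_high = round(ci_high, digits))])
  if (x$family == "nb") {
    cat(sprintf("dispersion alpha %.4f (95%% CI: %.4f, %.4f)\n",
                x$alpha, x$alpha_ci[1], x$alpha_ci[2]))
  }
  invisible(x)
}

#' Incidence rate ratios by Rx-Risk band
#'
#' Negative-binomial regression of event counts on Rx-Risk band indicators
#' with a log person-years offset, adjusted for birth year and calendar
#' year, using band `"<=0"` as the reference. The `missing` band is kept as
#' its own indicator. Exponentiated coefficients with Wald 95% CIs are
#' returned together with the dispersion estimate alpha (variance
#' `mu * (1 + alpha * mu)`; alpha near 0 means the data are Poisson-like).
#'
#' @param cells Cells from [aggregate_slices()] (band exposure).
#' @param sex Optional `"female"` or `"male"` to stratify.
#' @param age Optional age-group label (`"51-65"`, `"66-80"`, `">80"`).
#' @param adjust Adjustment columns (default birth year and calendar year).
#' @param year_terms `"continuous"` (default) or `"factor"` parameterization
#'   of the adjustment terms.
#' @param family `"nb"` (default) or `"poisson"`.
#' @param reference Reference band (default `"<=0"`).
#' @return An object of class `rxrisk_irr`: a list with the IRR table
#'   (`$irr`, including the reference row at exactly 1), the dispersion
#'   estimate (`$alpha`, `$alpha_ci`), the family actually used and the
#'   underlying fit.
#' @export
fit_band_irr <- function(cells, sex = NULL, age = NULL,
                         adjust = c("birth_year", "calendar_year"),
                         year_terms = c("continuous", "factor"),
                         family = c("nb", "poisson"), reference = "<=0") {
  year_terms <- match.arg(year_terms)
  family <- match.arg(family)
  cl <- as.data.table(cells)
  stopifnot("rx_risk_band" %in% names(cl))
  if (!is.null(sex)) { sx <- sex; cl <- cl[sex == sx] }
  if (!is.null(age)) { ag <- age; cl <- cl[age_group == ag] }
  if (nrow(cl) == 0L) stop("no cells left after stratification")
  use <- cl[, .(person_years = sum(person_years)), by = rx_risk_band]
  dead_bands <- as.character(use[person_years <= 0, rx_risk_band])
  present <- setdiff(intersect(levels(cl$rx_risk_band),
                               as.character(unique(cl$rx_risk_band))),
                     dead_bands)
  if (length(dead_bands)) {
    warning("band(s) with zero person-time dropped: ",
            paste(dead_bands, collapse = ", "))
    cl <- cl[as.character(rx_risk_band) %in% present]
  }
  if (!reference %in% present) stop("reference band ", reference,
                                    " has no person-time")
  if (cl[as.character(rx_risk_band) == reference, sum(events)] == 0) {
    stop("reference band ", reference, " has zero events")
  }
  cl[, band := factor(as.character(rx_risk_band), levels = present)]
  cl[, band := stats::relevel(band, ref = reference)]
  rhs <- c("band", adjust_terms(adjust, year_terms),
           "offset(log(person_years))")
  fml <- as.formula(paste("events ~", paste(rhs, collapse = " + ")))
  model <- fit_count_model(fml, cl, family)
  tab <- wald_irr(model$fit, "^band")
  tab[, term := sub("^band", "", term)]
  ref_row <- data.table(term = reference, irr = 1, ci_low = 1, ci_high = 1)
  tab <- rbind(ref_row, tab)
  tab[, term := factor(term, levels = present)]
  setorder(tab, term)
  tab[, term := as.character(term)]
  new_irr_result(tab, model, reference = reference,
                 n_events = sum(cl$events), person_years = sum(cl$person_years))
}

#' Incidence rate ratio per unit of Rx-Risk
#'
#' Fits the lagged score as a continuous covariate on cells aggregated by
#' exact score value (see [aggregate_slices()] with `exposure = "score"`);
#' person-years with a missing score are excluded.
#'
#' @inheritParams fit_band_irr
#' @param cells Cells from `aggregate_slices(slices, exposure = "score")`.
#' @return An `rxrisk_irr` with a single `per_unit` term.
#' @export
fit_trend_irr <- function(cells, sex = NULL,
                          adjust = c("birth_year", "calendar_year"),
                          year_terms = c("continuous", "factor"),
                          family = c("nb", "poisson")) {
  year_terms <- match.arg(year_terms)
  family <- match.arg(family)
  cl <- as.data.table(cells)
  stopifnot("rx_risk_value" %in% names(cl))
  if (!is.null(sex)) { sx <- sex; cl <- cl[sex == sx] }
  cl <- cl[!is.na(rx_risk_value)]
  if (uniqueN(cl$rx_risk_value) < 2L) {
    stop("need at least 2 distinct score values for a continuous trend")
  }
  rhs <- c("rx_risk_value", adjust_terms(adjust, year_terms),
           "offset(log(person_years))")
  fml <- as.formula(paste("events ~", paste(rhs, collapse = " + ")))
  model <- fit_count_model(fml, cl, family)
  tab <- wald_irr(model$fit, "^rx_risk_value$")
  tab[, term := "per_unit"]
  new_irr_result(tab, model, n_events = sum(cl$events),
                 person_years = sum(cl$person_years))
}

#' Likelihood-ratio test for effect modification of the Rx-Risk association
#'
#' Compares the band model with and without exposure-by-modifier product
#' terms; the modifier is sex, birth year or calendar year.
#'
#' @inheritParams fit_band_irr
#' @param modifier One of `"sex"`, `"birth_year"`, `"calendar_year"`.
#' @return The likelihood-ratio p-value.
#' @export
test_interaction <- function(cells, modifier = c("sex", "birth_year",
                                                 "calendar_year"),
                             adjust = c("birth_year", "calendar_year"),
                             family = c("nb", "poisson"),
                             reference = "<=0") {
  modifier <- match.arg(modifier)
  family <- match.arg(family)
  cl <- as.data.table(cells)
  if (uniqueN(cl[[modifier]]) < 2L) {
    stop("modifier ", modifier, " has fewer than 2 levels")
  }
  cl <- cl[person_years > 0]
  cl[, band := stats::relevel(factor(as.character(rx_risk_band)),
                              ref = reference)]
  mod_term <- if (modifier == "sex") "factor(sex)" else modifier
  base <- unique(c(mod_term, adjust_terms(adjust, "continuous")))
  rhs_red <- c("band", base, "offset(log(person_years))")
  rhs_full <- c("band", base, paste0("band:", mod_term),
                "offset(log(person_years))")
  f_red <- as.formula(paste("events ~", paste(rhs_red, collapse = " + ")))
  f_full <- as.formula(paste("events ~", paste(rhs_full, collapse = " + ")))
  m_red <- fit_count_model(f_red, cl, family)
  m_full <- fit_count_model(f_full, cl, family)
  if (m_red$family != m_full$family) {
    ## a log-likelihood comparison needs one family; use the Poisson limit
    m_red <- fit_count_model(f_red, cl, "poisson")
    m_full <- fit_count_model(f_full, cl, "poisson")
  }
  ll_red <- logLik(m_red$fit)
  ll_full <- logLik(m_full$fit)
  df <- length(coef(m_full$fit)) - length(coef(m_red$fit))
  if (df <= 0) stop("interaction model is not a proper extension ",
                    "of the reduced model")
  stat <- max(0, 2 * (as.numeric(ll_full) - as.numeric(ll_red)))
  pchisq(stat, df = df, lower.tail = FALSE)
}

#' Women-versus-men incidence rate ratios by band and age group
#'
#' Within each Rx-Risk band x age-group stratum, fits a count model with a
#' sex indicator (men as reference), adjusted for birth year and calendar
#' year, and returns the exponentiated sex coefficient.
#'
#' @inheritParams fit_band_irr
#' @return `data.table` with `rx_risk_band`, `age_group`, `irr`, `ci_low`,
#'   `ci_high`, `n_events`; single-sex strata are skipped with a warning.
#' @export
sex_contrast <- function(cells, adjust = c("birth_year", "calendar_year"),
                         family = c("nb", "poisson")) {
  family <- match.arg(family)
  cl <- as.data.table(cells)
  cl <- cl[person_years > 0]
  strata <- unique(cl[, .(rx_risk_band, age_group)])
  out <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    sub <- cl[rx_risk_band == strata$rx_risk_band[i] &
                age_group == strata$age_group[i]]
    if (uniqueN(sub$sex) < 2L || sum(sub$events) == 0) {
      warning("stratum ", strata$rx_risk_band[i], " x ",
              strata$age_group[i], " skipped (single sex or no events)")
      next
    }
    sub[, female := as.integer(sex == "female")]
    rhs <- c("female", adjust_terms(adjust, "continuous"),
             "offset(log(person_years))")
    fml <- as.formula(paste("events ~", paste(rhs, collapse = " + ")))
    model <- fit_count_model(fml, sub, family)
    tab <- wald_irr(model$fit, "^female$")
    out[[i]] <- data.table(rx_risk_band = strata$rx_risk_band[i],
                           age_group = strata$age_group[i],
                           irr = tab$irr, ci_low = tab$ci_low,
                           ci_high = tab$ci_high,
                           n_events = sum(sub$events))
  }
  res <- rbindlist(out)
  if (nrow(res)) setkey(res, rx_risk_band, age_group)
  res[]
}

#' Per-disease-category incidence rate ratios
#'
#' Uses the disease categories of one exposure year as simultaneous 0/1
#' indicators for first fractures in the following year, at the person
#' level, offset by each person's person-time in the outcome year and
#' adjusted for birth year (and sex when not stratifying). Within each
#' category, persons without the condition form the reference.
#'
#' @param slices Slices from [build_slices()].
#' @param category_sets Result of [assign_categories()].
#' @param exposure_year Calendar year whose categories are the exposure;
#'   outcomes are fractures in `exposure_year + 1`.
#' @param sex `"both"` (default, sex-adjusted), `"female"` or `"male"`.
#' @param family `"nb"` (default; collapses to the Poisson limit on
#'   person-level 0/1 counts) or `"poisson"`.
#' @return `data.table` with `category_id`, `irr`, `ci_low`, `ci_high`,
#'   `n_exposed`; empty categories are dropped with a warning.
#' @export
category_irr <- function(slices, category_sets, exposure_year,
                         sex = c("both", "female", "male"),
                         family = c("nb", "poisson")) {
  sex <- match.arg(sex)
  family <- match.arg(family)
  stopifnot(inherits(category_sets, "rxrisk_categories"))
  sl <- as.data.table(slices)
  outcome_year <- exposure_year + 1L
  sl <- sl[calendar_year == outcome_year]
  if (nrow(sl) == 0L) stop("no slices in outcome year ", outcome_year)
  if (sex != "both") { sx <- sex; sl <- sl[sex == sx] }
  cats <- category_sets$categories[year == exposure_year &
                                     person_id %in% sl$person_id]
  present <- sort(unique(cats$category_id))
  all_cats <- sort(unique(category_sets$categories$category_id))
  dropped <- setdiff(all_cats, present)
  if (length(dropped)) {
    warning(length(dropped), " empty categor",
            if (length(dropped) == 1L) "y" else "ies", " dropped: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  if (!length(present)) stop("no exposed categories in year ", exposure_year)
  X <- indicator_matrix(sl$person_id,
                        cats[, .(person_id, category_id)], present)
  df <- data.table(events = sl$event, person_years = sl$person_time,
                   birth_year = sl$birth_year,
                   female = as.integer(sl$sex == "female"))
  for (k in present) set(df, j = paste0("cat_", k), value = X[, k])
  rhs <- c(paste0("`cat_", present, "`"), "birth_year",
           if (sex == "both") "female", "offset(log(person_years))")
  fml <- as.formula(paste("events ~", paste(rhs, collapse = " + ")))
  model <- fit_count_model(fml, df, family)
  tab <- wald_irr(model$fit, "^`?cat_")
  tab[, term := gsub("^`?cat_|`$", "", term)]
  setnames(tab, "term", "category_id")
  tab[, n_exposed := as.integer(colSums(X)[category_id])]
  setkey(tab, category_id)
  tab[]
}

#' Latency analysis: banded IRRs with exposure fixed several years back
#'
#' Re-estimates the band association using the Rx-Risk of one fixed
#' exposure year against first fractures 1, 3 and 5 years later. For each
#' lag the risk set is the persons still under follow-up and fracture-free
#' at the start of the outcome year; persons who fractured, died or
#' emigrated in between are excluded. Scores above 15 are collapsed into a
#' single `">15"` band.
#'
#' @param slices Slices from [build_slices()].
#' @param scores Score table from [compute_scores()].
#' @param exposure_year Fixed exposure year (default 2007).
#' @param lags Integer vector of lags in years (default `c(1, 3, 5)`).
#' @param adjust Adjustment columns (default birth year; the calendar year
#'   is constant within a lag). Sex is always included.
#' @param family `"nb"` or `"poisson"`.
#' @return Named list (`"lag_1"`, ...) of `rxrisk_irr` objects.
#' @export
latency_analysis <- function(slices, scores, exposure_year = 2007L,
                             lags = c(1L, 3L, 5L), adjust = "birth_year",
                             family = c("nb", "poisson")) {
  family <- match.arg(family)
  sl <- as.data.table(slices)
  s <- as.data.table(scores)
  fu_years <- unique(sl$calendar_year)
  out <- list()
  for (lag in lags) {
    oy <- exposure_year + lag
    if (!oy %in% fu_years) stop("outcome year ", oy, " outside follow-up")
    risk <- sl[calendar_year == oy,
               .(person_id, sex, birth_year, person_time, event)]
    ey <- exposure_year
    risk <- s[year == ey, .(person_id, rx_risk)][risk, on = "person_id"]
    risk[, band := band_rx_risk(rx_risk, collapse_over_15 = TRUE)]
    risk[, band := stats::relevel(factor(as.character(band),
                                         levels = levels(band)[
                                           levels(band) %in% as.character(band)]),
                                  ref = "<=0")]
    risk[, female := as.integer(sex == "female")]
    rhs <- c("band", "female", adjust, "offset(log(person_time))")
    fml <- as.formula(paste("event ~", paste(rhs, collapse = " + ")))
    model <- fit_count_model(fml, risk, family)
    tab <- wald_irr(model$fit, "^band")
    tab[, term := sub("^band", "", term)]
    tab <- rbind(data.table(term = "<=0", irr = 1, ci_low = 1, ci_high = 1),
                 tab)
    out[[paste0("lag_", lag)]] <-
      new_irr_result(tab, model, reference = "<=0",
                     n_events = sum(risk$event),
                     person_years = sum(risk$person_time))
  }
  out
}

#' Sensitivity variants for person-years without an Rx-Risk
#'
#' Variant `"reassign_young_missing"` moves missing-score slices of persons
#' aged under 70 into the reference band `"<=0"` (treating them as
#' presumably healthy non-users); variant `"drop_missing"` excludes all
#' missing-score slices. Either variant is followed by the main band fit.
#'
#' @param slices Slices from [build_slices()].
#' @param variant `"reassign_young_missing"` or `"drop_missing"`.
#' @param ... Passed to [fit_band_irr()].
#' @return An `rxrisk_irr`; its `person_years` element reflects the variant
#'   cohort.
#' @export
sensitivity_variants <- function(slices,
                                 variant = c("reassign_young_missing",
                                             "drop_missing"), ...) {
  variant <- match.arg(variant)
  sl <- copy(as.data.table(slices))
  if (variant == "reassign_young_missing") {
    sl[rx_risk_band == "missing" & attained_age < 70,
       rx_risk_band := factor("<=0", levels = levels(sl$rx_risk_band))]
  } else {
    sl <- sl[rx_risk_band != "missing"]
  }
  fit_band_irr(aggregate_slices(sl), ...)
}
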