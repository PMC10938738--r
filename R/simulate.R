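#' Default synthetic disease-category specifications
#'
#' Twelve categories from the packaged mapping, each with a representative
#' full ATC code, a baseline annual fill probability, a log-odds loading on
#' the shared frailty, and a true one-year-mortality odds ratio. The true
#' ORs sit near the centres of the severity-weight bands so that the
#' implied "true" weights (OR passed through [map_or_to_weight()] with
#' p = 0, or p = 1 for a null OR of exactly 1) are stable targets for
#' calibration-recovery checks.
#'
#' @return `data.table` with columns `category_id`, `atc_code`,
#'   `base_fill_prob`, `fill_logodds_per_frailty`,
#'   `fill_logodds_per_year_age`, `true_or`.
#' @export
default_category_specs <- function() {
  specs <- data.table(
    category_id = c("hypertension", "hyperlipidaemia", "diabetes", "pain",
                    "depression", "chronic_airways_disease",
                    "congestive_heart_failure", "anticoagulants",
                    "malignancies", "dementia", "osteoporosis_pagets",
                    "steroid_responsive_disease"),
    atc_code = c("C07AB02", "C10AA01", "A10BA02", "N02AA01", "N06AB04",
                 "R03AC02", "C03DA01", "B01AA03", "L01AA01", "N06DA02",
                 "M05BA04", "H02AB06"),
    base_fill_prob = c(0.30, 0.25, 0.10, 0.15, 0.10, 0.10,
                       0.05, 0.08, 0.03, 0.03, 0.06, 0.07),
    fill_logodds_per_frailty = c(0.5, 0.4, 0.6, 0.8, 0.6, 0.5,
                                 0.8, 0.6, 0.4, 0.7, 0.3, 0.5),
    fill_logodds_per_year_age = rep(0.02, 12L),
    true_or = c(1.00, 0.90, 1.50, 1.30, 1.10, 1.70,
                2.50, 1.90, 2.50, 2.10, 1.10, 1.50))
  specs
}

## severity weight implied by a generating OR: a null OR (exactly 1) has,
## by construction, no evidence against the null
true_weights <- function(true_or) {
  map_or_to_weight(true_or, ifelse(true_or == 1, 1, 0))
}

#' Configuration for the synthetic registry generator
#'
#' Defaults emulate the registry linkage the analysis was designed for:
#' dispensing cross-sections 2005-2016 with fractures through 2017, about
#' 14% of person-years without an index fill, month-resolution death,
#' emigration and fracture dates, mortality driven by the disease
#' categories, and a fracture hazard log-linear in the previous year's true
#' score, attained age and sex.
#'
#' @param n_persons Number of persons.
#' @param year_range Two calendar years: first and last dispensing year
#'   (default 2005-2016); deaths and fractures run one year further.
#' @param seed Integer seed; mandatory, all randomness flows from it.
#' @param category_specs See [default_category_specs()].
#' @param frailty_sd Standard deviation of the per-person latent frailty
#'   shared across categories and years (default 1).
#' @param fracture_model List: `base_log_rate` (log events per person-year
#'   at age 70, male, score 0), `log_rr_per_unit` (per true-score unit),
#'   `log_rr_age` (per year of age), `log_rr_female`.
#' @param mortality_model List: `base_log_odds` (one-year death at age 70,
#'   female, no categories), `log_or_age`, `log_or_male`.
#' @param nonfiller_rate Probability that an alive person-year has no index
#'   fill (default 0.14).
#' @param emigration_rate Per-year emigration probability (default 0.002).
#' @param washout_history_rate Probability of a pre-follow-up (1994-2005)
#'   fracture history (default 0.02).
#' @param persistent_fills If `TRUE`, each person's category set is drawn
#'   once and repeated every year (a zero-drift score, useful for latency
#'   invariance checks); default `FALSE`.
#' @param prop_female Proportion of women (default 0.55).
#' @param baseline_ages Two bounds for age at the first dispensing year
#'   (default 50-95, populating all three attained-age groups).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_persons = 10000L,
                       year_range = c(2005L, 2016L),
                       seed = 1L,
                       category_specs = default_category_specs(),
                       frailty_sd = 1,
                       fracture_model = list(base_log_rate = log(30 / 1e4),
                                             log_rr_per_unit = log(1.07),
                                             log_rr_age = 0.08,
                                             log_rr_female = log(1.5)),
                       mortality_model = list(base_log_odds = qlogis(0.03),
                                              log_or_age = 0.09,
                                              log_or_male = 0.3),
                       nonfiller_rate = 0.14,
                       emigration_rate = 0.002,
                       washout_history_rate = 0.02,
                       persistent_fills = FALSE,
                       prop_female = 0.55,
                       baseline_ages = c(50L, 95L)) {
  specs <- as.data.table(category_specs)
  if (nrow(specs) == 0L) stop("category_specs must contain at least one category")
  stopifnot(
    n_persons >= 1,
    diff(year_range) >= 1,  # lagged exposure needs a preceding year
    is.numeric(seed), length(seed) == 1L,
    frailty_sd >= 0,
    all(specs$base_fill_prob >= 0 & specs$base_fill_prob <= 1),
    nonfiller_rate >= 0, nonfiller_rate <= 1,
    emigration_rate >= 0, emigration_rate <= 1,
    washout_history_rate >= 0, washout_history_rate <= 1,
    all(specs$true_or > 0)
  )
  structure(list(n_persons = as.integer(n_persons),
                 year_range = as.integer(year_range),
                 seed = as.integer(seed),
                 category_specs = specs,
                 frailty_sd = frailty_sd,
                 fracture_model = fracture_model,
                 mortality_model = mortality_model,
                 nonfiller_rate = nonfiller_rate,
                 emigration_rate = emigration_rate,
                 washout_history_rate = washout_history_rate,
                 persistent_fills = isTRUE(persistent_fills),
                 prop_female = prop_female,
                 baseline_ages = as.integer(baseline_ages)),
            class = "sim_config")
}

#' Simulate linked person, dispensing and fracture registry tables
#'
#' Generates an open synthetic cohort year by year: each alive, in-country
#' person-year either fills no index medication (with probability
#' `nonfiller_rate`) or fills each category independently with logit-linear
#' probability in the shared frailty and attained age (fillers are
#' guaranteed at least one category). Death in year `t + 1` is Bernoulli
#' with logit-linear dependence on the year-`t` category indicators (the
#' true ORs), sex and age; the first fracture in year `t + 1` is drawn from
#' a constant within-year hazard that is log-linear in the year-`t` true
#' score, age and sex, truncated at death or emigration. All dates have
#' month resolution; identical configurations (including the seed) give
#' identical tables.
#'
#' @param config A [sim_config()].
#' @return List of `data.table`s: `persons`, `dispensings`, `fractures`
#'   (with `is_history` flagging pre-follow-up washout events), and
#'   `true_params` (the category specs with their implied true weights).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_persons
  specs <- config$category_specs
  K <- nrow(specs)
  tw <- true_weights(specs$true_or)
  log_or <- log(specs$true_or)
  fill_years <- config$year_range[1]:config$year_range[2]
  fm <- config$fracture_model
  mm <- config$mortality_model

  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(config$prop_female, 1 - config$prop_female))
  age0 <- sample(config$baseline_ages[1]:config$baseline_ages[2], n,
                 replace = TRUE)
  birth_year <- fill_years[1] - age0
  frailty <- rnorm(n) * config$frailty_sd

  hist_flag <- runif(n) < config$washout_history_rate
  n_hist <- sum(hist_flag)
  hist_fx <- data.table(person_id = which(hist_flag),
                        year = sample(1994:2005, n_hist, replace = TRUE),
                        month = sample(1:12, n_hist, replace = TRUE),
                        is_history = TRUE)

  death_yr <- rep(NA_integer_, n); death_mo <- rep(NA_integer_, n)
  emig_yr <- rep(NA_integer_, n); emig_mo <- rep(NA_integer_, n)
  fx_yr <- rep(NA_integer_, n); fx_mo <- rep(NA_integer_, n)
  FM_persist <- NULL
  disp <- vector("list", length(fill_years))

  for (ti in seq_along(fill_years)) {
    t <- fill_years[ti]
    age_t <- t - birth_year
    active <- (is.na(death_yr) | death_yr >= t) & (is.na(emig_yr) | emig_yr >= t)
    m_end <- rep(12L, n)
    m_end[!is.na(death_yr) & death_yr == t] <-
      death_mo[!is.na(death_yr) & death_yr == t]
    m_end[!is.na(emig_yr) & emig_yr == t] <-
      pmin(m_end, emig_mo)[!is.na(emig_yr) & emig_yr == t]

    ## fill probabilities (logit-linear in frailty and age)
    P <- plogis(outer(rep(1, n), qlogis(specs$base_fill_prob)) +
                  outer(frailty, specs$fill_logodds_per_frailty) +
                  outer(age_t - 70, specs$fill_logodds_per_year_age))
    if (config$persistent_fills) {
      if (is.null(FM_persist)) {
        FM_persist <- matrix(rbinom(n * K, 1L, as.vector(P)), n, K)
        FM_persist <- force_one_category(FM_persist, P, rep(TRUE, n))
      }
      FM <- FM_persist
    } else {
      FM <- matrix(rbinom(n * K, 1L, as.vector(P)), n, K)
    }
    nonfiller <- runif(n) < config$nonfiller_rate
    if (!config$persistent_fills) {
      FM <- force_one_category(FM, P, !nonfiller)
    }
    FM[nonfiller | !active, ] <- 0L

    ## dispensing rows for index fills
    idx <- which(FM == 1L)
    if (length(idx)) {
      pid <- ((idx - 1L) %% n) + 1L
      cat_i <- ((idx - 1L) %/% n) + 1L
      disp_t <- data.table(person_id = pid,
                           atc = specs$atc_code[cat_i],
                           year = t,
                           month = as.integer(ceiling(runif(length(idx)) *
                                                        m_end[pid])))
    } else {
      disp_t <- data.table(person_id = integer(), atc = character(),
                           year = integer(), month = integer())
    }
    ## some non-filler person-years still visit a pharmacy (non-index fill)
    ni <- which(nonfiller & active & runif(n) < 0.5)
    if (length(ni)) {
      disp_t <- rbind(disp_t, data.table(
        person_id = ni, atc = "V07AB01", year = t,
        month = as.integer(ceiling(runif(length(ni)) * m_end[ni]))))
    }
    disp[[ti]] <- disp_t

    score_t <- as.vector(FM %*% tw)
    score_t[nonfiller] <- 0  # missing score: baseline hazard/mortality

    ## death in year t + 1 (depends on year-t categories)
    t1 <- t + 1L
    lin_death <- mm$base_log_odds + mm$log_or_age * (t1 - birth_year - 70) +
      mm$log_or_male * (sex == "male") + as.vector(FM %*% log_or)
    can_die <- active & is.na(death_yr) & is.na(emig_yr)
    die <- can_die & runif(n) < plogis(lin_death)
    death_yr[die] <- t1
    death_mo[die] <- sample(1:12, sum(die), replace = TRUE)

    ## emigration in year t + 1 among the remaining alive
    can_emig <- can_die & !die
    emig <- can_emig & runif(n) < config$emigration_rate
    emig_yr[emig] <- t1
    emig_mo[emig] <- sample(1:12, sum(emig), replace = TRUE)

    ## first fracture in year t + 1, hazard from the year-t true score
    at_risk <- active & is.na(fx_yr) &
      (is.na(death_yr) | death_yr >= t1) & (is.na(emig_yr) | emig_yr >= t1)
    m_risk <- rep(12L, n)
    m_risk[die] <- death_mo[die]
    m_risk[emig] <- emig_mo[emig]
    lam <- exp(fm$base_log_rate + fm$log_rr_per_unit * score_t +
                 fm$log_rr_age * (t1 - birth_year - 70) +
                 fm$log_rr_female * (sex == "female"))
    p_fx <- 1 - exp(-lam * m_risk / 12)
    hit <- at_risk & runif(n) < p_fx
    fx_yr[hit] <- t1
    fx_mo[hit] <- as.integer(ceiling(runif(sum(hit)) * m_risk[hit]))
  }

  persons <- data.table(person_id = seq_len(n), sex = sex,
                        birth_year = birth_year,
                        death_year = death_yr, death_month = death_mo,
                        emig_year = emig_yr, emig_month = emig_mo)
  dispensings <- rbindlist(disp)
  setkey(dispensings, person_id, year, month)
  fx <- data.table(person_id = which(!is.na(fx_yr)),
                   year = fx_yr[!is.na(fx_yr)],
                   month = fx_mo[!is.na(fx_yr)],
                   is_history = FALSE)
  fractures <- rbind(hist_fx, fx)
  setkey(fractures, person_id, year)
  true_params <- copy(specs)[, true_weight := tw]
  list(persons = persons, dispensings = dispensings, fractures = fractures,
       true_params = true_params)
}

## guarantee rows flagged in `eligible` fill at least one category, sampling
## the forced category proportionally to that person's fill probabilities
force_one_category <- function(FM, P, eligible) {
  need <- which(eligible & rowSums(FM) == 0L)
  if (!length(need)) return(FM)
  Pn <- P[need, , drop = FALSE]
  tot <- rowSums(Pn)
  u <- runif(length(need)) * tot
  cum <- Pn
  if (ncol(cum) > 1L) {
    for (k in 2:ncol(cum)) cum[, k] <- cum[, k] + cum[, k - 1L]
  }
  pick <- max.col(cum >= u, ties.method = "first")
  FM[cbind(need, pick)] <- 1L
  FM
}

#' Write registry tables to disk
#'
#' @param tables List with `persons`, `dispensings`, `fractures` (as from
#'   [simulate_population()]; extra elements are ignored).
#' @param path Directory to write into (created if needed).
#' @param format `"csv"` (delimited text, default) or `"parquet"`
#'   (columnar; requires the arrow package).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_registry <- function(tables, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  names_out <- c("persons", "dispensings", "fractures")
  stopifnot(all(names_out %in% names(tables)))
  files <- file.path(path, paste0(names_out, ".", format))
  names(files) <- names_out
  for (nm in names_out) {
    tab <- as.data.table(tables[[nm]])
    if (format == "csv") {
      fwrite(tab, files[[nm]])
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("parquet output requires the arrow package")
      }
      arrow::write_parquet(tab, files[[nm]])
    }
  }
  invisible(files)
}

#' Read registry tables from disk
#'
#' Inverse of [write_registry()]: reads `persons`, `dispensings` and
#' `fractures` from a directory and restores column types.
#'
#' @param path Directory containing the tables.
#' @param format `"csv"` or `"parquet"`.
#' @return List of `data.table`s.
#' @export
read_registry <- function(path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  names_in <- c("persons", "dispensings", "fractures")
  out <- vector("list", 3L)
  names(out) <- names_in
  for (nm in names_in) {
    f <- file.path(path, paste0(nm, ".", format))
    if (!file.exists(f)) stop("missing registry file: ", f)
    tab <- if (format == "csv") {
      fread(f)
    } else {
      if (!requireNamespace("arrow", quietly = TRUE)) {
        stop("parquet input requires the arrow package")
      }
      as.data.table(arrow::read_parquet(f))
    }
    if (nm == "fractures" && nrow(tab)) tab[, is_history := as.logical(is_history)]
    if (nm == "fractures" && nrow(tab) == 0L) {
      tab <- data.table(person_id = integer(), year = integer(),
                        month = integer(), is_history = logical())
    }
    out[[nm]] <- tab
  }
  out
}
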