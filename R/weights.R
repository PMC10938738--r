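#' Map a mortality odds ratio and p-value to a severity weight
#'
#' The index assigns each disease category an integer severity weight from
#' its adjusted odds ratio (OR) for death in the following year: weight 0
#' for any OR whose p-value exceeds 0.10; otherwise weight -1 for OR < 1,
#' and weights 1 to 5 for ORs in successive 0.20-wide bands starting at
#' 1.00 (1.00-1.19, 1.20-1.39, 1.40-1.59, 1.60-1.79, 1.80-1.99), with
#' weight 6 for OR >= 2.00. Bands are half-open `[lower, lower + 0.20)` so
#' every positive OR maps to exactly one weight.
#'
#' @param odds_ratio Positive numeric vector of odds ratios.
#' @param p_value Numeric vector of two-sided p-values in `[0, 1]`; recycled
#'   against `odds_ratio`.
#' @return Integer vector of weights in `{-1, 0, 1, ..., 6}`.
#' @examples
#' map_or_to_weight(2.50, 0.01)  # 6
#' map_or_to_weight(1.50, 0.50)  # 0 (not significant)
#' map_or_to_weight(0.70, 0.01)  # -1
#' @export
map_or_to_weight <- function(odds_ratio, p_value) {
  n <- max(length(odds_ratio), length(p_value))
  odds_ratio <- rep_len(odds_ratio, n)
  p_value <- rep_len(p_value, n)
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0)) {
    stop("odds_ratio must be positive and finite")
  }
  if (any(!is.finite(p_value)) || any(p_value < 0 | p_value > 1)) {
    stop("p_value must lie in [0, 1]")
  }
  w <- integer(n)
  sig <- p_value <= 0.10
  w[sig & odds_ratio < 1] <- -1L
  pos <- sig & odds_ratio >= 1
  w[pos] <- findInterval(odds_ratio[pos], c(1.0, 1.2, 1.4, 1.6, 1.8, 2.0))
  w
}

#' Calibrate calendar-year severity weights from one-year mortality
#'
#' For each requested calendar year, fits a sex- and age-adjusted logistic
#' regression of death in the following year on indicator variables for all
#' disease categories simultaneously, over subjects aged >= 50 who filled at
#' least one prescription that year. Each category's exponentiated
#' coefficient (OR) and two-sided Wald p-value are passed through
#' [map_or_to_weight()] to give the year's severity weights.
#'
#' Categories with no users, no variation, or inestimable coefficients in a
#' given year receive weight 0 with a warning rather than aborting the year.
#'
#' @param category_sets Result of [assign_categories()].
#' @param persons `data.table` with `person_id`, `sex` ("female"/"male"),
#'   `birth_year`, and optional `death_year`, `death_month`, `emig_year`,
#'   `emig_month` (NA when absent).
#' @param years Integer vector of calibration years. Vital status must be
#'   known for `year + 1`, so the last dispensing year of the data is the
#'   last usable calibration year.
#' @param mapping Mapping whose categories define the rows of the weight
#'   table (default: the packaged mapping).
#' @param min_age Minimum age in the calibration year (default 50).
#' @return A `data.table` ("weight table") with one row per year x category:
#'   `year`, `category_id`, `odds_ratio`, `p_value`, `weight`, `n_exposed`,
#'   `n_deaths_exposed`.
#' @export
calibrate_weights <- function(category_sets, persons, years,
                              mapping = default_mapping(), min_age = 50L) {
  stopifnot(inherits(category_sets, "rxrisk_categories"))
  p <- as.data.table(persons)
  all_categories <- unique(mapping$category_id)
  out <- vector("list", length(years))
  for (i in seq_along(years)) {
    out[[i]] <- calibrate_one_year(category_sets, p, years[i],
                                   all_categories, min_age)
  }
  rbindlist(out)
}

calibrate_one_year <- function(category_sets, persons, year,
                               all_categories, min_age) {
  yr <- year
  py <- category_sets$person_years[year == yr, .(person_id)]
  pop <- persons[py, on = "person_id", nomatch = NULL]
  pop[, age := year - birth_year]
  pop <- pop[age >= min_age]
  ## must be under observation in year+1: not dead in or before `year`,
  ## not emigrated in or before `year`
  pop <- pop[is.na(death_year) | death_year > year]
  if ("emig_year" %in% names(pop)) pop <- pop[is.na(emig_year) | emig_year > year]
  zero_table <- function(msg) {
    if (!is.null(msg)) warning(msg)
    data.table(year = year, category_id = all_categories,
               odds_ratio = NA_real_, p_value = NA_real_, weight = 0L,
               n_exposed = 0L, n_deaths_exposed = 0L)
  }
  if (nrow(pop) == 0L) {
    return(zero_table(paste0("calibration year ", year,
                             ": no eligible subjects; all weights set to 0")))
  }
  pop[, death := as.integer(!is.na(death_year) & death_year == year + 1L)]
  cats <- category_sets$categories[year == yr & person_id %in% pop$person_id]
  X <- indicator_matrix(pop$person_id, cats, all_categories)
  exposed <- colSums(X)
  exp_deaths <- as.integer(crossprod(X, pop$death))
  estimable <- exposed > 0L & exposed < nrow(pop)
  if (length(var_d <- unique(pop$death)) == 1L) {
    return(zero_table(paste0("calibration year ", year,
                             ": outcome has no variation; all weights 0")))
  }
  df <- data.table(death = pop$death, age = pop$age,
                   sex = as.integer(pop$sex == "female"))
  covars <- c("age", "sex")[c(length(unique(pop$age)) > 1L,
                              length(unique(pop$sex)) > 1L)]
  keep <- all_categories[estimable]
  for (k in keep) set(df, j = paste0("cat_", k), value = X[, k])
  rhs <- c("1", covars,
           if (length(keep)) paste0("`cat_", keep, "`"))
  fml <- as.formula(paste("death ~", paste(rhs, collapse = " + ")))
  fit <- suppressWarnings(glm(fml, family = binomial(), data = df))
  sm <- summary(fit)$coefficients
  res <- data.table(year = year, category_id = all_categories,
                    odds_ratio = NA_real_, p_value = NA_real_, weight = 0L,
                    n_exposed = as.integer(exposed),
                    n_deaths_exposed = exp_deaths)
  rn <- paste0("cat_", res$category_id)
  hit <- match(rn, rownames(sm))
  got <- !is.na(hit)
  res[got, `:=`(odds_ratio = exp(sm[hit[got], "Estimate"]),
                p_value = sm[hit[got], "Pr(>|z|)"])]
  ok <- got & is.finite(res$odds_ratio) & is.finite(res$p_value)
  res[ok, weight := map_or_to_weight(odds_ratio, p_value)]
  dropped <- all_categories[!ok]
  if (length(dropped)) {
    warning("calibration year ", year, ": weight 0 assigned to ",
            length(dropped), " degenerate/unused categor",
            if (length(dropped) == 1L) "y" else "ies", ": ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  }
  res
}

## 0/1 matrix of category membership, rows aligned with person_ids
indicator_matrix <- function(person_ids, cats, all_categories) {
  X <- matrix(0L, nrow = length(person_ids), ncol = length(all_categories),
              dimnames = list(NULL, all_categories))
  if (nrow(cats)) {
    ri <- match(cats$person_id, person_ids)
    ci <- match(cats$category_id, all_categories)
    ok <- !is.na(ri) & !is.na(ci)
    X[cbind(ri[ok], ci[ok])] <- 1L
  }
  X
}
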