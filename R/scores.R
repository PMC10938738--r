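#' Compute yearly Rx-Risk scores from category sets and a weight table
#'
#' A person's total score for a calendar year is the sum of that year's
#' severity weights over the *distinct* disease categories from which they
#' filled at least one prescription. Observed person-years with no fill of
#' an index medication (only non-index fills) get a missing score (`NA`),
#' which is a distinct state from a score of 0 and is never coerced here;
#' downstream analyses decide how to treat it.
#'
#' @param category_sets Result of [assign_categories()].
#' @param weight_table Weight table from [calibrate_weights()] (or hand-built
#'   with columns `year`, `category_id`, `weight`).
#' @return `data.table` with `person_id`, `year`, `rx_risk` (integer, `NA`
#'   when missing), one row per observed person-year whose year is covered
#'   by the weight table.
#' @export
compute_scores <- function(category_sets, weight_table) {
  stopifnot(inherits(category_sets, "rxrisk_categories"))
  wt <- as.data.table(weight_table)
  stopifnot(all(c("year", "category_id", "weight") %in% names(wt)))
  py <- category_sets$person_years[year %in% unique(wt$year)]
  cats <- category_sets$categories[year %in% unique(wt$year)]
  miss <- cats[!wt, on = c("year", "category_id")]
  if (nrow(miss)) {
    stop("weight table does not cover categor",
         if (uniqueN(miss$category_id) == 1L) "y " else "ies ",
         paste(unique(head(miss$category_id, 5L)), collapse = ", "),
         " in year(s) ", paste(unique(head(miss$year, 5L)), collapse = ", "))
  }
  scored <- wt[cats, on = c("year", "category_id")][
    , .(rx_risk = as.integer(sum(weight))), by = .(person_id, year)]
  out <- scored[py[, .(person_id, year)], on = c("person_id", "year")]
  setkey(out, person_id, year)
  out[]
}
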