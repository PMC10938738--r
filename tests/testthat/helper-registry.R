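## Shared fixtures, built once per test run.

.rxrisk_test_cache <- new.env(parent = emptyenv())

## A moderate simulated registry plus all derived pipeline products,
## reused across test files.
shared_pipeline <- function() {
  if (is.null(.rxrisk_test_cache$pipe)) {
    cfg <- sim_config(n_persons = 20000L, seed = 7L)
    reg <- simulate_population(cfg)
    mapping <- default_mapping()
    category_sets <- assign_categories(reg$dispensings, mapping)
    weights <- suppressWarnings(
      calibrate_weights(category_sets, reg$persons, 2005:2016, mapping))
    scores <- compute_scores(category_sets, weights)
    persons <- suppressMessages(apply_washout(reg$persons, reg$fractures))
    persons <- require_any_dispensing(persons, reg$dispensings)
    slices <- build_slices(persons, scores, reg$fractures)
    .rxrisk_test_cache$pipe <- list(
      config = cfg, registry = reg, mapping = mapping,
      category_sets = category_sets, weights = weights, scores = scores,
      persons = persons, slices = slices,
      cells = aggregate_slices(slices),
      score_cells = aggregate_slices(slices, exposure = "score"))
  }
  .rxrisk_test_cache$pipe
}

## Minimal persons table; death/emigration columns NA unless supplied.
make_persons <- function(n, sex = "female", birth_year = 1940L,
                         death_year = NA_integer_, death_month = NA_integer_,
                         emig_year = NA_integer_, emig_month = NA_integer_) {
  data.table::data.table(
    person_id = seq_len(n), sex = rep_len(sex, n),
    birth_year = rep_len(as.integer(birth_year), n),
    death_year = rep_len(as.integer(death_year), n),
    death_month = rep_len(as.integer(death_month), n),
    emig_year = rep_len(as.integer(emig_year), n),
    emig_month = rep_len(as.integer(emig_month), n))
}

make_dispensings <- function(person_id, atc, year, month = 6L) {
  data.table::data.table(person_id = person_id, atc = atc,
                         year = as.integer(year),
                         month = rep_len(as.integer(month), length(person_id)))
}

make_fractures <- function(person_id = integer(), year = integer(),
                           month = integer(), is_history = logical()) {
  n <- length(person_id)
  data.table::data.table(person_id = person_id, year = as.integer(year),
                         month = rep_len(as.integer(month), n),
                         is_history = rep_len(as.logical(is_history), n))
}

## A tiny one-category mapping for closed-form calibration checks.
tiny_mapping <- function() {
  f <- tempfile(fileext = ".csv")
  data.table::fwrite(data.table::data.table(
    atc_prefix = "A10", category_id = "diabetes",
    category_name = "Diabetes"), f)
  load_mapping(f)
}

## Hand-built slices table.
make_slices <- function(...) {
  sl <- data.table::data.table(...)
  if (!"rx_risk_band" %in% names(sl) && "rx_risk_value" %in% names(sl)) {
    sl[, rx_risk_band := band_rx_risk(rx_risk_value)]
  }
  sl
}
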