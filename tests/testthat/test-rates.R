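test_that("aggregation conserves events and person-time exactly", {
  pipe <- shared_pipeline()
  cells <- pipe$cells
  expect_equal(sum(cells$events), sum(pipe$slices$event))
  expect_equal(sum(cells$person_years), sum(pipe$slices$person_time))
  ## shuffled input gives identical cells
  set.seed(1)
  shuffled <- pipe$slices[sample(.N)]
  expect_equal(aggregate_slices(shuffled), cells)
})

test_that("a hand-built fixture aggregates to hand-summed cells", {
  sl <- make_slices(
    person_id = 1:12,
    calendar_year = rep(c(2010L, 2011L), each = 6L),
    sex = rep(c("female", "male"), 6L),
    birth_year = 1940L,
    attained_age = rep(c(70L, 71L), each = 6L),
    rx_risk_value = 3L,
    person_time = rep(c(1, 0.5), 6L),
    event = rep(c(0L, 1L), 6L))
  cells <- aggregate_slices(sl)
  expect_equal(nrow(cells), 4L)  # 2 sexes x 2 years
  ## hand sums: females hold slices 1, 3, 5 of each year (pt 1, event 0),
  ## males slices 2, 4, 6 (pt 0.5, event 1)
  expect_equal(cells[sex == "female" & calendar_year == 2010L, events], 0L)
  expect_equal(cells[sex == "male" & calendar_year == 2010L, events], 3L)
  expect_equal(cells[sex == "female" & calendar_year == 2010L, person_years], 3)
  expect_equal(cells[sex == "male" & calendar_year == 2010L, person_years], 1.5)
  ## single slice: single identical cell
  c1 <- aggregate_slices(sl[1L])
  expect_equal(c1$events, 0L)
  expect_equal(c1$person_years, 1)
})

test_that("standardization reduces to the crude rate in degenerate cases", {
  sl <- make_slices(person_id = 1:2, calendar_year = 2010L,
                    sex = "female", birth_year = 1940L, attained_age = 70L,
                    rx_risk_value = 3L, person_time = c(1, 1),
                    event = c(1L, 0L))
  r <- standardized_rates(aggregate_slices(sl), by = "rx_risk_band")
  expect_equal(r$rate, 1 / 2 * 1e4)
  expect_true(r$ci_low <= r$rate && r$rate <= r$ci_high)
})

test_that("standardized rate is the weighted mean of stratum rates", {
  ## two strata with rates 10 and 30 per 10,000 PY and 50/50 weights
  cells <- data.table::data.table(
    sex = "female", birth_year = c(1940L, 1930L), calendar_year = 2010L,
    age_group = factor(c("66-80", ">80"), levels = c("51-65", "66-80", ">80")),
    rx_risk_band = band_rx_risk(c(3L, 3L)),
    events = c(10L, 30L), person_years = c(1e4, 1e4))
  std <- data.table::data.table(birth_year = c(1940L, 1930L),
                                calendar_year = 2010L, weight = c(0.5, 0.5))
  r <- standardized_rates(cells, by = "rx_risk_band", standard = std)
  expect_equal(r$rate, 20)
  ## splitting a cell into sub-cells with the same totals changes nothing
  cells2 <- rbind(cells[1L][, `:=`(events = 4L, person_years = 4e3)],
                  cells[1L][, `:=`(events = 6L, person_years = 6e3)],
                  cells[2L])
  r2 <- standardized_rates(cells2, by = "rx_risk_band", standard = std)
  expect_equal(r2$rate, r$rate)
})

test_that("standardization equals the crude rate when distributions coincide", {
  pipe <- shared_pipeline()
  cells <- pipe$cells
  crude <- sum(cells$events) / sum(cells$person_years) * 1e4
  ## one overall group: the default standard IS the target distribution
  cl <- data.table::copy(cells)[, grp := "all"]
  r <- standardized_rates(cl, by = "grp")
  expect_equal(r$rate, crude, tolerance = 1e-12)
})

test_that("a missing standard stratum is skipped with renormalized weights", {
  cells <- data.table::data.table(
    sex = "female", birth_year = c(1940L, 1930L), calendar_year = 2010L,
    age_group = factor(c("66-80", ">80"), levels = c("51-65", "66-80", ">80")),
    rx_risk_band = band_rx_risk(c(3L, 3L)),
    events = c(10L, 0L), person_years = c(1e4, 0))
  std <- data.table::data.table(birth_year = c(1940L, 1930L),
                                calendar_year = 2010L, weight = c(0.5, 0.5))
  expect_warning(r <- standardized_rates(cells, by = "rx_risk_band",
                                         standard = std), "zero person-time")
  expect_equal(r$rate, 10)
})

test_that("the median test matches a closed-form chi-square and has power", {
  expect_warning(p_ident <- median_test(rep(2, 30), rep(2, 40)), "p = 1")
  expect_equal(p_ident, 1)
  ## table (30,10 / 10,30): hand-computed continuity-corrected chi-square
  a <- c(rep(1, 30), rep(0, 10))   # pooled median is 0.5
  b <- c(rep(1, 10), rep(0, 30))
  n <- 80; r1 <- 40; r2 <- 40; c1 <- 40; c2 <- 40
  chi <- n * (abs(30 * 30 - 10 * 10) - n / 2)^2 / (r1 * r2 * c1 * c2)
  expect_equal(median_test(a, b), pchisq(chi, 1, lower.tail = FALSE))
  ## large shifted samples are detected
  set.seed(3)
  expect_lt(median_test(rnorm(5000), rnorm(5000, 0.2)), 1e-3)
  expect_error(median_test(numeric(), 1:3), "non-empty")
})

test_that("the descriptive table is internally consistent with aggregation", {
  pipe <- shared_pipeline()
  tab <- describe_slices(pipe$slices, 2012L)
  cells12 <- pipe$cells[calendar_year == 2012L]
  expect_equal(sum(tab$person_years), sum(cells12$person_years))
  expect_equal(sum(tab$n_individuals),
               nrow(pipe$slices[calendar_year == 2012L]))
  ## fracture cases are older on average than non-cases (by construction,
  ## the generator's hazard increases with age)
  cases <- pipe$slices[calendar_year == 2012L & event == 1L, attained_age]
  ctrl <- pipe$slices[calendar_year == 2012L & event == 0L, attained_age]
  expect_gt(median(cases), median(ctrl))
  expect_error(describe_slices(pipe$slices, 1999L), "not inside follow-up")
  ## one person, no fracture: a single stratum with count 1
  one <- describe_slices(make_slices(
    person_id = 1L, calendar_year = 2010L, sex = "female",
    birth_year = 1940L, attained_age = 70L, rx_risk_value = 1L,
    person_time = 1, event = 0L), 2010L)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n_individuals, 1L)
})
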