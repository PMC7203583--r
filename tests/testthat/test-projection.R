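test_that("expected counts are rate x population over aligned bands", {
  inc <- incidence_table("F", c(50, 55), c(55, NA), c(100, 200))
  pop <- population_table(rep(2015, 2), rep("F", 2), c(50, 55), c(55, NA),
                          c(50000, 10000))
  cnt <- expected_counts(inc, pop, 2015)
  expect_equal(cnt[["F"]], 100 / 1e5 * 50000 + 200 / 1e5 * 10000)

  # zero population gives zero counts
  pop0 <- population_table(rep(2015, 4), rep(c("F", "M"), each = 2),
                           rep(c(50, 55), 2), rep(c(55, NA), 2), rep(0, 4))
  inc2 <- incidence_table(rep(c("F", "M"), each = 2), rep(c(50, 55), 2),
                          rep(c(55, NA), 2), c(100, 200, 80, 150))
  expect_equal(unname(expected_counts(inc2, pop0, 2015)), c(0, 0))

  expect_error(expected_counts(inc, pop, 2020), class = "surfrax_range_error")
  pop_bad <- population_table(2015, "F", 50, NA, 1000)
  expect_error(expected_counts(inc, pop_bad, 2015),
               class = "surfrax_alignment_error")
})

test_that("bands starting below the age cut-off are excluded entirely", {
  inc <- incidence_table("F", c(45, 50, 55), c(50, 55, NA), c(999, 100, 200))
  pop <- population_table(rep(2015, 3), rep("F", 3), c(45, 50, 55),
                          c(50, 55, NA), c(99999, 50000, 10000))
  cnt <- expected_counts(inc, pop, 2015, min_age = 50)
  expect_equal(cnt[["F"]], 50 + 20)
})

test_that("expected counts match an independently hand-summed oracle", {
  withr::local_seed(31)
  bands <- age_bands()
  rates <- list(M = runif(nrow(bands), 10, 500), F = runif(nrow(bands), 10, 800))
  counts <- list(M = runif(nrow(bands), 1e3, 1e5), F = runif(nrow(bands), 1e3, 1e5))
  inc <- incidence_table(rep(c("M", "F"), each = nrow(bands)),
                         rep(bands$age_lo, 2), rep(bands$age_hi, 2),
                         c(rates$M, rates$F))
  pop <- population_table(rep(2015, 2 * nrow(bands)),
                          rep(c("M", "F"), each = nrow(bands)),
                          rep(bands$age_lo, 2), rep(bands$age_hi, 2),
                          c(counts$M, counts$F))
  got <- expected_counts(inc, pop, 2015)
  # plain-arithmetic oracle, summed term by term
  oracle <- vapply(c("M", "F"), function(s) {
    total <- 0
    for (i in seq_len(nrow(bands))) total <- total + rates[[s]][i] / 1e5 * counts[[s]][i]
    total
  }, numeric(1))
  expect_equal(got[["M"]], oracle[["M"]], tolerance = 1e-12)
  expect_equal(got[["F"]], oracle[["F"]], tolerance = 1e-12)
})

test_that("projection percent increases follow the base year and rounding rule", {
  inc <- incidence_table(c("F", "M"), c(50, 50), c(NA, NA), c(100, 80))
  yrs <- c(2015, 2020, 2030)
  # constant population -> zero increase everywhere
  pop_const <- population_table(rep(yrs, each = 2), rep(c("F", "M"), 3),
                                rep(50, 6), rep(NA, 6), rep(1e5, 6))
  prj <- project(inc, pop_const, years = yrs)
  expect_true(all(prj$totals$pct_increase == 0))

  # doubling the population doubles counts: +100%
  pop2 <- population_table(rep(c(2015, 2020), each = 2), rep(c("F", "M"), 2),
                           rep(50, 4), rep(NA, 4), c(1e5, 1e5, 2e5, 2e5))
  prj2 <- project(inc, pop2, years = c(2015, 2020))
  expect_equal(prj2$totals$pct_increase[prj2$totals$year == 2020], 100)

  # conservation: totals are the sum over sexes for every year
  sums <- tapply(prj2$counts$count, prj2$counts$year, sum)
  expect_equal(as.numeric(sums), prj2$totals$total)

  # rescaling both years by one factor leaves the increase unchanged
  pop2s <- population_table(rep(c(2015, 2020), each = 2), rep(c("F", "M"), 2),
                            rep(50, 4), rep(NA, 4),
                            3.7 * c(1e5, 1e5, 2e5, 2e5))
  prj2s <- project(inc, pop2s, years = c(2015, 2020))
  expect_equal(prj2s$totals$pct_increase, prj2$totals$pct_increase)

  expect_error(project(inc, pop_const, years = c(2015, 2050)),
               class = "surfrax_range_error")
})

test_that("counts are linear in incidence and population", {
  sc <- synth_scenario(seed = 2)
  inc <- sc$authentic$hip_incidence
  pop <- sc$population
  base <- expected_counts(inc, pop, 2015)
  inc2 <- incidence_table(inc$sex, inc$age_lo, inc$age_hi, 2 * inc$value)
  expect_equal(unname(expected_counts(inc2, pop, 2015)), unname(2 * base))
  pop3 <- population_table(pop$year, pop$sex, pop$age_lo, pop$age_hi,
                           3 * pop$count)
  expect_equal(unname(expected_counts(inc, pop3, 2015)), unname(3 * base))
})

test_that("projection report renders the men/women/total/increase layout", {
  inc <- incidence_table(c("F", "M"), c(50, 50), c(NA, NA), c(100, 80))
  pop <- population_table(rep(c(2015, 2020), each = 2), rep(c("F", "M"), 2),
                          rep(50, 4), rep(NA, 4), c(1e5, 1e5, 1.5e5, 1.5e5))
  prj <- project(inc, pop, years = c(2015, 2020))
  rep_tbl <- projection_report(prj)
  expect_equal(rep_tbl$quantity, c("Men", "Women", "Total", "Increase (%)"))
  expect_equal(names(rep_tbl), c("quantity", "2015", "2020"))
  expect_equal(rep_tbl[["2015"]][rep_tbl$quantity == "Total"], "180")
  expect_equal(rep_tbl[["2015"]][rep_tbl$quantity == "Increase (%)"], "-")
  expect_equal(rep_tbl[["2020"]][rep_tbl$quantity == "Increase (%)"], "50")
})

test_that("round_half_up rounds .5 away from zero at integer precision", {
  expect_equal(round_half_up(c(206.504, 13.77, 55.92, 171.54, 0.5, 1.5)),
               c(207, 14, 56, 172, 1, 2))
})
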