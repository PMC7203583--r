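test_that("piecewise fit recovers the identity line and known coefficients", {
  x <- seq(10, 70, by = 5)
  fit_id <- piecewise_fit(x, x, knot = 40)
  expect_equal(fit_id$intercept, 0, tolerance = 1e-10)
  expect_equal(fit_id$slope_below, 1, tolerance = 1e-10)
  expect_equal(fit_id$slope_above, 1, tolerance = 1e-10)
  expect_equal(fit_id$r, 1)
  expect_false(fit_id$degenerate)

  # noiseless hinge data: coefficients back to >= 10 significant digits
  y <- 2 + 0.9 * x + 0.3 * pmax(0, x - 40)
  fit <- piecewise_fit(x, y, knot = 40)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$slope_below, 0.9, tolerance = 1e-10)
  expect_equal(fit$slope_above, 1.2, tolerance = 1e-10)
  expect_equal(fit$n, length(x))
})

test_that("piecewise fit degenerates gracefully when the knot is unused", {
  x <- seq(5, 35, by = 5)
  y <- 1 + 2 * x
  fit <- piecewise_fit(x, y, knot = 40) # all points below the knot
  expect_true(fit$degenerate)
  expect_equal(fit$slope_above, 0)
  ols <- stats::lm(y ~ x)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$slope_below, unname(coef(ols)[2]), tolerance = 1e-10)

  # knot below the whole data range: hinge collinear with x, same reduction
  fit_lo <- piecewise_fit(x, y, knot = 0)
  expect_true(fit_lo$degenerate)
  expect_equal(fit_lo$slope_below, unname(coef(ols)[2]), tolerance = 1e-10)

  expect_error(piecewise_fit(c(1, 2), c(1, 2)),
               class = "surfrax_insufficient_data_error")
  expect_error(piecewise_fit(rep(3, 5), 1:5),
               class = "surfrax_degenerate_error")
})

test_that("percentile comparison locates the reference percentile profile", {
  ref <- fake_grid_probs(c(0.10, 0.155, 0.20))
  sur <- fake_grid_probs(c(0.10, 0.174, 0.21), model = "sur")
  pc <- percentile_compare(ref, sur, "mof", 70, "M")
  expect_equal(pc$value_reference, 15.5)
  expect_equal(pc$value_surrogate, 17.4)
  expect_equal(pc$relative_difference_pct, 100 * (17.4 - 15.5) / 15.5)
  expect_equal(round_half_up(pc$relative_difference_pct), 12)

  # identical grids -> zero difference
  pc0 <- percentile_compare(ref, ref, "mof", 70, "M")
  expect_equal(pc0$relative_difference_pct, 0)
  expect_equal(pc0$value_surrogate, pc0$value_reference)

  # even-count median is the mean of the central pair
  ref2 <- fake_grid_probs(c(0.10, 0.20))
  pc2 <- percentile_compare(ref2, ref2, "mof", 70, "M")
  expect_equal(pc2$value_reference, 15)

  # the percentile convention matches type-7 quantiles in general
  withr::local_seed(99)
  vals <- runif(37)
  refr <- fake_grid_probs(vals)
  for (p in c(25, 50, 75, 90)) {
    pcq <- percentile_compare(refr, refr, "mof", 70, "M", percentile = p)
    expect_equal(pcq$value_reference,
                 100 * unname(stats::quantile(vals, p / 100, type = 7)))
  }

  expect_error(percentile_compare(ref, sur, "hip", 70, "M"),
               class = "surfrax_empty_selection_error")
})

test_that("swapping models flips the relative difference by the denominator rule", {
  withr::local_seed(7)
  vals <- sort(runif(25, 0.05, 0.40))
  ref <- fake_grid_probs(vals)
  sur <- fake_grid_probs(vals * 1.1, model = "sur") # order-preserving shift
  d <- percentile_compare(ref, sur, "mof", 70, "M")$relative_difference_pct
  d_swap <- percentile_compare(sur, ref, "mof", 70, "M")$relative_difference_pct
  expect_equal(d_swap, 100 * (-d) / (100 + d), tolerance = 1e-10)
})

test_that("tolerance intervals behave like order-statistic intervals", {
  # degenerate distribution collapses to a point
  ti_const <- tolerance_interval(rep(4.2, 50))
  expect_equal(c(ti_const$lo, ti_const$hi), c(4.2, 4.2))

  # n = 1000 uniforms: the interval must hold >= 95% of the sample
  withr::local_seed(123)
  u <- runif(1000)
  ti <- tolerance_interval(u, coverage = 0.95, confidence = 0.95)
  inside <- sum(u >= ti$lo & u <= ti$hi)
  expect_gte(inside, 950)
  expect_false(ti$under_covered)

  # tiny samples fall back to (min, max), flagged
  ti3 <- tolerance_interval(c(3, 1, 2))
  expect_equal(c(ti3$lo, ti3$hi), c(1, 3))
  expect_true(ti3$under_covered)

  expect_error(tolerance_interval(1),
               class = "surfrax_insufficient_data_error")
})

test_that("tolerance intervals widen with coverage and confidence", {
  withr::local_seed(5)
  u <- rnorm(500)
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(cov) {
    ti <- tolerance_interval(u, coverage = cov, confidence = 0.95)
    ti$hi - ti$lo
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))

  widths_conf <- vapply(c(0.5, 0.8, 0.95, 0.99), function(conf) {
    ti <- tolerance_interval(u, coverage = 0.9, confidence = conf)
    ti$hi - ti$lo
  }, numeric(1))
  expect_true(all(diff(widths_conf) >= 0))

  # the implemented method keeps the surrogate percentile value inside
  withr::local_seed(11)
  vals <- sort(runif(101, 0.05, 0.3))
  ref <- fake_grid_probs(vals)
  sur <- fake_grid_probs(vals * 1.05, model = "sur")
  pc <- percentile_compare(ref, sur, "mof", 70, "M")
  expect_gte(pc$value_surrogate, pc$tolerance_interval$lo)
  expect_lte(pc$value_surrogate, pc$tolerance_interval$hi)
})

test_that("near-identical countries give correlation 1 at every age and sex", {
  model <- gompertz_model()
  # mortality differing by less than 1%
  near <- synth_mortality(
    list(M = gompertz_params(0.004 * 1.008, 0.095),
         F = gompertz_params(0.002 * 1.008, 0.095)),
    age_bands()
  )
  surr <- build_surrogate(model, near, "near-identical")
  grid <- make_grid(ages = c(50, 70))
  ref <- evaluate_grid(model, grid)
  sur <- evaluate_grid(surr, grid)
  report <- comparison_report(ref, sur)
  expect_equal(nrow(report), 2 * 2 * 2) # ages x sexes x outcomes
  expect_true(all(report$r >= 0.999))
  expect_true(all(abs(report$relative_difference_pct) < 1))
})
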