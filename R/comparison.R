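#' Piecewise linear regression with a fixed knot
#'
#' Least-squares fit of `y` on the hinge basis `{1, x, max(0, x - knot)}`,
#' continuous at the knot, used to compare probability distributions from
#' two models (in percent) against the line of identity. Reports the Pearson
#' correlation between `x` and `y`.
#'
#' When no design points lie strictly above the knot (or the hinge column is
#' collinear with `x`), the hinge coefficient is fixed at zero, the fit
#' reduces to simple linear regression, `slope_above` is reported as 0 and
#' the `degenerate` flag is set.
#'
#' @param x,y Numeric vectors of equal length (at least 3), typically
#'   probabilities in percent.
#' @param knot Knot location on the `x` scale (default 40, i.e. 40%).
#' @return An object of class `piecewise_fit` with fields `knot`,
#'   `intercept`, `slope_below`, `slope_above`, `r`, `n`, `degenerate`.
#' @export
#' @examples
#' x <- seq(10, 70, by = 5)
#' y <- 2 + 0.9 * x + 0.3 * pmax(0, x - 40)
#' piecewise_fit(x, y, knot = 40)
piecewise_fit <- function(x, y, knot = 40) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort_surfrax("x and y must have equal length", "surfrax_validation_error")
  }
  n <- length(x)
  if (n < 3) {
    abort_surfrax("piecewise fit needs at least 3 points",
                  "surfrax_insufficient_data_error")
  }
  if (stats::var(x) == 0) {
    abort_surfrax("x has zero variance", "surfrax_degenerate_error")
  }
  hinge <- pmax(0, x - knot)
  degenerate <- all(hinge == 0)
  if (!degenerate) {
    fit <- stats::lm(y ~ x + hinge)
    b <- coef(fit)
    if (anyNA(b)) degenerate <- TRUE # hinge collinear with x
  }
  if (degenerate) {
    fit <- stats::lm(y ~ x)
    b <- c(coef(fit), hinge = 0)
  }
  structure(
    list(
      knot = knot,
      intercept = unname(b[1]),
      slope_below = unname(b[2]),
      slope_above = if (degenerate) 0 else unname(b[2] + b[3]),
      r = stats::cor(x, y),
      n = n,
      degenerate = degenerate
    ),
    class = "piecewise_fit"
  )
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fit> knot %.6g | intercept %.6g | slope below %.6g | slope above %.6g | r %.6g | n %d%s\n",
    x$knot, x$intercept, x$slope_below, x$slope_above, x$r, x$n,
    if (x$degenerate) " | degenerate (no points above knot)" else ""
  ))
  invisible(x)
}

#' Distribution-free tolerance interval from order statistics
#'
#' Returns the narrowest symmetric pair of order statistics
#' `(x_(i), x_(n+1-i))` whose probability of covering at least `coverage` of
#' the sampled distribution is at least `confidence`. The coverage of that
#' pair follows a `Beta(n + 1 - 2i, 2i)` law, so the condition is
#' `1 - pbeta(coverage, n + 1 - 2i, 2i) >= confidence`. If even the sample
#' extremes `(min, max)` fail the condition, they are returned with the
#' `under_covered` flag set.
#'
#' @param values Numeric vector, at least 2 values.
#' @param coverage Proportion of the distribution to cover (default 0.95).
#' @param confidence Confidence that the interval achieves the coverage
#'   (default 0.95).
#' @return An object of class `tolerance_interval` with fields `lo`, `hi`,
#'   `order` (the pair `(i, n + 1 - i)` used), `coverage`, `confidence`,
#'   `n`, `under_covered`.
#' @export
#' @examples
#' set.seed(1)
#' tolerance_interval(runif(1000))
tolerance_interval <- function(values, coverage = 0.95, confidence = 0.95) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) {
    abort_surfrax("tolerance interval needs at least 2 values",
                  "surfrax_insufficient_data_error")
  }
  stopifnot(coverage > 0, coverage < 1, confidence > 0, confidence < 1)
  xs <- sort(values)
  i_max <- floor((n - 1) / 2) # keep n + 1 - 2i >= 1 and i < n + 1 - i
  admissible <- 0L
  for (i in seq_len(max(i_max, 0))) {
    ok <- (1 - pbeta(coverage, n + 1 - 2 * i, 2 * i)) >= confidence
    if (ok) admissible <- i else break
  }
  under <- FALSE
  if (admissible == 0L) {
    # even (min, max) may fail for small n; fall back, flagged
    under <- (1 - pbeta(coverage, n - 1, 2)) < confidence
    i <- 1L
  } else {
    i <- admissible
  }
  structure(
    list(lo = xs[i], hi = xs[n + 1 - i], order = c(i, n + 1 - i),
         coverage = coverage, confidence = confidence, n = n,
         under_covered = under),
    class = "tolerance_interval"
  )
}

#' @export
print.tolerance_interval <- function(x, ...) {
  cat(sprintf(
    "<tolerance_interval> [%.6g, %.6g] (order stats %d/%d of n = %d; coverage %.2f, confidence %.2f)%s\n",
    x$lo, x$hi, x$order[1], x$order[2], x$n, x$coverage, x$confidence,
    if (x$under_covered) " [under-covered: sample too small]" else ""
  ))
  invisible(x)
}

# percentile by linear interpolation between closest ranks; even-count
# median is the mean of the central pair (same convention as type-7
# quantiles). Returns ranks + weight so paired values can be interpolated
# with the same weights.
percentile_ranks <- function(n, percentile) {
  h <- (n - 1) * percentile / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  list(lo = lo, hi = hi, w = h - lo)
}

#' Compare two models at a percentile of the reference distribution
#'
#' Pairs the two grids on profile id for one (outcome, age, sex) cell,
#' locates the requested percentile of the reference model's probability
#' distribution (linear interpolation between closest ranks; an even-count
#' median is the mean of the two central order statistics), and reports the
#' surrogate model's probability for the same profile(s), the relative
#' difference in percent of the reference value, and a nonparametric
#' tolerance interval on the surrogate values of profiles ranked within
#' `rank_window` of the reference percentile. All probabilities are reported
#' in percent.
#'
#' @param reference,surrogate `grid_probabilities` tibbles from
#'   [evaluate_grid()] sharing profile ids.
#' @param outcome `"hip"` or `"mof"`.
#' @param age,sex Cell selectors.
#' @param percentile Percentile of the reference distribution (default 50).
#' @param rank_window Half-width, in ranks, of the neighbourhood whose
#'   surrogate values feed the tolerance interval (default 10).
#' @param ti_coverage,ti_confidence Passed to [tolerance_interval()].
#' @return An object of class `percentile_comparison` with fields
#'   `percentile`, `value_reference`, `value_surrogate`,
#'   `relative_difference_pct`, `tolerance_interval` and `n`. Correlations
#'   are reported by [comparison_report()].
#' @export
percentile_compare <- function(reference, surrogate, outcome, age, sex,
                               percentile = 50, rank_window = 10,
                               ti_coverage = 0.95, ti_confidence = 0.95) {
  stopifnot(inherits(reference, "grid_probabilities"),
            inherits(surrogate, "grid_probabilities"))
  ref <- reference[reference$outcome == outcome & reference$age == age &
                     reference$sex == sex, ]
  sur <- surrogate[surrogate$outcome == outcome & surrogate$age == age &
                     surrogate$sex == sex, ]
  paired <- dplyr::inner_join(
    ref[, c("profile_id", "probability")],
    sur[, c("profile_id", "probability")],
    by = "profile_id", suffix = c("_ref", "_sur")
  )
  if (nrow(paired) == 0) {
    abort_surfrax(
      paste0("no matching profiles for outcome ", outcome, ", age ", age,
             ", sex ", sex),
      "surfrax_empty_selection_error"
    )
  }
  paired <- paired[order(paired$probability_ref), ]
  n <- nrow(paired)
  rk <- percentile_ranks(n, percentile)
  ref_pct <- 100 * paired$probability_ref
  sur_pct <- 100 * paired$probability_sur
  v_ref <- (1 - rk$w) * ref_pct[rk$lo] + rk$w * ref_pct[rk$hi]
  v_sur <- (1 - rk$w) * sur_pct[rk$lo] + rk$w * sur_pct[rk$hi]
  win <- max(1, rk$lo - rank_window):min(n, rk$hi + rank_window)
  ti <- if (length(win) >= 2) {
    tolerance_interval(sur_pct[win], ti_coverage, ti_confidence)
  } else {
    NULL
  }
  structure(
    list(
      outcome = outcome, age = age, sex = sex,
      percentile = percentile,
      value_reference = v_ref,
      value_surrogate = v_sur,
      relative_difference_pct = 100 * (v_sur - v_ref) / v_ref,
      tolerance_interval = ti,
      n = n
    ),
    class = "percentile_comparison"
  )
}

#' @export
print.percentile_comparison <- function(x, ...) {
  cat(sprintf(
    "<percentile_comparison> %s, age %d, sex %s, P%g: reference %.1f%% vs surrogate %.1f%% (%+.2f%%)\n",
    x$outcome, x$age, x$sex, x$percentile, x$value_reference,
    x$value_surrogate, x$relative_difference_pct
  ))
  if (!is.null(x$tolerance_interval)) {
    cat(sprintf("  TI: %.1f-%.1f\n", x$tolerance_interval$lo,
                x$tolerance_interval$hi))
  }
  invisible(x)
}

#' Full model-comparison report
#'
#' For every (age, sex, outcome) cell present in both grids, reports the
#' reference and surrogate probabilities (percent) at the requested
#' percentile of the reference distribution, the tolerance interval on the
#' surrogate values near that percentile, and the Pearson correlation from
#' the piecewise regression of surrogate on reference probabilities.
#'
#' @inheritParams percentile_compare
#' @param knot Knot (in percent) for [piecewise_fit()] (default 40).
#' @return A tibble with columns `age`, `sex`, `outcome`, `percentile`,
#'   `reference_median`, `surrogate_median`, `relative_difference_pct`,
#'   `ti_lo`, `ti_hi`, `r`.
#' @export
comparison_report <- function(reference, surrogate, percentile = 50,
                              knot = 40, rank_window = 10,
                              ti_coverage = 0.95, ti_confidence = 0.95) {
  cells <- dplyr::distinct(
    dplyr::inner_join(
      dplyr::distinct(tibble::as_tibble(reference)[, c("age", "sex", "outcome")]),
      dplyr::distinct(tibble::as_tibble(surrogate)[, c("age", "sex", "outcome")]),
      by = c("age", "sex", "outcome")
    )
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    a <- cells$age[i]; s <- cells$sex[i]; o <- cells$outcome[i]
    pc <- percentile_compare(reference, surrogate, o, a, s,
                             percentile = percentile,
                             rank_window = rank_window,
                             ti_coverage = ti_coverage,
                             ti_confidence = ti_confidence)
    ref <- reference[reference$outcome == o & reference$age == a &
                       reference$sex == s, ]
    sur <- surrogate[surrogate$outcome == o & surrogate$age == a &
                       surrogate$sex == s, ]
    paired <- dplyr::inner_join(
      ref[, c("profile_id", "probability")],
      sur[, c("profile_id", "probability")],
      by = "profile_id", suffix = c("_ref", "_sur")
    )
    fit <- piecewise_fit(100 * paired$probability_ref,
                         100 * paired$probability_sur, knot = knot)
    tibble::tibble(
      age = a, sex = s, outcome = o, percentile = percentile,
      reference_median = pc$value_reference,
      surrogate_median = pc$value_surrogate,
      relative_difference_pct = pc$relative_difference_pct,
      ti_lo = pc$tolerance_interval$lo,
      ti_hi = pc$tolerance_interval$hi,
      r = fit$r
    )
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$outcome, .data$sex, .data$age)
}
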