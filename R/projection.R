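#' Round half-up
#'
#' Commercial rounding: .5 always rounds away from zero for positive values
#' (used for reported percent increases; base R's `round()` rounds half to
#' even).
#' @param x Numeric vector (non-negative use intended).
#' @param digits Decimal digits to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Expected annual fracture counts from incidence and population
#'
#' Applies age- and sex-specific incidence rates to the population of one
#' calendar year: for each sex, the expected count is the sum over age bands
#' with `age_lo >= min_age` of `rate / 100000 * persons`. Bands starting
#' below `min_age` are excluded entirely. Incidence and population bands
#' must align exactly (no proration across mismatched bands).
#'
#' @param incidence An [incidence_table()].
#' @param population A [population_table()] containing `year`.
#' @param year Calendar year to evaluate.
#' @param min_age Lower age cut-off (default 50).
#' @return Named numeric vector of expected counts per sex.
#' @export
#' @examples
#' inc <- incidence_table("F", c(50, 70), c(70, NA), c(100, 400))
#' pop <- population_table(2015, c("F", "F"), c(50, 70), c(70, NA),
#'                         c(50000, 20000))
#' expected_counts(inc, pop, 2015) # F: 50 + 80
expected_counts <- function(incidence, population, year, min_age = 50) {
  stopifnot(inherits(incidence, "incidence_table"),
            inherits(population, "population_table"))
  if (!year %in% population$year) {
    abort_surfrax(paste0("year ", year, " absent from population table"),
                  "surfrax_range_error")
  }
  pop <- population[population$year == year & population$age_lo >= min_age, ]
  key <- function(sex, lo, hi) paste(sex, lo, band_hi_closed(lo, hi))
  inc_key <- key(incidence$sex, incidence$age_lo, incidence$age_hi)
  pop_key <- key(pop$sex, pop$age_lo, pop$age_hi)
  idx <- match(pop_key, inc_key)
  if (anyNA(idx)) {
    abort_surfrax(
      paste0("population bands not matched by incidence bands: ",
             paste(unique(pop_key[is.na(idx)]), collapse = "; ")),
      "surfrax_alignment_error"
    )
  }
  expected <- incidence$value[idx] / 1e5 * pop$count
  out <- tapply(expected, pop$sex, sum)
  setNames(as.numeric(out), names(out))
}

#' Project national fracture counts under stable incidence
#'
#' Cross-sectional projection: each year's expected counts are the product
#' of fixed age- and sex-specific incidence and that year's projected
#' population pyramid — no cohort dynamics, exactly the "incidence remains
#' stable" assumption. Percent increases are relative to `base_year`,
#' reported both unrounded and rounded half-up to integer percent.
#'
#' @inheritParams expected_counts
#' @param years Calendar years to project (default 2015-2050 milestones).
#' @param base_year Reference year for percent increases (default the first
#'   of `years`).
#' @return An object of class `projection_result` with fields `counts`
#'   (tibble `year`, `sex`, `count`), `totals` (tibble `year`, `total`,
#'   `pct_increase`, `pct_increase_rounded`), `base_year`, `min_age`.
#' @export
project <- function(incidence, population,
                    years = c(2015L, 2020L, 2030L, 2040L, 2050L),
                    base_year = years[1], min_age = 50) {
  if (!base_year %in% years) years <- sort(unique(c(base_year, years)))
  missing_years <- setdiff(years, unique(population$year))
  if (length(missing_years) > 0) {
    abort_surfrax(
      paste0("years absent from population table: ",
             paste(missing_years, collapse = ", ")),
      "surfrax_range_error"
    )
  }
  counts <- dplyr::bind_rows(lapply(years, function(y) {
    cnt <- expected_counts(incidence, population, y, min_age = min_age)
    tibble::tibble(year = as.integer(y), sex = names(cnt), count = unname(cnt))
  }))
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$year),
                             total = sum(.data$count), .groups = "drop")
  base_total <- totals$total[totals$year == base_year]
  if (base_total == 0) {
    abort_surfrax("base-year total count is zero; percent increase undefined",
                  "surfrax_degenerate_error")
  }
  totals$pct_increase <- 100 * (totals$total - base_total) / base_total
  totals$pct_increase_rounded <- round_half_up(totals$pct_increase)
  structure(
    list(counts = counts, totals = totals, base_year = as.integer(base_year),
         min_age = min_age),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat("<projection_result> base year ", x$base_year,
      ", ages ", x$min_age, "+\n", sep = "")
  print(projection_report(x))
  invisible(x)
}

#' Render a projection as a year-by-row report table
#'
#' Lays the projection out in the conventional presentation: one column per
#' year; rows for men, women, the total (rounded half-up to whole
#' fractures), and the percent increase over the base year (integer percent,
#' blank for the base year).
#'
#' @param result A [project()] result.
#' @return A tibble with a `quantity` column and one character column per
#'   year.
#' @export
projection_report <- function(result) {
  stopifnot(inherits(result, "projection_result"))
  wide <- tidyr::pivot_wider(result$counts, names_from = "year",
                             values_from = "count")
  yrs <- as.character(result$totals$year)
  fmt_count <- function(v) as.character(round_half_up(v))
  rows <- list()
  for (s in c("M", "F")) {
    if (s %in% wide$sex) {
      v <- as.numeric(wide[wide$sex == s, yrs])
      rows[[length(rows) + 1]] <-
        c(quantity = if (s == "M") "Men" else "Women", setNames(fmt_count(v), yrs))
    }
  }
  rows[[length(rows) + 1]] <-
    c(quantity = "Total", setNames(fmt_count(result$totals$total), yrs))
  inc <- ifelse(result$totals$year == result$base_year, "-",
                as.character(result$totals$pct_increase_rounded))
  rows[[length(rows) + 1]] <- c(quantity = "Increase (%)", setNames(inc, yrs))
  dplyr::bind_rows(lapply(rows, function(r) tibble::as_tibble(as.list(r))))
}

#' @rdname projection_report
#' @param path Output CSV path.
#' @export
write_projection_report <- function(result, path) {
  readr::write_csv(projection_report(result), path, progress = FALSE)
  invisible(path)
}
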