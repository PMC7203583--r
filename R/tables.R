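#' Epidemiological rate and population tables
#'
#' Four tibble-backed classes hold the model inputs:
#' \describe{
#'   \item{`incidence_table`}{hip (or major osteoporotic) fracture incidence,
#'     in events per 100,000 person-years, by sex and age band.}
#'   \item{`mortality_table`}{annual death hazard per person-year, by sex and
#'     age band.}
#'   \item{`ratio_table`}{unitless ratio of major-osteoporotic to hip fracture
#'     incidence (the Malmo-pattern imputation ratios), by sex and age band.}
#'   \item{`population_table`}{person counts by calendar year, sex and age
#'     band.}
#' }
#'
#' Age bands are half-open integer intervals `[age_lo, age_hi)`. Within each
#' sex the bands must be sorted, non-overlapping and contiguous, and must
#' cover at least ages 50 to 89. The final band may be open-ended
#' (`age_hi = NA`), in which case it extends to the model ceiling of age 100
#' with constant hazard.
#'
#' @param sex Character vector, `"M"` or `"F"`.
#' @param age_lo,age_hi Integer band edges; `age_hi = NA` marks an
#'   open-ended final band.
#' @param rate Rates: per 100,000 person-years for incidence, per
#'   person-year for mortality.
#' @param ratio Unitless MOF:hip incidence ratios (at least 1 from age 50 up,
#'   since MOF includes hip fractures).
#' @param year Calendar year (population tables).
#' @param count Person counts.
#' @param country_label Free-text label for the table's origin.
#'
#' @return A tibble with class `incidence_table`, `mortality_table`,
#'   `ratio_table` or `population_table`.
#' @name epi-tables
NULL

SEX_LEVELS <- c("M", "F")

band_hi_closed <- function(age_lo, age_hi) {
  ifelse(is.na(age_hi), MODEL_CEILING, age_hi)
}

check_sex <- function(sex) {
  bad <- setdiff(unique(sex), SEX_LEVELS)
  if (length(bad) > 0) {
    abort_surfrax(
      paste0("sex must be one of M, F; found: ", paste(bad, collapse = ", ")),
      "surfrax_validation_error"
    )
  }
  invisible(sex)
}

# per-sex band structure: sorted, non-overlapping, contiguous, covering
# at least [50, 90); only the last band may be open-ended
validate_band_structure <- function(df, what) {
  for (s in unique(df$sex)) {
    b <- df[df$sex == s, , drop = FALSE]
    b <- b[order(b$age_lo), , drop = FALSE]
    hi <- band_hi_closed(b$age_lo, b$age_hi)
    if (any(is.na(b$age_hi) & seq_len(nrow(b)) != nrow(b))) {
      abort_surfrax(
        paste0(what, ": only the final band may be open-ended (sex ", s, ")"),
        "surfrax_validation_error"
      )
    }
    if (any(hi <= b$age_lo)) {
      abort_surfrax(
        paste0(what, ": empty or inverted age band (sex ", s, ")"),
        "surfrax_validation_error"
      )
    }
    if (nrow(b) > 1) {
      gaps <- b$age_lo[-1] - hi[-nrow(b)]
      if (any(gaps > 0)) {
        abort_surfrax(
          paste0(what, ": age bands have gaps (sex ", s, ")"),
          "surfrax_validation_error"
        )
      }
      if (any(gaps < 0)) {
        abort_surfrax(
          paste0(what, ": age bands overlap (sex ", s, ")"),
          "surfrax_validation_error"
        )
      }
    }
    if (min(b$age_lo) > 50 || max(hi) < 90) {
      abort_surfrax(
        paste0(what, ": bands must cover at least ages [50, 90) (sex ", s, ")"),
        "surfrax_validation_error"
      )
    }
  }
  invisible(df)
}

new_band_table <- function(df, class, country_label = "") {
  out <- tibble::as_tibble(df)
  out <- out[order(out$sex, out$age_lo), ]
  attr(out, "country_label") <- country_label
  class(out) <- c(class, "epi_table", class(out))
  out
}

#' @rdname epi-tables
#' @export
incidence_table <- function(sex, age_lo, age_hi, rate, country_label = "") {
  df <- tibble::tibble(
    sex = as.character(sex), age_lo = as.integer(age_lo),
    age_hi = as.integer(age_hi), value = as.numeric(rate)
  )
  check_sex(df$sex)
  if (any(df$value < 0)) {
    abort_surfrax("incidence rates must be non-negative", "surfrax_validation_error")
  }
  validate_band_structure(df, "incidence table")
  new_band_table(df, "incidence_table", country_label)
}

#' @rdname epi-tables
#' @export
mortality_table <- function(sex, age_lo, age_hi, rate, country_label = "") {
  df <- tibble::tibble(
    sex = as.character(sex), age_lo = as.integer(age_lo),
    age_hi = as.integer(age_hi), value = as.numeric(rate)
  )
  check_sex(df$sex)
  if (any(df$value < 0)) {
    abort_surfrax("mortality rates must be non-negative", "surfrax_validation_error")
  }
  validate_band_structure(df, "mortality table")
  new_band_table(df, "mortality_table", country_label)
}

#' @rdname epi-tables
#' @export
ratio_table <- function(sex, age_lo, age_hi, ratio, country_label = "") {
  df <- tibble::tibble(
    sex = as.character(sex), age_lo = as.integer(age_lo),
    age_hi = as.integer(age_hi), value = as.numeric(ratio)
  )
  check_sex(df$sex)
  if (any(df$value < 0)) {
    abort_surfrax("ratios must be non-negative", "surfrax_validation_error")
  }
  if (any(df$value[df$age_lo >= 50] < 1)) {
    abort_surfrax(
      "MOF:hip ratios must be at least 1 from age 50 upwards",
      "surfrax_validation_error"
    )
  }
  validate_band_structure(df, "ratio table")
  new_band_table(df, "ratio_table", country_label)
}

#' @rdname epi-tables
#' @export
population_table <- function(year, sex, age_lo, age_hi, count,
                             country_label = "") {
  df <- tibble::tibble(
    year = as.integer(year), sex = as.character(sex),
    age_lo = as.integer(age_lo), age_hi = as.integer(age_hi),
    count = as.numeric(count)
  )
  check_sex(df$sex)
  if (any(df$count < 0)) {
    abort_surfrax("population counts must be non-negative", "surfrax_validation_error")
  }
  cells <- lapply(split(df, df$year), function(b) {
    sort(paste(b$sex, b$age_lo, band_hi_closed(b$age_lo, b$age_hi)))
  })
  if (length(unique(cells)) > 1) {
    abort_surfrax(
      "population table: all (sex, age band) cells must be present for every year",
      "surfrax_validation_error"
    )
  }
  if (anyDuplicated(df[, c("year", "sex", "age_lo")])) {
    abort_surfrax("population table: duplicate (year, sex, band) rows",
                  "surfrax_validation_error")
  }
  out <- tibble::as_tibble(df)
  out <- out[order(out$year, out$sex, out$age_lo), ]
  attr(out, "country_label") <- country_label
  class(out) <- c("population_table", "epi_table", class(out))
  out
}

#' Read or write an epidemiological table
#'
#' CSV schemas (header row required, UTF-8):
#' * incidence / mortality / ratio: columns `sex`, `age_lo`, `age_hi`,
#'   `value`; an empty `age_hi` marks an open-ended final band.
#' * population: columns `year`, `sex`, `age_lo`, `age_hi`, `count`.
#'
#' All class invariants are validated on read; `read_table()` after
#' `write_table()` is the identity on valid tables.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"incidence"`, `"mortality"`, `"ratio"`,
#'   `"population"`.
#' @param country_label Label attached to the returned table.
#' @param table A table created by [incidence_table()] and friends.
#' @return `read_table()`: the validated table; `write_table()`: `path`,
#'   invisibly.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' inc <- incidence_table("F", c(50, 55, 60, 70, 80), c(55, 60, 70, 80, NA),
#'                        c(20, 30, 60, 150, 400))
#' write_table(inc, tf)
#' identical(read_table(tf, "incidence"), inc)
read_table <- function(path, schema = c("incidence", "mortality", "ratio",
                                        "population"),
                       country_label = "") {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort_surfrax(paste0("file not found: ", path), "surfrax_io_error")
  }
  # "F" must parse as a sex code, never as FALSE
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          sex = readr::col_character(),
                          .default = readr::col_double()
                        ))
  needed <- if (schema == "population") {
    c("year", "sex", "age_lo", "age_hi", "count")
  } else {
    c("sex", "age_lo", "age_hi", "value")
  }
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    abort_surfrax(
      paste0("missing columns for ", schema, " schema: ",
             paste(missing_cols, collapse = ", ")),
      "surfrax_schema_error"
    )
  }
  switch(schema,
    incidence = incidence_table(df$sex, df$age_lo, df$age_hi, df$value,
                                country_label),
    mortality = mortality_table(df$sex, df$age_lo, df$age_hi, df$value,
                                country_label),
    ratio = ratio_table(df$sex, df$age_lo, df$age_hi, df$value,
                        country_label),
    population = population_table(df$year, df$sex, df$age_lo, df$age_hi,
                                  df$count, country_label)
  )
}

#' @rdname read_table
#' @export
write_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(unclass(table)[names(table)]), path,
                   progress = FALSE)
  invisible(path)
}

#' Single-year hazard lookup
#'
#' Expands an age-banded table to single-year hazards: the hazard is constant
#' within a band (no interpolation). Incidence rates are converted from per
#' 100,000 person-years to per person-year; mortality rates are already per
#' person-year and are returned unchanged. Ages outside the table's coverage
#' (or at/above the model ceiling of 100) raise a range error rather than
#' extrapolating.
#'
#' @param table An `incidence_table`, `mortality_table` or `ratio_table`.
#' @param sex `"M"` or `"F"`.
#' @param age Integer vector of ages in years.
#' @return Numeric vector of hazards per person-year (or unitless ratios for
#'   a `ratio_table`), one per age.
#' @export
#' @examples
#' inc <- incidence_table("F", c(50, 70, 75), c(70, 75, NA), c(30, 250, 400))
#' hazard_at(inc, "F", 72) # 250 per 100,000 -> 0.0025
hazard_at <- function(table, sex, age) {
  stopifnot(inherits(table, "epi_table"), length(sex) == 1)
  check_sex(sex)
  b <- table[table$sex == sex, , drop = FALSE]
  if (nrow(b) == 0) {
    abort_surfrax(paste0("no bands for sex ", sex), "surfrax_range_error")
  }
  b <- b[order(b$age_lo), , drop = FALSE]
  hi <- band_hi_closed(b$age_lo, b$age_hi)
  idx <- findInterval(age, b$age_lo)
  ok <- idx >= 1 & age < hi[pmax(idx, 1)]
  if (any(!ok)) {
    abort_surfrax(
      paste0("age(s) outside table coverage for sex ", sex, ": ",
             paste(age[!ok], collapse = ", ")),
      "surfrax_range_error"
    )
  }
  v <- b$value[idx]
  if (inherits(table, "incidence_table")) v <- v / 1e5
  v
}

#' @export
print.epi_table <- function(x, ...) {
  lbl <- attr(x, "country_label")
  cat("<", class(x)[1], ">",
      if (nzchar(lbl)) paste0(" [", lbl, "]"), "\n", sep = "")
  NextMethod()
}

country_label <- function(table) attr(table, "country_label") %||% ""
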