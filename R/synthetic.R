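#' Age-band scaffolds
#'
#' Builds the half-open five-year (or custom) age bands used by the
#' synthetic generators: `[from, from + by), ...` up to `to`, plus an
#' optional open-ended final band `[to, NA)` that the model treats as
#' extending to the ceiling of age 100.
#'
#' @param from First band lower edge (default 50).
#' @param to Lower edge of the open-ended final band (default 95).
#' @param by Band width in years (default 5).
#' @param open_end Append the open-ended final band (default `TRUE`).
#' @return A tibble with columns `age_lo`, `age_hi`.
#' @export
#' @examples
#' age_bands()
age_bands <- function(from = 50L, to = 95L, by = 5L, open_end = TRUE) {
  edges <- seq(from, to, by = by)
  out <- tibble::tibble(
    age_lo = as.integer(edges[-length(edges)]),
    age_hi = as.integer(edges[-1])
  )
  if (open_end) {
    out <- dplyr::bind_rows(out, tibble::tibble(age_lo = as.integer(to),
                                                age_hi = NA_integer_))
  }
  out
}

#' Gompertz hazard parameters
#'
#' Both hip-fracture incidence and adult mortality rise roughly
#' exponentially with age; the synthetic tables encode this with a Gompertz
#' law anchored at age 50: `rate(age) = alpha * exp(beta * (age - 50))`,
#' evaluated at band midpoints.
#'
#' @param alpha Hazard at age 50 (per 100,000 person-years for incidence,
#'   per person-year for mortality); strictly positive.
#' @param beta Log-slope per year of age; non-negative.
#' @param sex Optional sex tag, `"M"` or `"F"`.
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(alpha, beta, sex = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) {
    abort_surfrax("alpha must be strictly positive", "surfrax_validation_error")
  }
  if (!is.numeric(beta) || beta < 0) {
    abort_surfrax("beta must be non-negative", "surfrax_validation_error")
  }
  if (!is.null(sex)) check_sex(sex)
  structure(list(alpha = alpha, beta = beta, sex = sex),
            class = "gompertz_params")
}

band_midpoints <- function(bands) {
  (bands$age_lo + band_hi_closed(bands$age_lo, bands$age_hi)) / 2
}

gompertz_rate <- function(params, mid) {
  params$alpha * exp(params$beta * (mid - 50))
}

#' Synthetic Gompertz incidence and mortality tables
#'
#' Deterministic tables whose band rates follow the Gompertz law at band
#' midpoints, so a log-linear regression of generated rates on midpoints
#' recovers `beta` exactly.
#'
#' @param params Named list of [gompertz_params()], one element per sex
#'   (names `"M"`/`"F"`).
#' @param bands Band scaffold from [age_bands()].
#' @param country_label Label for the generated table.
#' @return [synth_incidence()]: an [incidence_table()] (rates per 100,000
#'   person-years); [synth_mortality()]: a [mortality_table()] (rates per
#'   person-year).
#' @export
#' @examples
#' synth_incidence(list(F = gompertz_params(20, 0.09)), age_bands())
synth_incidence <- function(params, bands = age_bands(), country_label = "") {
  rows <- build_gompertz_rows(params, bands)
  incidence_table(rows$sex, rows$age_lo, rows$age_hi, rows$value, country_label)
}

#' @rdname synth_incidence
#' @export
synth_mortality <- function(params, bands = age_bands(), country_label = "") {
  rows <- build_gompertz_rows(params, bands)
  mortality_table(rows$sex, rows$age_lo, rows$age_hi, rows$value, country_label)
}

build_gompertz_rows <- function(params, bands) {
  check_sex(names(params))
  mid <- band_midpoints(bands)
  dplyr::bind_rows(lapply(names(params), function(s) {
    tibble::tibble(sex = s, age_lo = bands$age_lo, age_hi = bands$age_hi,
                   value = gompertz_rate(params[[s]], mid))
  }))
}

#' Synthetic MOF:hip incidence-ratio table
#'
#' The ratio of major osteoporotic to hip fracture incidence falls with age
#' (forearm fractures dominate early, hip fractures late). The synthetic
#' table declines log-linearly between an anchor at age 50 and one at age
#' 90, evaluated at band midpoints and floored at 1 (MOF includes hip by
#' definition). The value at the age-70 midpoint is the geometric mean of
#' the two anchors.
#'
#' @param bands Band scaffold from [age_bands()].
#' @param ratio_at_50,ratio_at_90 Anchor ratios (defaults 7.0 and 1.3).
#' @param sexes Sexes to generate (default both).
#' @param country_label Label for the generated table.
#' @return A [ratio_table()].
#' @export
synth_ratio <- function(bands = age_bands(), ratio_at_50 = 7.0,
                        ratio_at_90 = 1.3, sexes = c("M", "F"),
                        country_label = "") {
  stopifnot(ratio_at_50 >= 1, ratio_at_90 >= 1)
  mid <- band_midpoints(bands)
  logr <- log(ratio_at_50) +
    (mid - 50) / 40 * (log(ratio_at_90) - log(ratio_at_50))
  value <- pmax(1, exp(logr))
  rows <- dplyr::bind_rows(lapply(sexes, function(s) {
    tibble::tibble(sex = s, age_lo = bands$age_lo, age_hi = bands$age_hi,
                   value = value)
  }))
  ratio_table(rows$sex, rows$age_lo, rows$age_hi, rows$value, country_label)
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (length(seed) != 1 || is.na(suppressWarnings(as.integer(seed))) ||
      as.numeric(seed) != as.integer(seed)) {
    abort_surfrax("seed must be a single integer or NULL",
                  "surfrax_config_error")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Synthetic population pyramids
#'
#' Medium-variant-style pyramids: within a year, counts decline
#' geometrically with age band; across years, every cell grows geometrically
#' at `growth_per_year`. A seeded lognormal jitter (sd 0.05 on the log
#' scale) per (sex, band) cell — identical across years — gives the pyramid
#' realistic roughness without disturbing the year-on-year growth rate.
#'
#' @param base_count_at_50 Persons per sex in the first band of the first
#'   year (default 100,000).
#' @param decline_per_band Proportional drop per successive band (default
#'   0.18).
#' @param growth_per_year Annual growth rate applied to every cell (default
#'   0.02).
#' @param years Calendar years (default 2015-2050 milestones).
#' @param bands Band scaffold from [age_bands()].
#' @param sexes Sexes to generate.
#' @param seed Integer seed for the jitter, or `NULL` for no jitter.
#' @param country_label Label for the generated table.
#' @return A [population_table()].
#' @export
synth_population <- function(base_count_at_50 = 1e5, decline_per_band = 0.18,
                             growth_per_year = 0.02,
                             years = c(2015L, 2020L, 2030L, 2040L, 2050L),
                             bands = age_bands(), sexes = c("M", "F"),
                             seed = NULL, country_label = "") {
  stopifnot(base_count_at_50 > 0, decline_per_band >= 0, decline_per_band < 1)
  nb <- nrow(bands)
  jitter <- with_local_seed(seed, {
    if (is.null(seed)) rep(1, nb * length(sexes))
    else exp(stats::rnorm(nb * length(sexes), 0, 0.05))
  })
  cell <- tidyr::expand_grid(sex = sexes, band_idx = seq_len(nb))
  cell$base <- base_count_at_50 * (1 - decline_per_band)^(cell$band_idx - 1) *
    jitter
  rows <- dplyr::bind_rows(lapply(years, function(y) {
    tibble::tibble(
      year = as.integer(y),
      sex = cell$sex,
      age_lo = bands$age_lo[cell$band_idx],
      age_hi = bands$age_hi[cell$band_idx],
      count = cell$base * (1 + growth_per_year)^(y - min(years))
    )
  }))
  population_table(rows$year, rows$sex, rows$age_lo, rows$age_hi, rows$count,
                   country_label)
}

#' Default synthetic two-country scenario
#'
#' Bundles the package's default study conditions: a moderate-risk
#' "source-country" model (Gompertz hip incidence: women alpha 20 per
#' 100,000 person-years at age 50, beta 0.09; men alpha 15, beta 0.075;
#' Gompertz mortality with beta 0.095 for both sexes), an "index-country"
#' mortality table with the same age slope but 10% higher level (the
#' surrogate construction assumes broadly similar mortality), the default
#' MOF:hip ratio table, the default relative-risk configuration, and a
#' synthetic population projection for the index country.
#'
#' @param seed Integer seed for the population jitter, or `NULL`.
#' @return A list with elements `authentic` (a [frax_model()]),
#'   `target_mortality` (a [mortality_table()]), `surrogate` (a
#'   [frax_model()] built via [build_surrogate()]), and `population` (a
#'   [population_table()]).
#' @export
#' @examples
#' sc <- synth_scenario(seed = 1)
#' sc$authentic
synth_scenario <- function(seed = NULL) {
  bands <- age_bands()
  hip <- synth_incidence(
    list(M = gompertz_params(15, 0.075, "M"),
         F = gompertz_params(20, 0.09, "F")),
    bands, country_label = "source-country"
  )
  mort_source <- synth_mortality(
    list(M = gompertz_params(0.004, 0.095, "M"),
         F = gompertz_params(0.002, 0.095, "F")),
    bands, country_label = "source-country"
  )
  mort_target <- synth_mortality(
    list(M = gompertz_params(0.0044, 0.095, "M"),
         F = gompertz_params(0.0022, 0.095, "F")),
    bands, country_label = "index-country"
  )
  ratio <- synth_ratio(bands, country_label = "source-country")
  authentic <- frax_model(hip, mort_source, ratio,
                          rr_model = default_rr_model(),
                          label = "authentic")
  list(
    authentic = authentic,
    target_mortality = mort_target,
    surrogate = build_surrogate(authentic, mort_target, label = "surrogate"),
    population = synth_population(seed = seed, country_label = "index-country")
  )
}

#' Monte Carlo cohort oracle for the probability engine
#'
#' Simulates `n` individuals with the same piecewise-constant annual hazards
#' as [ten_year_probability()]: each year an individual exits with
#' probability `1 - exp(-(h_f + h_d))` (one exponential draw on the total
#' hazard) and, conditional on exit, fractures with probability
#' `h_f / (h_f + h_d)` (the Bernoulli cause split). Individuals are
#' exchangeable, so the simulation advances the whole cohort with binomial
#' draws per year — distributionally identical to per-individual simulation
#' and exact with respect to the engine's formula, which makes
#' engine-versus-oracle tests sharp.
#'
#' @param model A [frax_model()].
#' @param profile A [risk_profile()].
#' @param n Cohort size (at least 1).
#' @param outcome `"hip"` or `"mof"`.
#' @param horizon Years simulated (default 10).
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Named integer-ish vector `c(fractured, died_first, survived)`
#'   summing to `n`.
#' @export
#' @examples
#' sc <- synth_scenario()
#' simulate_cohort(sc$authentic, risk_profile(70, "F"), n = 1000, seed = 1)
simulate_cohort <- function(model, profile, n, outcome = c("hip", "mof"),
                            horizon = 10, seed = NULL) {
  stopifnot(inherits(model, "frax_model"), inherits(profile, "risk_profile"))
  outcome <- match.arg(outcome)
  if (length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    abort_surfrax("n must be a single integer >= 1", "surfrax_config_error")
  }
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1 ||
                         is.na(seed) || seed != floor(seed))) {
    abort_surfrax("seed must be a single integer or NULL",
                  "surfrax_config_error")
  }
  inc <- if (outcome == "hip") model$hip_incidence else model$mof_incidence
  ages <- profile$age + seq_len(horizon) - 1L
  h_f <- hazard_at(inc, profile$sex, ages) *
    relative_risk(profile, model$rr_model, outcome)
  h_d <- hazard_at(model$mortality, profile$sex, ages)
  run <- function() {
    alive <- as.integer(n)
    fractured <- 0L
    died <- 0L
    for (t in seq_len(horizon)) {
      total <- h_f[t] + h_d[t]
      if (total <= 0 || alive == 0L) next
      exits <- rbinom(1, alive, 1 - exp(-total))
      frs <- rbinom(1, exits, h_f[t] / total)
      fractured <- fractured + frs
      died <- died + (exits - frs)
      alive <- alive - exits
    }
    c(fractured = fractured, died_first = died, survived = alive)
  }
  if (is.null(seed)) run() else with_local_seed(seed, run())
}
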