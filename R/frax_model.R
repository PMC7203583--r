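#' Impute major osteoporotic fracture incidence from hip incidence
#'
#' Many countries have reliable hip-fracture registries but no direct data on
#' the other major osteoporotic fractures (clinical spine, distal forearm,
#' proximal humerus). Following standard practice, MOF incidence is imputed
#' by multiplying hip incidence by age- and sex-specific MOF:hip ratios that
#' assume the Malmo fracture pattern holds. Both tables must share identical
#' band edges per sex; no proration across mismatched bands is attempted.
#'
#' @param hip An [incidence_table()] of hip-fracture rates.
#' @param ratio A [ratio_table()] of MOF:hip incidence ratios on the same
#'   bands.
#' @return An `incidence_table` of MOF rates on the same bands.
#' @export
#' @examples
#' hip <- incidence_table("F", c(50, 70), c(70, NA), c(50, 300))
#' rat <- ratio_table("F", c(50, 70), c(70, NA), c(5, 2))
#' mof_incidence(hip, rat)
mof_incidence <- function(hip, ratio) {
  stopifnot(inherits(hip, "incidence_table"), inherits(ratio, "ratio_table"))
  key <- function(t) paste(t$sex, t$age_lo, band_hi_closed(t$age_lo, t$age_hi))
  if (!identical(sort(key(hip)), sort(key(ratio)))) {
    abort_surfrax(
      "hip incidence and MOF ratio tables must share identical age bands per sex",
      "surfrax_alignment_error"
    )
  }
  r <- ratio$value[match(key(hip), key(ratio))]
  incidence_table(hip$sex, hip$age_lo, hip$age_hi, hip$value * r,
                  country_label = country_label(hip))
}

#' Bundle tables into a country fracture-risk model
#'
#' A `frax_model` bundles the hazards and ratios that define one country
#' model: hip-fracture incidence, mortality (the competing risk), MOF:hip
#' ratios, and a relative-risk configuration. The MOF incidence table is
#' derived eagerly via [mof_incidence()] so both outcomes share one set of
#' validated bands.
#'
#' @param hip_incidence An [incidence_table()].
#' @param mortality A [mortality_table()] covering (at least) the sexes and
#'   ages of the incidence table.
#' @param mof_ratio A [ratio_table()] aligned with `hip_incidence`.
#' @param rr_model A [relative_risk_model()].
#' @param label Free-text model label (e.g. the country).
#' @return An object of class `frax_model`.
#' @export
frax_model <- function(hip_incidence, mortality, mof_ratio,
                       rr_model = default_rr_model(), label = "") {
  stopifnot(inherits(hip_incidence, "incidence_table"),
            inherits(mortality, "mortality_table"),
            inherits(mof_ratio, "ratio_table"),
            inherits(rr_model, "relative_risk_model"))
  check_model_coverage(hip_incidence, mortality)
  structure(
    list(
      hip_incidence = hip_incidence,
      mof_incidence = mof_incidence(hip_incidence, mof_ratio),
      mortality = mortality,
      mof_ratio = mof_ratio,
      rr_model = rr_model,
      label = label
    ),
    class = "frax_model"
  )
}

# mortality must cover every sex and every age the incidence covers
check_model_coverage <- function(incidence, mortality) {
  for (s in unique(incidence$sex)) {
    if (!s %in% mortality$sex) {
      abort_surfrax(paste0("mortality table lacks sex ", s),
                    "surfrax_validation_error")
    }
    inc_b <- incidence[incidence$sex == s, ]
    mor_b <- mortality[mortality$sex == s, ]
    inc_hi <- max(band_hi_closed(inc_b$age_lo, inc_b$age_hi))
    mor_hi <- max(band_hi_closed(mor_b$age_lo, mor_b$age_hi))
    if (min(mor_b$age_lo) > min(inc_b$age_lo) || mor_hi < inc_hi) {
      abort_surfrax(
        paste0("mortality coverage does not span incidence coverage for sex ", s),
        "surfrax_validation_error"
      )
    }
  }
  invisible(NULL)
}

#' @export
print.frax_model <- function(x, ...) {
  cat("<frax_model> ", x$label, "\n",
      "  incidence: ", country_label(x$hip_incidence),
      " | mortality: ", country_label(x$mortality), "\n", sep = "")
  invisible(x)
}

#' Ten-year fracture probability under competing mortality
#'
#' Computes the 10-year probability of a first hip or major osteoporotic
#' fracture for a clinical risk profile, accounting for the competing risk
#' of death, by the standard double-decrement construction with annual
#' discretization. For each year of age `a` in `[age, age + 10)`, with
#' piecewise-constant hazards:
#' fracture hazard `h_f(a)` = baseline outcome incidence at `(a, sex)` times
#' the profile's [relative_risk()] multiplier; death hazard `h_d(a)` is the
#' country mortality. Starting from survival `S = 1`, each year contributes
#' `S * h_f / (h_f + h_d) * (1 - exp(-(h_f + h_d)))` to the cumulative
#' fracture incidence, and `S` is multiplied by `exp(-(h_f + h_d))`. A year
#' with zero total hazard contributes nothing and leaves `S` unchanged.
#' First event wins; relative risks act on the fracture hazard only.
#'
#' @param profile A [risk_profile()]; all ages in `[age, age + 10)` must be
#'   covered by the model's tables.
#' @param model A [frax_model()].
#' @param outcome `"hip"` or `"mof"`.
#' @return A probability in `[0, 1]`.
#' @export
#' @examples
#' kaz <- synth_scenario()$authentic
#' ten_year_probability(risk_profile(70, "F", t_score = -2.5), kaz, "mof")
ten_year_probability <- function(profile, model, outcome = c("hip", "mof")) {
  stopifnot(inherits(profile, "risk_profile"), inherits(model, "frax_model"))
  outcome <- match.arg(outcome)
  d <- decrement_contributions(profile, model, outcome)
  sum(d$fracture)
}

# shared year-by-year double-decrement ledger; the conservation identity
# sum(fracture) + sum(death) + S(10) == 1 is a test invariant
decrement_contributions <- function(profile, model, outcome, horizon = 10) {
  inc <- if (outcome == "hip") model$hip_incidence else model$mof_incidence
  ages <- profile$age + seq_len(horizon) - 1L
  rr <- relative_risk(profile, model$rr_model, outcome)
  h_f <- hazard_at(inc, profile$sex, ages) * rr
  h_d <- hazard_at(model$mortality, profile$sex, ages)
  total <- h_f + h_d
  surv_step <- exp(-total)
  s_start <- cumprod(c(1, surv_step))[seq_len(horizon)]
  frac_share <- ifelse(total > 0, h_f / total, 0)
  death_share <- ifelse(total > 0, h_d / total, 0)
  exit <- s_start * (1 - surv_step)
  list(
    ages = ages,
    fracture = exit * frac_share,
    death = exit * death_share,
    survival = prod(surv_step)
  )
}
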