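# shared fixture builders -- everything constructed in code, no files

# single open-ended band covering [50, 100): constant hazards, exact
# closed-form checks
flat_model <- function(h_f = 0.01, h_d = 0.02, ratio = 1, label = "flat") {
  inc <- incidence_table(c("M", "F"), c(50, 50), c(NA, NA),
                         rep(h_f * 1e5, 2))
  mort <- mortality_table(c("M", "F"), c(50, 50), c(NA, NA), rep(h_d, 2))
  rat <- ratio_table(c("M", "F"), c(50, 50), c(NA, NA), rep(ratio, 2))
  frax_model(inc, mort, rat, label = label)
}

# Gompertz model with tweakable parameters
gompertz_model <- function(inc_alpha = c(M = 15, F = 20),
                           inc_beta = c(M = 0.075, F = 0.09),
                           mort_alpha = c(M = 0.004, F = 0.002),
                           mort_beta = c(M = 0.095, F = 0.095),
                           label = "gompertz") {
  bands <- age_bands()
  inc <- synth_incidence(
    list(M = gompertz_params(inc_alpha[["M"]], inc_beta[["M"]]),
         F = gompertz_params(inc_alpha[["F"]], inc_beta[["F"]])),
    bands
  )
  mort <- synth_mortality(
    list(M = gompertz_params(mort_alpha[["M"]], mort_beta[["M"]]),
         F = gompertz_params(mort_alpha[["F"]], mort_beta[["F"]])),
    bands
  )
  frax_model(inc, mort, synth_ratio(bands), label = label)
}

# hand-built grid_probabilities for comparison-statistics tests
fake_grid_probs <- function(probability, model = "ref", outcome = "mof",
                            age = 70, sex = "M") {
  n <- length(probability)
  out <- tibble::tibble(
    profile_id = sprintf("p%03d", seq_len(n)),
    age = as.integer(age), sex = sex, crf_bitmask = seq_len(n) - 1L,
    t_score = 0, model = model, outcome = outcome,
    probability = probability
  )
  class(out) <- c("grid_probabilities", class(out))
  out
}

# rr model where one named CRF has a given rr (both outcomes alike unless
# split), all others 1, with configurable gradients of risk
simple_rr_model <- function(rr_values = NULL, gr_hip = 1.5, gr_mof = 1.5) {
  base <- tidyr::expand_grid(crf_name = frax_crfs(),
                             outcome = c("hip", "mof"))
  base$rr <- 1
  if (!is.null(rr_values)) {
    for (nm in names(rr_values)) {
      base$rr[base$crf_name == nm] <- rr_values[[nm]]
    }
  }
  relative_risk_model(base, c(hip = gr_hip, mof = gr_mof))
}

write_temp_csv <- function(text) {
  f <- withr::local_tempfile(fileext = ".csv",
                             .local_envir = parent.frame())
  writeLines(text, f)
  f
}
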