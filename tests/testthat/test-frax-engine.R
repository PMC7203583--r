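test_that("relative_risk composes CRF multipliers and the BMD gradient", {
  # no CRFs, T = 0 -> identity
  m <- simple_rr_model()
  expect_identical(relative_risk(risk_profile(70, "F", t_score = 0), m, "hip"), 1)
  expect_identical(relative_risk(risk_profile(70, "F"), m, "mof"), 1)

  # one CRF rr 2.0 with T = -1, GR = 1.5 -> 3.0
  m2 <- simple_rr_model(list(smoking = 2.0), gr_hip = 1.5)
  p2 <- risk_profile(70, "F", crfs = "smoking", t_score = -1)
  expect_equal(relative_risk(p2, m2, "hip"), 3.0)

  # all six CRFs rr 1 each, T = -3.5, GR = 1.6 -> 1.6^3.5
  m3 <- simple_rr_model(gr_mof = 1.6)
  p3 <- risk_profile(60, "M", crfs = frax_crfs(), t_score = -3.5)
  expect_equal(relative_risk(p3, m3, "mof"), 1.6^3.5, tolerance = 1e-12)

  # T above zero gives symmetric credit
  p4 <- risk_profile(60, "M", t_score = 1)
  expect_equal(relative_risk(p4, m3, "mof"), 1 / 1.6)
})

test_that("profile and rr-model validation catch bad configuration", {
  expect_error(risk_profile(70, "F", crfs = "coffee"),
               class = "surfrax_config_error")
  expect_error(risk_profile(39, "F"), class = "surfrax_validation_error")
  expect_error(risk_profile(70, "F", t_score = -6),
               class = "surfrax_validation_error")
  expect_error(risk_profile(70, "F", bmi = 60),
               class = "surfrax_validation_error")
  # gradient of risk must exceed 1
  base <- tidyr::expand_grid(crf_name = frax_crfs(), outcome = c("hip", "mof"))
  base$rr <- 1
  expect_error(relative_risk_model(base, c(hip = 1.0, mof = 1.6)),
               class = "surfrax_config_error")
  expect_error(relative_risk_model(base[-1, ], c(hip = 2, mof = 1.6)),
               class = "surfrax_config_error")
})

test_that("rr model round-trips through CSV and YAML configs", {
  dir <- withr::local_tempdir()
  m <- default_rr_model()
  csv <- file.path(dir, "rr.csv")
  write_rr_model(m, csv)
  expect_equal(read_rr_model(csv)$rr$rr, m$rr$rr)
  expect_equal(read_rr_model(csv)$gradient_of_risk, m$gradient_of_risk)

  yml <- file.path(dir, "rr.yaml")
  crf_list <- split(m$rr, m$rr$crf_name)
  yaml::write_yaml(list(
    crfs = lapply(crf_list, function(d) {
      as.list(setNames(d$rr, d$outcome))
    }),
    gradient_of_risk = as.list(m$gradient_of_risk)
  ), yml)
  m_yaml <- read_rr_model(yml)
  expect_equal(
    dplyr::arrange(m_yaml$rr, crf_name, outcome),
    dplyr::arrange(m$rr, crf_name, outcome)
  )
})

test_that("mof_incidence multiplies hip rates by aligned ratios", {
  hip <- incidence_table("F", c(50, 70), c(70, NA), c(100, 300))
  rat <- ratio_table("F", c(50, 70), c(70, NA), c(4, 1.5))
  mof <- mof_incidence(hip, rat)
  expect_s3_class(mof, "incidence_table")
  expect_equal(mof$value, c(400, 450))

  # all-ones ratio is the identity
  rat1 <- ratio_table("F", c(50, 70), c(70, NA), c(1, 1))
  expect_equal(mof_incidence(hip, rat1)$value, hip$value)

  # band mismatch is refused, no proration
  rat_bad <- ratio_table("F", 50, NA, 4)
  expect_error(mof_incidence(hip, rat_bad),
               class = "surfrax_alignment_error")
})

test_that("ten-year probability matches constant-hazard closed forms", {
  # no fracture hazard -> probability 0
  m0 <- flat_model(h_f = 0, h_d = 0.02)
  expect_identical(ten_year_probability(risk_profile(60, "F"), m0, "hip"), 0)

  # single decrement: 1 - exp(-10 h_f)
  m1 <- flat_model(h_f = 0.01, h_d = 0)
  expect_equal(ten_year_probability(risk_profile(60, "F"), m1, "hip"),
               1 - exp(-0.1), tolerance = 1e-12)

  # competing risk: (h_f / H) (1 - exp(-10 H))
  m2 <- flat_model(h_f = 0.01, h_d = 0.02)
  expect_equal(ten_year_probability(risk_profile(60, "F"), m2, "hip"),
               (1 / 3) * (1 - exp(-0.3)), tolerance = 1e-12)

  # zero total hazard contributes nothing, survival unchanged
  mz <- flat_model(h_f = 0, h_d = 0)
  expect_identical(ten_year_probability(risk_profile(60, "M"), mz, "mof"), 0)
})

test_that("fracture, death and survival probabilities conserve mass", {
  model <- gompertz_model()
  for (age in c(50, 65, 80)) {
    for (sex in c("M", "F")) {
      prof <- risk_profile(age, sex, crfs = c("smoking", "prior_fracture"),
                           t_score = -2)
      d <- surfrax:::decrement_contributions(prof, model, "mof")
      expect_equal(sum(d$fracture) + sum(d$death) + d$survival, 1,
                   tolerance = 1e-12)
      expect_true(all(d$fracture >= 0) && all(d$death >= 0))
    }
  }
})

test_that("probability responds monotonically to risk factors, BMD and mortality", {
  model <- gompertz_model()
  base_prof <- risk_profile(70, "F", t_score = -1)
  p_base <- ten_year_probability(base_prof, model, "mof")
  expect_gt(p_base, 0)
  expect_lt(p_base, 1)

  # each additional CRF (rr > 1) strictly increases the probability
  for (crf in frax_crfs()) {
    p_crf <- ten_year_probability(
      risk_profile(70, "F", crfs = crf, t_score = -1), model, "mof"
    )
    expect_gt(p_crf, p_base)
  }

  # each 0.5 SD drop in T-score strictly increases the probability
  probs <- vapply(seq(0, -3.5, by = -0.5), function(t) {
    ten_year_probability(risk_profile(70, "F", t_score = t), model, "mof")
  }, numeric(1))
  expect_true(all(diff(probs) > 0))

  # raising mortality pointwise never increases fracture probability
  raised <- gompertz_model(mort_alpha = c(M = 0.008, F = 0.004))
  for (age in c(50, 70, 85)) {
    prof <- risk_profile(age, "M", t_score = -2.5)
    expect_lte(ten_year_probability(prof, raised, "hip"),
               ten_year_probability(prof, model, "hip"))
  }
})

test_that("hip never exceeds MOF probability when MOF hazard dominates", {
  # with no CRFs and no T-score the adjusted hazards reduce to the baseline
  # tables, where MOF incidence = hip incidence x ratio >= hip incidence
  model <- gompertz_model()
  for (age in c(50, 60, 70, 80)) {
    for (sex in c("M", "F")) {
      prof <- risk_profile(age, sex)
      expect_lte(ten_year_probability(prof, model, "hip"),
                 ten_year_probability(prof, model, "mof"))
    }
  }
})

test_that("probabilities stay in [0, 1] under extreme configurations", {
  extreme <- flat_model(h_f = 0.5, h_d = 0.5)
  prof <- risk_profile(50, "F", crfs = frax_crfs(), t_score = -3.5)
  for (outc in c("hip", "mof")) {
    p <- ten_year_probability(prof, extreme, outc)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("engine agrees with the Monte Carlo cohort oracle", {
  withr::local_seed(424242)
  model <- gompertz_model()
  for (i in 1:5) {
    prof <- risk_profile(
      age = sample(c(50, 60, 70, 80), 1),
      sex = sample(c("M", "F"), 1),
      crfs = sample(frax_crfs(), sample(0:3, 1)),
      t_score = sample(seq(0, -3.5, by = -0.5), 1)
    )
    outc <- sample(c("hip", "mof"), 1)
    n <- 50000
    p_engine <- ten_year_probability(prof, model, outc)
    sim <- simulate_cohort(model, prof, n = n, outcome = outc,
                           seed = sample.int(1e6, 1))
    p_mc <- sim[["fractured"]] / n
    se <- sqrt(p_engine * (1 - p_engine) / n)
    expect_lte(abs(p_engine - p_mc), 3 * se)
  }
})
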