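#' Clinical risk profile
#'
#' One clinical scenario for the probability engine: age, sex, any subset of
#' the six dichotomous clinical risk factors (CRFs), an optional femoral-neck
#' BMD T-score, and body mass index. BMI is recorded but carries no risk
#' multiplier: the scenario grid holds it fixed at 26 kg/m2 and no BMI-risk
#' function is part of the model.
#'
#' @param age Integer age in years, 40 to 90.
#' @param sex `"M"` or `"F"`.
#' @param crfs Character vector of CRF names that are present (a subset of
#'   [frax_crfs()]); empty for no risk factors.
#' @param t_score Femoral-neck BMD T-score in SD units, in `[-5, 2]`, or
#'   `NULL` when BMD is not entered.
#' @param bmi Body mass index in kg/m2, in `[15, 45]`.
#' @return An object of class `risk_profile`.
#' @export
#' @examples
#' risk_profile(70, "F", crfs = c("prior_fracture", "smoking"), t_score = -2.5)
risk_profile <- function(age, sex, crfs = character(), t_score = NULL,
                         bmi = 26) {
  age <- as.integer(age)
  if (length(age) != 1 || is.na(age) || age < 40 || age > 90) {
    abort_surfrax("age must be a single integer in [40, 90]",
                  "surfrax_validation_error")
  }
  check_sex(sex)
  unknown <- setdiff(crfs, frax_crfs())
  if (length(unknown) > 0) {
    abort_surfrax(
      paste0("unknown clinical risk factor(s): ", paste(unknown, collapse = ", ")),
      "surfrax_config_error"
    )
  }
  if (!is.null(t_score)) {
    t_score <- as.numeric(t_score)
    if (length(t_score) != 1 || is.na(t_score) || t_score < -5 || t_score > 2) {
      abort_surfrax("t_score must lie in [-5, 2]", "surfrax_validation_error")
    }
  }
  bmi <- as.numeric(bmi)
  if (length(bmi) != 1 || is.na(bmi) || bmi < 15 || bmi > 45) {
    abort_surfrax("bmi must lie in [15, 45]", "surfrax_validation_error")
  }
  structure(
    list(age = age, sex = sex, crfs = sort(unique(crfs)),
         t_score = t_score, bmi = bmi),
    class = "risk_profile"
  )
}

#' @export
print.risk_profile <- function(x, ...) {
  cat("<risk_profile> age ", x$age, ", sex ", x$sex,
      ", CRFs: ", if (length(x$crfs)) paste(x$crfs, collapse = "+") else "none",
      ", T-score: ", if (is.null(x$t_score)) "absent" else x$t_score,
      ", BMI: ", x$bmi, "\n", sep = "")
  invisible(x)
}

#' Relative-risk model for clinical risk factors and BMD
#'
#' Holds the multiplicative relative risks `rr(crf, outcome)` for the six
#' dichotomous CRFs and the gradient of risk (GR): the risk multiplier per
#' SD decrease in femoral-neck T-score, per outcome. CRF effects compose
#' multiplicatively and are age-independent; the T-score multiplier is
#' anchored at 1 for T = 0 and equals `GR^(-t_score)` (so risk increases
#' below zero and decreases symmetrically above).
#'
#' @param rr A data frame with columns `crf_name`, `outcome` (`"hip"` or
#'   `"mof"`) and `rr` (strictly positive multipliers), covering every CRF in
#'   [frax_crfs()] for both outcomes.
#' @param gradient_of_risk Named numeric vector with elements `hip` and
#'   `mof`, each greater than 1.
#' @return An object of class `relative_risk_model`.
#' @export
relative_risk_model <- function(rr, gradient_of_risk) {
  rr <- tibble::as_tibble(rr)
  needed <- c("crf_name", "outcome", "rr")
  if (!all(needed %in% names(rr))) {
    abort_surfrax("rr must have columns crf_name, outcome, rr",
                  "surfrax_config_error")
  }
  if (!all(rr$outcome %in% c("hip", "mof"))) {
    abort_surfrax("rr outcome must be 'hip' or 'mof'", "surfrax_config_error")
  }
  unknown <- setdiff(rr$crf_name, frax_crfs())
  if (length(unknown) > 0) {
    abort_surfrax(paste0("unknown CRF in rr table: ",
                         paste(unknown, collapse = ", ")),
                  "surfrax_config_error")
  }
  full <- expand.grid(crf_name = frax_crfs(), outcome = c("hip", "mof"),
                      stringsAsFactors = FALSE)
  have <- paste(rr$crf_name, rr$outcome)
  if (!all(paste(full$crf_name, full$outcome) %in% have)) {
    abort_surfrax("rr table must cover all six CRFs for both outcomes",
                  "surfrax_config_error")
  }
  if (any(rr$rr <= 0)) {
    abort_surfrax("relative risks must be strictly positive",
                  "surfrax_config_error")
  }
  gr <- gradient_of_risk[c("hip", "mof")]
  if (any(is.na(gr)) || any(gr <= 1)) {
    abort_surfrax("gradient_of_risk must exceed 1 for both outcomes",
                  "surfrax_config_error")
  }
  structure(
    list(rr = rr[, needed], gradient_of_risk = gr),
    class = "relative_risk_model"
  )
}

#' Default relative-risk configuration
#'
#' A plausible literature-scale set of CRF relative risks and gradients of
#' risk used by the synthetic scenario. These are synthetic configuration
#' values for testing and illustration, not estimates of any calibrated
#' fracture-risk engine's coefficients.
#'
#' @return A `relative_risk_model`.
#' @export
default_rr_model <- function() {
  rr <- tibble::tribble(
    ~crf_name,              ~hip, ~mof,
    "prior_fracture",        2.0,  1.8,
    "parent_hip_fracture",   2.3,  1.5,
    "smoking",               1.6,  1.2,
    "glucocorticoids",       2.2,  1.6,
    "rheumatoid_arthritis",  1.7,  1.4,
    "alcohol",               1.7,  1.4
  )
  rr_long <- tidyr::pivot_longer(rr, c("hip", "mof"),
                                 names_to = "outcome", values_to = "rr")
  relative_risk_model(
    rr = rr_long[, c("crf_name", "outcome", "rr")],
    gradient_of_risk = c(hip = 2.4, mof = 1.6)
  )
}

#' Read a relative-risk model from a YAML or CSV configuration
#'
#' YAML layout: a `crfs` mapping of CRF name to `{hip: rr, mof: rr}` plus a
#' `gradient_of_risk` mapping `{hip: gr, mof: gr}`. CSV layout: columns
#' `crf_name`, `outcome`, `rr`, with the gradient of risk encoded as rows
#' whose `crf_name` is `gradient_of_risk`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.csv` file.
#' @return A `relative_risk_model`.
#' @export
read_rr_model <- function(path) {
  if (!file.exists(path)) {
    abort_surfrax(paste0("file not found: ", path), "surfrax_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$crfs) || is.null(cfg$gradient_of_risk)) {
      abort_surfrax("rr config must contain 'crfs' and 'gradient_of_risk'",
                    "surfrax_config_error")
    }
    rr <- dplyr::bind_rows(lapply(names(cfg$crfs), function(nm) {
      tibble::tibble(crf_name = nm, outcome = c("hip", "mof"),
                     rr = c(cfg$crfs[[nm]]$hip, cfg$crfs[[nm]]$mof))
    }))
    gr <- c(hip = cfg$gradient_of_risk$hip, mof = cfg$gradient_of_risk$mof)
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    if (!all(c("crf_name", "outcome", "rr") %in% names(df))) {
      abort_surfrax("rr CSV must have columns crf_name, outcome, rr",
                    "surfrax_schema_error")
    }
    grrows <- df$crf_name == "gradient_of_risk"
    gr <- setNames(df$rr[grrows], df$outcome[grrows])[c("hip", "mof")]
    rr <- df[!grrows, ]
  }
  relative_risk_model(rr, gr)
}

#' Write a relative-risk model to CSV
#'
#' @param model A `relative_risk_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rr_model <- function(model, path) {
  stopifnot(inherits(model, "relative_risk_model"))
  gr <- tibble::tibble(crf_name = "gradient_of_risk",
                       outcome = c("hip", "mof"),
                       rr = unname(model$gradient_of_risk[c("hip", "mof")]))
  readr::write_csv(dplyr::bind_rows(model$rr, gr), path, progress = FALSE)
  invisible(path)
}

#' Combined relative-risk multiplier for a profile
#'
#' The product over the profile's set CRFs of `rr(crf, outcome)`, times
#' `GR^(-t_score)` when a T-score is entered. A profile with no CRFs and
#' T-score 0 (or absent) has multiplier 1. The multiplier scales the
#' fracture hazard only; mortality is never adjusted.
#'
#' @param profile A [risk_profile()].
#' @param rr_model A [relative_risk_model()].
#' @param outcome `"hip"` or `"mof"`.
#' @return A single positive multiplier.
#' @export
#' @examples
#' m <- default_rr_model()
#' relative_risk(risk_profile(70, "F"), m, "hip") # 1
relative_risk <- function(profile, rr_model, outcome = c("hip", "mof")) {
  stopifnot(inherits(profile, "risk_profile"),
            inherits(rr_model, "relative_risk_model"))
  outcome <- match.arg(outcome)
  rr <- rr_model$rr[rr_model$rr$outcome == outcome, ]
  mult <- 1
  if (length(profile$crfs) > 0) {
    idx <- match(profile$crfs, rr$crf_name)
    if (anyNA(idx)) {
      abort_surfrax("profile contains a CRF absent from the rr model",
                    "surfrax_config_error")
    }
    mult <- prod(rr$rr[idx])
  }
  if (!is.null(profile$t_score)) {
    mult <- mult * rr_model$gradient_of_risk[[outcome]]^(-profile$t_score)
  }
  mult
}
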