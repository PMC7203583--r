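#' Build a surrogate country model
#'
#' A surrogate model is recommended practice when a country lacks reliable
#' fracture registries but has good mortality statistics: fracture incidence
#' is borrowed from a country judged epidemiologically representative, and
#' combined with the index country's own death rates. The returned model
#' shares the source model's hip incidence, MOF ratios and relative-risk
#' configuration (value-identical), and carries the target mortality and a
#' new label.
#'
#' @param source A [frax_model()] supplying the fracture epidemiology.
#' @param target_mortality A [mortality_table()] for the index country; must
#'   cover the sexes and ages of the source incidence.
#' @param label Label for the surrogate model.
#' @return A [frax_model()].
#' @export
#' @examples
#' sc <- synth_scenario()
#' surr <- build_surrogate(sc$authentic, sc$target_mortality, "surrogate")
build_surrogate <- function(source, target_mortality, label = "surrogate") {
  stopifnot(inherits(source, "frax_model"),
            inherits(target_mortality, "mortality_table"))
  check_model_coverage(source$hip_incidence, target_mortality)
  frax_model(
    hip_incidence = source$hip_incidence,
    mortality = target_mortality,
    mof_ratio = source$mof_ratio,
    rr_model = source$rr_model,
    label = label
  )
}

#' Exhaustive clinical-scenario grid
#'
#' Expands every combination of the dichotomous clinical risk factors with a
#' ladder of BMD T-scores, at each requested age and sex. With the default
#' six CRFs and eight T-scores (0 to -3.5 SD in 0.5 SD steps) this yields
#' `2^6 * 8 = 512` profiles per age/sex cell — an array of all possible
#' combinations, not a population simulation. Profiles carry stable
#' deterministic ids ordered by CRF bitmask then T-score so that paired
#' comparisons across models align exactly.
#'
#' @param ages Integer vector of ages (default 50, 60, 70, 80).
#' @param sexes Character vector (default both sexes).
#' @param t_scores Numeric vector of T-scores (default `seq(0, -3.5, -0.5)`).
#' @param bmi BMI held fixed across the grid (default 26 kg/m2).
#' @param crfs CRF names to toggle (default all six in [frax_crfs()]).
#' @return A tibble of class `scenario_grid` with columns `profile_id`,
#'   `age`, `sex`, `crf_bitmask`, `t_score`, `bmi`.
#' @export
#' @examples
#' nrow(make_grid(ages = 70, sexes = "M")) # 512
make_grid <- function(ages = c(50L, 60L, 70L, 80L),
                      sexes = c("M", "F"),
                      t_scores = seq(0, -3.5, by = -0.5),
                      bmi = 26,
                      crfs = frax_crfs()) {
  if (length(ages) == 0 || length(sexes) == 0) {
    abort_surfrax("ages and sexes must be non-empty", "surfrax_validation_error")
  }
  if (length(t_scores) == 0) {
    abort_surfrax("t_scores must be non-empty", "surfrax_validation_error")
  }
  check_sex(sexes)
  unknown <- setdiff(crfs, frax_crfs())
  if (length(unknown) > 0) {
    abort_surfrax(paste0("unknown CRF(s): ", paste(unknown, collapse = ", ")),
                  "surfrax_config_error")
  }
  masks <- seq_len(2^length(crfs)) - 1L
  grid <- tidyr::expand_grid(
    age = as.integer(ages),
    sex = sexes,
    crf_bitmask = masks,
    t_score = as.numeric(t_scores)
  )
  grid <- dplyr::arrange(grid, .data$age, .data$sex, .data$crf_bitmask,
                         dplyr::desc(.data$t_score))
  grid$bmi <- bmi
  t_norm <- ifelse(grid$t_score == 0, 0, grid$t_score) # drop negative zero
  grid$profile_id <- sprintf("a%02d_%s_c%03d_t%+05.1f",
                             grid$age, grid$sex, grid$crf_bitmask, t_norm)
  out <- grid[, c("profile_id", "age", "sex", "crf_bitmask", "t_score", "bmi")]
  attr(out, "crfs") <- crfs
  class(out) <- c("scenario_grid", class(out))
  out
}

# decode a CRF bitmask (bit j set -> crfs[j + 1] present)
crfs_from_bitmask <- function(bitmask, crfs = frax_crfs()) {
  crfs[bitwAnd(bitmask, 2^(seq_along(crfs) - 1)) > 0]
}

#' Evaluate a scenario grid under a model
#'
#' Computes hip and major osteoporotic 10-year probabilities for every
#' profile in the grid. Both outcomes are always evaluated; callers filter.
#' The result is deterministic given the inputs.
#'
#' @param model A [frax_model()]; its tables must cover every grid age plus
#'   ten years.
#' @param grid A [make_grid()] result.
#' @return A tibble of class `grid_probabilities` with columns `profile_id`,
#'   `age`, `sex`, `crf_bitmask`, `t_score`, `model`, `outcome`,
#'   `probability` — one row per profile and outcome.
#' @export
evaluate_grid <- function(model, grid) {
  stopifnot(inherits(model, "frax_model"), inherits(grid, "scenario_grid"))
  crfs <- attr(grid, "crfs") %||% frax_crfs()
  rows <- lapply(c("hip", "mof"), function(outc) {
    p <- vapply(seq_len(nrow(grid)), function(i) {
      prof <- risk_profile(
        age = grid$age[i], sex = grid$sex[i],
        crfs = crfs_from_bitmask(grid$crf_bitmask[i], crfs),
        t_score = grid$t_score[i], bmi = grid$bmi[i]
      )
      tryCatch(
        ten_year_probability(prof, model, outc),
        surfrax_range_error = function(e) {
          abort_surfrax(
            paste0("model coverage fails for profile ", grid$profile_id[i],
                   ": ", conditionMessage(e)),
            "surfrax_range_error"
          )
        }
      )
    }, numeric(1))
    tibble::tibble(
      profile_id = grid$profile_id, age = grid$age, sex = grid$sex,
      crf_bitmask = grid$crf_bitmask, t_score = grid$t_score,
      model = model$label, outcome = outc, probability = p
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grid_probabilities", class(out))
  out
}

#' Write or read grid probabilities as CSV
#'
#' @param probs A `grid_probabilities` tibble from [evaluate_grid()].
#' @param path CSV path.
#' @return `write_grid_probabilities()`: `path` invisibly;
#'   `read_grid_probabilities()`: the `grid_probabilities` tibble.
#' @export
write_grid_probabilities <- function(probs, path) {
  stopifnot(inherits(probs, "grid_probabilities"))
  readr::write_csv(tibble::as_tibble(unclass(probs)[names(probs)]), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_grid_probabilities
#' @export
read_grid_probabilities <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(
                          profile_id = readr::col_character(),
                          sex = readr::col_character(),
                          model = readr::col_character(),
                          outcome = readr::col_character(),
                          .default = readr::col_double()
                        ))
  needed <- c("profile_id", "age", "sex", "crf_bitmask", "t_score",
              "model", "outcome", "probability")
  if (!all(needed %in% names(df))) {
    abort_surfrax("not a grid-probabilities CSV", "surfrax_schema_error")
  }
  out <- df[, needed]
  out$age <- as.integer(out$age)
  out$crf_bitmask <- as.integer(out$crf_bitmask)
  out$t_score <- as.numeric(out$t_score)
  out$probability <- as.numeric(out$probability)
  class(out) <- c("grid_probabilities", class(out))
  out
}
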