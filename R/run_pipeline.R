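#' Pipeline run configuration
#'
#' Reads (or builds from defaults) the configuration driving the batch
#' commands [run_simulate()], [run_evaluate()], [run_compare()] and
#' [run_project()]. A YAML file may override any subset of:
#'
#' ```yaml
#' tables:                 # CSV paths; omit to use the synthetic scenario
#'   incidence: path.csv
#'   mortality: path.csv
#'   ratio: path.csv
#'   target_mortality: path.csv
#'   population: path.csv
#'   rr_model: path.csv    # or .yaml
#' grid: {ages: [50, 60, 70, 80], t_min: -3.5, t_max: 0.0, t_step: 0.5, bmi: 26}
#' comparison: {knot: 40, percentile: 50, ti_coverage: 0.95,
#'              ti_confidence: 0.95, rank_window: 10}
#' projection: {years: [2015, 2020, 2030, 2040, 2050], base_year: 2015, min_age: 50}
#' labels: {authentic: authentic, surrogate: surrogate}
#' out_dir: out
#' seed: 1
#' ```
#'
#' Referenced table paths must exist at validation time, and the T-score
#' step must divide the T-score range.
#'
#' @param path Path to a YAML config, or `NULL` for pure defaults.
#' @param out_dir,seed Optional overrides applied after reading the file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path = NULL, out_dir = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_surfrax(paste0("config file not found: ", path),
                    "surfrax_config_error")
    }
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (!is.null(seed)) cfg$seed <- seed
  validate_run_config(cfg)
}

default_run_config <- function() {
  list(
    tables = list(),
    grid = list(ages = c(50L, 60L, 70L, 80L), t_min = -3.5, t_max = 0,
                t_step = 0.5, bmi = 26),
    comparison = list(knot = 40, percentile = 50, ti_coverage = 0.95,
                      ti_confidence = 0.95, rank_window = 10),
    projection = list(years = c(2015L, 2020L, 2030L, 2040L, 2050L),
                      base_year = 2015L, min_age = 50L),
    labels = list(authentic = "authentic", surrogate = "surrogate"),
    out_dir = "out",
    seed = 1L
  )
}

validate_run_config <- function(cfg) {
  for (nm in names(cfg$tables)) {
    p <- cfg$tables[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      abort_surfrax(paste0("configured table path does not exist: ", nm,
                           " = ", p), "surfrax_config_error")
    }
  }
  g <- cfg$grid
  span <- g$t_max - g$t_min
  if (g$t_step <= 0 || abs(span / g$t_step - round(span / g$t_step)) > 1e-9) {
    abort_surfrax("t_step must divide the T-score range", "surfrax_config_error")
  }
  structure(cfg, class = "run_config")
}

config_t_scores <- function(cfg) {
  seq(cfg$grid$t_max, cfg$grid$t_min, by = -cfg$grid$t_step)
}

# assemble the two models from configured tables, falling back to the
# synthetic default scenario for any table not supplied
config_models <- function(cfg) {
  t <- cfg$tables
  all_supplied <- all(c("incidence", "mortality", "ratio",
                        "target_mortality") %in% names(t))
  if (!all_supplied) {
    sc <- synth_scenario(seed = cfg$seed)
    authentic <- sc$authentic
    target_mortality <- sc$target_mortality
    population <- sc$population
  }
  if (all_supplied) {
    rr <- if (!is.null(t$rr_model)) read_rr_model(t$rr_model) else default_rr_model()
    authentic <- frax_model(
      read_table(t$incidence, "incidence"),
      read_table(t$mortality, "mortality"),
      read_table(t$ratio, "ratio"),
      rr_model = rr, label = cfg$labels$authentic
    )
    target_mortality <- read_table(t$target_mortality, "mortality")
    population <- if (!is.null(t$population)) {
      read_table(t$population, "population")
    } else {
      synth_population(seed = cfg$seed)
    }
  } else if (!is.null(t$population)) {
    population <- read_table(t$population, "population")
  }
  authentic$label <- cfg$labels$authentic
  list(
    authentic = authentic,
    surrogate = build_surrogate(authentic, target_mortality,
                                label = cfg$labels$surrogate),
    population = population
  )
}

# every run drops a manifest next to its outputs: config hash, versions,
# timestamp, file list
write_manifest <- function(cfg, out_dir, files, command) {
  norm <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(cfg), norm)
  manifest <- list(
    command = command,
    config_md5 = unname(tools::md5sum(norm)),
    files = basename(files),
    package_version = as.character(utils::packageVersion("surfrax")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  unlink(norm)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

ensure_out_dir <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg$out_dir
}

#' Batch pipeline commands
#'
#' Thin orchestration over the package's functions, suitable for scripted
#' use; every command writes deterministic primary outputs (given config and
#' seed) plus a `manifest.json` recording the config hash, package and R
#' versions and a timestamp.
#'
#' * `run_simulate()` writes the synthetic default scenario's tables as
#'   fixture CSVs under `<out_dir>/fixtures/`.
#' * `run_evaluate()` evaluates the scenario grid under the authentic and
#'   surrogate models and writes one grid-probabilities CSV per model.
#' * `run_compare()` writes the percentile/tolerance-interval/correlation
#'   report (full precision plus 1-decimal display columns) and a scatter
#'   plot of surrogate versus authentic probabilities with the identity
#'   line.
#' * `run_project()` writes the fracture-count projection report.
#'
#' @param config A `run_config` from [read_run_config()].
#' @return Invisibly, a character vector of the files written.
#' @export
run_simulate <- function(config = read_run_config()) {
  config <- validate_run_config(config)
  out <- file.path(ensure_out_dir(config), "fixtures")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- synth_scenario(seed = config$seed)
  files <- c(
    write_table(sc$authentic$hip_incidence, file.path(out, "incidence.csv")),
    write_table(sc$authentic$mortality, file.path(out, "mortality.csv")),
    write_table(sc$target_mortality, file.path(out, "target_mortality.csv")),
    write_table(sc$authentic$mof_ratio, file.path(out, "ratio.csv")),
    write_table(sc$population, file.path(out, "population.csv")),
    write_rr_model(sc$authentic$rr_model, file.path(out, "rr_model.csv"))
  )
  write_manifest(config, out, files, "simulate")
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_evaluate <- function(config = read_run_config()) {
  config <- validate_run_config(config)
  out <- ensure_out_dir(config)
  models <- config_models(config)
  grid <- make_grid(ages = config$grid$ages,
                    t_scores = config_t_scores(config),
                    bmi = config$grid$bmi)
  files <- vapply(c("authentic", "surrogate"), function(which) {
    probs <- evaluate_grid(models[[which]], grid)
    f <- file.path(out, paste0("grid_probabilities_", which, ".csv"))
    write_grid_probabilities(probs, f)
    f
  }, character(1))
  write_manifest(config, out, files, "evaluate")
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_compare <- function(config = read_run_config()) {
  config <- validate_run_config(config)
  out <- ensure_out_dir(config)
  models <- config_models(config)
  grid <- make_grid(ages = config$grid$ages,
                    t_scores = config_t_scores(config),
                    bmi = config$grid$bmi)
  ref <- evaluate_grid(models$authentic, grid)
  sur <- evaluate_grid(models$surrogate, grid)
  cmp <- config$comparison
  report <- comparison_report(ref, sur, percentile = cmp$percentile,
                              knot = cmp$knot, rank_window = cmp$rank_window,
                              ti_coverage = cmp$ti_coverage,
                              ti_confidence = cmp$ti_confidence)
  # 1-decimal display columns alongside full precision
  report$reference_median_1dp <- sprintf("%.1f", report$reference_median)
  report$surrogate_median_1dp <- sprintf("%.1f", report$surrogate_median)
  report$ti_1dp <- sprintf("%.1f-%.1f", report$ti_lo, report$ti_hi)
  f_csv <- file.path(out, "comparison_report.csv")
  readr::write_csv(report, f_csv, progress = FALSE)
  f_plot <- file.path(out, "comparison_scatter.pdf")
  age_plot <- if (70 %in% config$grid$ages) 70 else config$grid$ages[1]
  p <- plot_grid_comparison(ref, sur, age = age_plot)
  ggplot2::ggsave(f_plot, p, width = 8, height = 8)
  files <- c(f_csv, f_plot)
  write_manifest(config, out, files, "compare")
  invisible(files)
}

#' @rdname run_simulate
#' @export
run_project <- function(config = read_run_config()) {
  config <- validate_run_config(config)
  out <- ensure_out_dir(config)
  models <- config_models(config)
  prj <- config$projection
  result <- project(models$authentic$hip_incidence, models$population,
                    years = prj$years, base_year = prj$base_year,
                    min_age = prj$min_age)
  f_report <- file.path(out, "projection_report.csv")
  write_projection_report(result, f_report)
  f_counts <- file.path(out, "projection_counts.csv")
  readr::write_csv(result$counts, f_counts, progress = FALSE)
  files <- c(f_report, f_counts)
  write_manifest(config, out, files, "project")
  invisible(files)
}

#' Scatter plot of surrogate versus reference probabilities
#'
#' One panel per outcome and sex at a single age, with the line of identity;
#' the standard visual check that a surrogate model preserves the ranking
#' of clinical scenarios.
#'
#' @param reference,surrogate `grid_probabilities` tibbles.
#' @param age Age (years) to display.
#' @return A ggplot object.
#' @export
plot_grid_comparison <- function(reference, surrogate, age = 70) {
  paired <- dplyr::inner_join(
    tibble::as_tibble(reference)[reference$age == age,
                                 c("profile_id", "sex", "outcome", "probability")],
    tibble::as_tibble(surrogate)[surrogate$age == age,
                                 c("profile_id", "sex", "outcome", "probability")],
    by = c("profile_id", "sex", "outcome"), suffix = c("_ref", "_sur")
  )
  if (nrow(paired) == 0) {
    abort_surfrax("no paired rows at the requested age",
                  "surfrax_empty_selection_error")
  }
  ggplot2::ggplot(paired,
                  ggplot2::aes(x = 100 * .data$probability_ref,
                               y = 100 * .data$probability_sur)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_grid(outcome ~ sex, scales = "free") +
    ggplot2::labs(
      x = "Reference model 10-year probability (%)",
      y = "Surrogate model 10-year probability (%)",
      title = paste0("Surrogate vs reference probabilities, age ", age)
    ) +
    ggplot2::theme_bw()
}
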