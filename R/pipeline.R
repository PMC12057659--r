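#' End-to-end synthetic study pipeline
#'
#' Composes every stage of the analysis on one synthetic study: generate
#' cytological scoring tables, FISH counts and progeny sex counts for a
#' driver genotype (plus a Mendelian control genotype for the comparative
#' tests); exclude nondisjunction spermatids; estimate the segregation
#' probabilities and the drive strength; run the three statistical tests;
#' and forecast the population consequence of the estimated drive strength
#' against the extinction threshold for the configured demography.
#'
#' All randomness derives deterministically from `config$seed`: the same
#' configuration and seed produce an identical report (and, via
#' [write_pipeline_report()], byte-identical JSON).
#'
#' @param config A list with elements:
#' * `preset` -- preset name from [drive_presets()] or an explicit list with
#'   `p1`, `q`, `p2`, `k` (and optionally `nondisjunction_rate`);
#' * `seed` -- integer master seed (required);
#' * `z`, `w` -- demographic parameters for the forecast (default 2, 2);
#' * `n_cells_MI`, `n_cells_MII` -- telophase cells scored (default 500);
#' * `n_spermatids` -- FISH-scored protein-positive spermatids (default 1000);
#' * `n_males`, `offspring_per_period_mean`, `n_periods`, `age_trend` --
#'   progeny assay design (defaults 10, 60, 5, 0);
#' * `out_dir` -- optional directory; when set, the synthetic tables are
#'   written as CSV and the report as JSON.
#'
#' @return An object of class `pipeline_report`: a list with the generating
#'   parameters, the synthetic tables, cytology estimates (with 95% CIs),
#'   `t_hat` with CI, `t_cytology` (drive strength implied by the true
#'   preset parameters), test results, and the population forecast
#'   (`t_threshold`, `threshold_margin`, `outcome`).
#' @examples
#' rep <- run_full_pipeline(list(preset = "idealized", seed = 1))
#' rep$estimates$t_hat$estimate
#' @export
run_full_pipeline <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config$seed is required [stage: config]")
  cfg <- utils::modifyList(
    list(preset = "XSte200_Y", z = 2, w = 2,
         n_cells_MI = 500L, n_cells_MII = 500L, n_spermatids = 1000L,
         n_males = 10L, offspring_per_period_mean = 60,
         n_periods = 5L, age_trend = 0, out_dir = NULL),
    config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s [stage: %s]", conditionMessage(e), name), call. = FALSE))
  }

  pp <- stage("config", resolve_preset(cfg$preset))
  mp <- stage("config", meiosis_params(pp$p1, pp$q, pp$p2, pp$k))
  t_true <- drive_strength_from_cytology(mp)
  seeds <- cfg$seed + 0:5  # deterministic per-stage sub-seeds

  # --- synthetic study -------------------------------------------------
  tI <- stage("gen_telophase_MI",
              gen_telophase_counts(cfg$n_cells_MI, pp$p1, pp$q, "MI",
                                   seed = seeds[1], genotype = pp$name))
  tII <- stage("gen_telophase_MII",
               gen_telophase_counts(cfg$n_cells_MII, pp$p2, stage = "MII",
                                    seed = seeds[2], genotype = pp$name))
  fish <- stage("gen_fish",
                gen_spermatid_fish_counts(cfg$n_spermatids, mp,
                                          pp$nondisjunction_rate,
                                          seed = seeds[3], genotype = pp$name))
  progeny <- stage("gen_progeny",
                   gen_progeny_counts(cfg$n_males, t_true,
                                      cfg$offspring_per_period_mean,
                                      cfg$n_periods, cfg$age_trend,
                                      seed = seeds[4], genotype = pp$name))
  control <- stage("gen_control_progeny",
                   gen_progeny_counts(cfg$n_males, 0.5,
                                      cfg$offspring_per_period_mean,
                                      cfg$n_periods, cfg$age_trend,
                                      seed = seeds[5], genotype = "control"))

  # --- estimation ------------------------------------------------------
  cyt <- stage("estimate_cytology", estimate_cytology_params(tI, tII))
  drive <- stage("estimate_drive", estimate_drive_strength(progeny))
  drive_ctl <- stage("estimate_drive_control", estimate_drive_strength(control))

  # --- tests (nondisjunction spermatids excluded) ----------------------
  n_y <- fish$counts[["Y"]]
  n_x <- fish$counts[["X"]]
  fish_test <- stage("binomial_test",
                     binomial_two_sided(n_y, n_y + n_x, 0.5))
  sex_table <- matrix(c(sum(progeny$females), sum(progeny$males),
                        sum(control$females), sum(control$males)),
                      nrow = 2, byrow = TRUE,
                      dimnames = list(c(pp$name, "control"),
                                      c("females", "males")))
  fisher_test <- stage("fisher_test", fisher_exact_two_sided(sex_table))
  ratio_a <- drive$per_male_ratio
  ratio_b <- drive_ctl$per_male_ratio
  t_test <- stage("t_test",
                  unpaired_t_two_sided(ratio_a[is.finite(ratio_a)],
                                       ratio_b[is.finite(ratio_b)]))

  # --- population forecast at the estimated drive strength -------------
  thr <- stage("threshold", analytic_threshold(cfg$z, cfg$w))
  t_for_model <- min(max(drive$t_hat, 0.5), 1)
  forecast_phase <- stage("classify",
                          classify_dynamics(drive_params(t_for_model,
                                                         cfg$z, cfg$w)))

  report <- structure(list(
    config = cfg[c("preset", "seed", "z", "w", "n_cells_MI", "n_cells_MII",
                   "n_spermatids", "n_males", "offspring_per_period_mean",
                   "n_periods", "age_trend")],
    preset_params = pp,
    t_cytology = t_true,
    tables = list(telophase_I = tI, telophase_II = tII, fish = fish,
                  progeny = progeny, control_progeny = control),
    estimates = list(
      cytology = cyt,
      t_hat = list(estimate = drive$t_hat, lower = drive$lower,
                   upper = drive$upper, n_offspring = drive$n_offspring),
      per_male_ratio = as.numeric(drive$per_male_ratio),
      control_t_hat = list(estimate = drive_ctl$t_hat,
                           lower = drive_ctl$lower, upper = drive_ctl$upper)),
    tests = list(fish_vs_equal = fish_test,
                 sex_ratio_vs_control = fisher_test,
                 per_male_ratio_t = t_test),
    forecast = list(t_threshold = thr$t_threshold,
                    threshold_margin = drive$t_hat - thr$t_threshold,
                    outcome = forecast_phase$outcome)),
    class = "pipeline_report")

  if (!is.null(cfg$out_dir)) write_pipeline_outputs(report, cfg$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("synthetic drive study: preset '%s', seed %s\n",
              x$config$preset, format(x$config$seed)))
  cat(sprintf("  drive strength: t_hat = %.4f [%.4f, %.4f] (cytology-implied %.4f)\n",
              x$estimates$t_hat$estimate, x$estimates$t_hat$lower,
              x$estimates$t_hat$upper, x$t_cytology))
  cat(sprintf("  threshold at z = %g, w = %g: %.4f; margin %+.4f -> %s\n",
              x$config$z, x$config$w, x$forecast$t_threshold,
              x$forecast$threshold_margin, x$forecast$outcome))
  cat(sprintf("  p-values: FISH vs 50:50 %.3g; sexes vs control %.3g; per-male t %.3g\n",
              x$tests$fish_vs_equal$p_value,
              x$tests$sex_ratio_vs_control$p_value,
              x$tests$per_male_ratio_t$p_value))
  invisible(x)
}

#' Serialize a pipeline report to canonical JSON
#'
#' Writes the report (without the raw tables) as JSON with 12 significant
#' digits so that identical configurations and seeds produce byte-identical
#' files.
#'
#' @param report A `pipeline_report`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_pipeline_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "pipeline_report"))
  strip <- function(x) {
    if (inherits(x, "exact_test_result"))
      x <- x[c("method", "statistic", "p_value", "sample_sizes")]
    if (is.list(x)) return(lapply(x, strip))
    x
  }
  payload <- strip(unclass(report)[c("config", "preset_params", "t_cytology",
                                     "estimates", "tests", "forecast")])
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 12,
                           null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

write_pipeline_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab_df <- function(st) data.frame(category = names(st$counts),
                                    count = as.integer(st$counts))
  utils::write.csv(tab_df(report$tables$telophase_I),
                   file.path(out_dir, "telophase_I.csv"), row.names = FALSE)
  utils::write.csv(tab_df(report$tables$telophase_II),
                   file.path(out_dir, "telophase_II.csv"), row.names = FALSE)
  utils::write.csv(tab_df(report$tables$fish),
                   file.path(out_dir, "fish_counts.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$tables$progeny),
                   file.path(out_dir, "progeny.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$tables$control_progeny),
                   file.path(out_dir, "control_progeny.csv"), row.names = FALSE)
  write_pipeline_report(report, file.path(out_dir, "report.json"))
  invisible(NULL)
}
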