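#' Configuration for the end-to-end photoporation analysis pipeline
#'
#' One master seed deterministically derives every stage's sub-seed, so the
#' whole run (synthetic data, trace analysis, step-scale calibration, Monte
#' Carlo curves, fits, concordance) is byte-reproducible.
#'
#' @param outdir Output directory for all stage files.
#' @param seed Master seed (integer).
#' @param design An [experiment_design()]; its seed is re-derived from the
#'   master seed.
#' @param threshold,k_sigma,confirm_frames Trace-processing settings
#'   (see [analyze_trace()]).
#' @param cell A [cell_model()].
#' @param sim A [sim_params()] for the loading curves (seed re-derived).
#' @param calib_sim A [sim_params()] for the bisection calibration; smaller
#'   by default since each bisection step repeats the anchor simulation.
#' @param anchor Named list `mw`, `time`, `loading`: the experimental
#'   operating point the step scale is calibrated against (defaults to the
#'   10 kDa tracer at 88.7 s resealing with 22.9 percent loading).
#' @param mw_grid Molecular weights for the loading-versus-MW curve (kDa).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = tempfile("optopore_run_"),
                            seed = 1L,
                            design = experiment_design(),
                            threshold = 0.90, k_sigma = 5, confirm_frames = 3L,
                            cell = cell_model(),
                            sim = sim_params(),
                            calib_sim = sim_params(n_particles = 2000L,
                                                   n_replicates = 4L),
                            anchor = list(mw = 10, time = 88.7, loading = 0.229),
                            mw_grid = c(5, 10, 40, 70, 100)) {
  stopifnot(inherits(design, "experiment_design"), inherits(cell, "cell_model"),
            inherits(sim, "sim_params"), inherits(calib_sim, "sim_params"),
            all(c("mw", "time", "loading") %in% names(anchor)))
  structure(list(outdir = outdir, seed = as.integer(seed), design = design,
                 threshold = threshold, k_sigma = k_sigma,
                 confirm_frames = as.integer(confirm_frames),
                 cell = cell, sim = sim, calib_sim = calib_sim,
                 anchor = anchor, mw_grid = mw_grid),
            class = "pipeline_config")
}

#' Read pipeline options from a YAML file
#'
#' Recognised top-level keys (all optional): `outdir`, `seed`, `fluences`,
#' `cells_per_condition`, `jitter_sd`, `noise_sd`, `threshold`, `k_sigma`,
#' `confirm_frames`, `pore_half_angle`, `domain_radius`, `n_particles`,
#' `n_replicates`, `anchor` (map with `mw`, `time`, `loading`), `mw_grid`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  tr <- trace_spec(noise_sd = y$noise_sd %||% 0)
  design <- experiment_design(
    fluences = y$fluences %||% c(0.064, 0.32, 0.64, 0.96, 1.28, 1.6),
    cells_per_condition = y$cells_per_condition %||% 10L,
    jitter_sd = y$jitter_sd %||% 0.1, trace = tr)
  cell <- cell_model(
    domain_radius = y$domain_radius %||% 5,
    pores = list(pore_spec(angular_radius = y$pore_half_angle %||% 0.2)))
  sim <- sim_params(n_particles = y$n_particles %||% 5000L,
                    n_replicates = y$n_replicates %||% 10L)
  anchor <- y$anchor %||% list(mw = 10, time = 88.7, loading = 0.229)
  pipeline_config(outdir = y$outdir %||% tempfile("optopore_run_"),
                  seed = y$seed %||% 1L, design = design,
                  threshold = y$threshold %||% 0.9,
                  k_sigma = y$k_sigma %||% 5,
                  confirm_frames = y$confirm_frames %||% 3L,
                  cell = cell, sim = sim, anchor = anchor,
                  mw_grid = y$mw_grid %||% c(5, 10, 40, 70, 100))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fit_json <- function(fit, path) {
  m <- fit$model
  jsonlite::write_json(list(form = m$form, a = m$a, b = m$b, c = m$c,
                            r_squared = fit$r_squared, n = fit$n_points,
                            converged = fit$converged,
                            degenerate = fit$degenerate),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stage_file <- function(config, name) file.path(config$outdir, name)

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) generate the synthetic experiment with known
#' ground truth; (2) extract perforation calls and resealing times from
#' every trace; (3) fit the fluence-to-resealing-time growth calibration;
#' (4) calibrate the Monte Carlo step scale against the anchor; (5) run the
#' loading-versus-resealing-time and loading-versus-MW Monte Carlo curves
#' and fit their exponential forms; (6) compare a simulated curve against
#' an independently seeded "measured" replicate set (the synthetic stand-in
#' for flow-cytometry loading) by ordinary least squares. All intermediates
#' are written to `config$outdir`; a manifest with MD5 checksums makes each
#' stage re-runnable standalone.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # stage 1: synthetic experiment ------------------------------------------
  experiment <- run_stage("simulate-data", function() {
    design <- config$design
    design$seed <- derive_seed(config$seed, "design")
    make_experiment(design)
  })
  truth_path <- stage_file(config, "truth.csv")
  write.csv(experiment$truth, truth_path, row.names = FALSE)

  # stage 2: trace processing ----------------------------------------------
  results <- run_stage("extract", function() {
    analyze_traces(experiment$traces, threshold = config$threshold,
                   k_sigma = config$k_sigma,
                   confirm_frames = config$confirm_frames)
  })
  results$fluence_J_cm2 <- experiment$truth$fluence_J_cm2
  results_path <- stage_file(config, "trace_results.csv")
  write.csv(results, results_path, row.names = FALSE)

  # stage 3: fluence -> resealing calibration ------------------------------
  fr <- run_stage("fit-fluence", function() {
    ok <- results$perforated & !is.na(results$resealing_time_s)
    agg <- aggregate(resealing_time_s ~ fluence_J_cm2, data = results[ok, ],
                     FUN = mean)
    list(fit = fit_exp_growth(agg$fluence_J_cm2, agg$resealing_time_s),
         means = agg)
  })
  write.csv(fr$means, stage_file(config, "fluence_resealing.csv"),
            row.names = FALSE)
  write_fit_json(fr$fit, stage_file(config, "fit_fluence_resealing.json"))

  # stage 4: step-scale calibration ----------------------------------------
  s_ref <- run_stage("calibrate", function() {
    calib <- config$calib_sim
    calib$seed <- derive_seed(config$seed, "calibration")
    calibrate_step(config$anchor$mw, config$anchor$time,
                   config$anchor$loading, config$cell, calib,
                   M_ref = config$anchor$mw)
  })

  # stage 5: Monte Carlo loading curves and their fits ----------------------
  sim <- config$sim
  sim$seed <- derive_seed(config$seed, "mc")
  mol <- molecule_spec(config$anchor$mw, M_ref = config$anchor$mw, s_ref = s_ref)
  lvt <- run_stage("mc-time", function() {
    loading_vs_time(fr$means$resealing_time_s, mol, config$cell, sim)
  })
  lvm <- run_stage("mc-mw", function() {
    loading_vs_mw(config$mw_grid, config$anchor$time, config$cell, sim,
                  M_ref = config$anchor$mw, s_ref = s_ref)
  })
  write.csv(lvt, stage_file(config, "loading_vs_time.csv"), row.names = FALSE)
  write.csv(lvm, stage_file(config, "loading_vs_mw.csv"), row.names = FALSE)
  zero_curve <- function(v) diff(range(v)) == 0
  fit_time <- fit_exp_growth(lvt$open_time_s, lvt$loading_mean)
  fit_mw <- fit_exp_decay(lvm$mw_kDa, lvm$loading_mean)
  write_fit_json(fit_time, stage_file(config, "fit_loading_vs_time.json"))
  write_fit_json(fit_mw, stage_file(config, "fit_loading_vs_mw.json"))

  # stage 6: concordance against independently seeded "measurements" --------
  conc <- run_stage("concordance", function() {
    sim_meas <- config$sim
    sim_meas$seed <- derive_seed(config$seed, "measurement")
    meas_t <- loading_vs_time(fr$means$resealing_time_s, mol, config$cell, sim_meas)
    meas_m <- loading_vs_mw(config$mw_grid, config$anchor$time, config$cell,
                            sim_meas, M_ref = config$anchor$mw, s_ref = s_ref)
    degenerate <- zero_curve(lvt$loading_mean) || zero_curve(lvm$loading_mean)
    list(
      time = if (degenerate) NULL else concordance(lvt$loading_mean, meas_t$loading_mean),
      mw = if (degenerate) NULL else concordance(lvm$loading_mean, meas_m$loading_mean),
      measured_time = meas_t, measured_mw = meas_m)
  })
  write.csv(cbind(conc$measured_time,
                  simulated = lvt$loading_mean),
            stage_file(config, "concordance_time.csv"), row.names = FALSE)
  write.csv(cbind(conc$measured_mw,
                  simulated = lvm$loading_mean),
            stage_file(config, "concordance_mw.csv"), row.names = FALSE)

  files <- c("truth.csv", "trace_results.csv", "fluence_resealing.csv",
             "fit_fluence_resealing.json", "loading_vs_time.csv",
             "loading_vs_mw.csv", "fit_loading_vs_time.json",
             "fit_loading_vs_mw.json", "concordance_time.csv",
             "concordance_mw.csv")
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(config$outdir, files))))
  write.csv(manifest, stage_file(config, "manifest.csv"), row.names = FALSE)

  structure(list(config = config, s_ref = s_ref,
                 fluence_fit = fr$fit, fluence_means = fr$means,
                 loading_time = lvt, loading_mw = lvm,
                 fit_time = fit_time, fit_mw = fit_mw,
                 concordance = conc[c("time", "mw")],
                 manifest = manifest),
            class = "pipeline_report")
}

#' Summary tables from a pipeline report
#'
#' Emits the four calibration/concordance tables (fluence versus resealing
#' time, loading versus resealing time, loading versus molecular weight,
#' simulated versus measured loading) plus a Markdown summary.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (defaults to the run's output directory).
#' @return Invisibly, the named vector of written file paths.
#' @export
report_tables <- function(report, dir = report$config$outdir) {
  stopifnot(inherits(report, "pipeline_report"))
  for (part in c("fluence_means", "loading_time", "loading_mw"))
    if (is.null(report[[part]])) stop(sprintf("report is missing stage output '%s'", part))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fluence = file.path(dir, "table_fluence_resealing.csv"),
    time = file.path(dir, "table_loading_vs_time.csv"),
    mw = file.path(dir, "table_loading_vs_mw.csv"),
    concordance = file.path(dir, "table_concordance.csv"))
  write.csv(report$fluence_means, paths["fluence"], row.names = FALSE)
  write.csv(report$loading_time, paths["time"], row.names = FALSE)
  write.csv(report$loading_mw, paths["mw"], row.names = FALSE)
  conc_rows <- do.call(rbind, lapply(names(report$concordance), function(nm) {
    cc <- report$concordance[[nm]]
    if (is.null(cc)) return(NULL)
    data.frame(curve = nm, slope = cc$slope, intercept = cc$intercept,
               r_squared = cc$r_squared, n = cc$n)
  }))
  if (is.null(conc_rows))
    conc_rows <- data.frame(curve = character(), slope = numeric(),
                            intercept = numeric(), r_squared = numeric(),
                            n = integer())
  write.csv(conc_rows, paths["concordance"], row.names = FALSE)

  md <- file.path(dir, "report.md")
  fm <- function(f) sprintf("y = %.4g * exp(%sx / %.4g) + %.4g  (R^2 = %.4f)",
                            f$model$a, if (f$model$form == "decay") "-" else "",
                            f$model$b, f$model$c, f$r_squared)
  lines <- c("# Photoporation pipeline summary", "",
             sprintf("- Calibrated step scale s_ref: %.5g (cell radii / sqrt s)", report$s_ref),
             sprintf("- Fluence -> resealing time: %s", fm(report$fluence_fit)),
             sprintf("- Resealing time -> loading: %s", fm(report$fit_time)),
             sprintf("- Molecular weight -> loading: %s", fm(report$fit_mw)))
  for (nm in names(report$concordance)) {
    cc <- report$concordance[[nm]]
    if (!is.null(cc))
      lines <- c(lines, sprintf(
        "- Concordance (%s curve): slope %.4f, intercept %.4f, R^2 %.4f",
        nm, cc$slope, cc$intercept, cc$r_squared))
  }
  writeLines(lines, md)
  invisible(c(paths, report = md))
}
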