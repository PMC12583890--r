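#' Configuration for a full pipeline run
#'
#' Bundles everything a run needs: the study design and ground truth (or a
#' path to a raw trial CSV to ingest instead of simulating), the sampler
#' settings, growth-model options, seed and output directory. Every
#' stochastic stage derives its own seed from `seed`, so a configuration
#' reproduces a run exactly.
#'
#' @param design A [vas_design()].
#' @param truth A [vas_truth()] (ignored in ingest mode).
#' @param fit_spec A [vas_fit_spec()]; its `seed` is overridden per year from
#'   `seed`.
#' @param seed Master integer seed.
#' @param output_dir Directory for all artifacts.
#' @param input_csv Optional path to a raw trial CSV; when given, ingestion
#'   replaces simulation.
#' @param attrition_rate Per-participant-year missingness for simulation.
#' @param screen_lower,screen_upper Validity-screen criteria.
#' @param screen_per_continuum Screen within each continuum instead of pooled.
#' @param df_method Degrees-of-freedom convention for growth models.
#' @return A list of class `vas_config`.
#' @export
vas_config <- function(design = vas_design(), truth = vas_truth(),
                       fit_spec = vas_fit_spec(), seed = 1L,
                       output_dir = tempfile("vascat_run_"),
                       input_csv = NULL, attrition_rate = 0.015,
                       screen_lower = 25, screen_upper = 75,
                       screen_per_continuum = FALSE,
                       df_method = "residual") {
  structure(list(design = design, truth = truth, fit_spec = fit_spec,
                 seed = as.integer(seed), output_dir = output_dir,
                 input_csv = input_csv, attrition_rate = attrition_rate,
                 screen_lower = screen_lower, screen_upper = screen_upper,
                 screen_per_continuum = screen_per_continuum,
                 df_method = df_method),
            class = "vas_config")
}

pipeline_log <- function(quiet, ...) {
  if (!quiet) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
}

#' Run the full VAS analysis pipeline
#'
#' Executes simulate (or ingest) -> orientation normalization -> validity
#' screening -> per-year hierarchical psychometric fits -> subject indices ->
#' growth-curve models for Slope and Response Variability -> practice-effect
#' contrasts, writing every intermediate artifact as plain text under
#' `config$output_dir` and returning a manifest with seeds, diagnostics and
#' md5 checksums of all artifacts. A stage failure aborts with the stage name.
#'
#' @param config A [vas_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = vas_config(), quiet = FALSE) {
  stopifnot(inherits(config, "vas_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  artifacts <- character()
  add <- function(path) artifacts <<- c(artifacts, path)

  # 1. simulate or ingest ------------------------------------------------
  truth_table <- NULL
  if (is.null(config$input_csv)) {
    pipeline_log(quiet, "simulating study (seed %d)", config$seed)
    study <- stage("simulate", simulate_study(config$design, config$truth,
                                              seed = config$seed,
                                              attrition_rate = config$attrition_rate))
    trials <- study$trials
    truth_table <- study$truth_table
    paths <- write_study(study, config$output_dir)
    for (p in paths) add(p)
  } else {
    pipeline_log(quiet, "ingesting %s", config$input_csv)
    trials <- stage("ingest", read_trials(config$input_csv))
  }

  # 2. preprocess ---------------------------------------------------------
  pipeline_log(quiet, "normalizing orientation and screening")
  clean <- stage("normalize", normalize_orientation(trials))
  screen <- stage("screen", screen_subject_years(
    clean, lower = config$screen_lower, upper = config$screen_upper,
    per_continuum = config$screen_per_continuum))
  p <- file.path(config$output_dir, "screen_report.csv")
  utils::write.csv(screen, p, row.names = FALSE); add(p)

  # 3. per-year hierarchical fits ------------------------------------------
  years <- sort(unique(clean$testing_year))
  indices <- list()
  fit_diag <- list()
  convergence_clean <- TRUE
  for (yr in years) {
    pipeline_log(quiet, "fitting hierarchical model, year %d", yr)
    spec <- config$fit_spec
    spec$seed <- config$seed + 101L * yr
    dat <- stage(sprintf("assemble_year_%d", yr),
                 assemble_year_dataset(clean, screen, yr))
    fit <- stage(sprintf("fit_year_%d", yr), {
      withCallingHandlers(
        fit_year(dat, spec),
        warning = function(w) {
          convergence_clean <<- FALSE
          pipeline_log(quiet, "year %d: %s", yr, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    })
    p <- file.path(config$output_dir, sprintf("posterior_year%d.csv", yr))
    utils::write.csv(fit$summary, p, row.names = FALSE); add(p)
    indices[[as.character(yr)]] <- extract_subject_indices(fit)
    fit_diag[[as.character(yr)]] <- fit$diagnostics[c("max_rhat", "min_ess",
                                                      "converged")]
  }
  indices <- do.call(rbind, indices)
  rownames(indices) <- NULL
  p <- file.path(config$output_dir, "subject_indices.csv")
  utils::write.csv(indices, p, row.names = FALSE); add(p)

  # 4. growth models --------------------------------------------------------
  growth <- list()
  for (outcome in c("slope_hat", "rv_hat")) {
    pipeline_log(quiet, "growth model for %s", outcome)
    gd <- stage(paste0("growth_data_", outcome),
                build_growth_dataset(indices, outcome))
    gf <- stage(paste0("growth_fit_", outcome),
                fit_growth_model(gd, df_method = config$df_method))
    p <- file.path(config$output_dir, sprintf("growth_%s.csv", outcome))
    growth_fit_to_csv(gf, p); add(p)
    preds <- marginal_predictions(gf, years = seq_len(config$design$years),
                                  grades = config$design$cohorts)
    p <- file.path(config$output_dir, sprintf("predictions_%s.csv", outcome))
    utils::write.csv(preds, p, row.names = FALSE); add(p)
    growth[[outcome]] <- gf
  }

  # 5. practice contrasts ----------------------------------------------------
  contrasts <- lapply(c(slope_hat = "slope_hat", rv_hat = "rv_hat"),
                      function(o) {
    tryCatch(first_session_contrast(indices, o), error = function(e) NULL)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("vascat")),
    seed = config$seed,
    output_dir = config$output_dir,
    mode = if (is.null(config$input_csv)) "simulate" else "ingest",
    n_trials = nrow(trials),
    n_participant_years = nrow(screen),
    n_kept = sum(screen$kept),
    fit_diagnostics = fit_diag,
    convergence_clean = convergence_clean,
    growth = lapply(growth, function(g)
      list(coefficients = g$coefficients, meta = g$meta[c("structure",
                                                          "converged",
                                                          "singular")])),
    practice_contrast = contrasts,
    has_ground_truth = !is.null(truth_table),
    checksums = as.list(tools::md5sum(artifacts))
  )
  p <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest$indices <- indices
  manifest$growth_fits <- growth
  class(manifest) <- "vas_manifest"
  pipeline_log(quiet, "done: %s", config$output_dir)
  invisible(manifest)
}

growth_signs <- function(gf) {
  cf <- gf$coefficients
  stats::setNames(sign(cf$B), cf$term)
}

#' Generate a plain-text + figure report for a completed run
#'
#' Produces trajectory and mean-function figures, echoes both growth-model
#' coefficient tables, and writes a plain-text summary of the recovered
#' effect signs. When the run simulated its own data, recovered signs are
#' compared with the generator truth and disagreements are flagged. Missing
#' artifacts are listed and a partial report is still produced.
#'
#' @param manifest A `vas_manifest` from [run_pipeline()], or the path of a
#'   run directory.
#' @param truth The [vas_truth()] used for simulation (for sign comparison);
#'   `NULL` disables the comparison.
#' @return Invisibly, a list with the report path and figure paths.
#' @export
make_report <- function(manifest, truth = vas_truth()) {
  dir <- if (is.character(manifest)) manifest else manifest$output_dir
  need <- c(trials = "trials.csv", indices = "subject_indices.csv",
            gslope = "growth_slope_hat.csv", grv = "growth_rv_hat.csv",
            pslope = "predictions_slope_hat.csv",
            prv = "predictions_rv_hat.csv")
  paths <- file.path(dir, need)
  names(paths) <- names(need)
  missing <- paths[!file.exists(paths)]
  lines <- c("# VAS categorization pipeline report", "")
  if (length(missing)) {
    lines <- c(lines, "Missing artifacts (partial report):",
               paste(" -", basename(missing)), "")
  }
  figures <- character()

  if (file.exists(paths["trials"]) && file.exists(file.path(dir, "screen_report.csv"))) {
    trials <- normalize_orientation(read_trials(paths["trials"]))
    trials$grade <- trials$start_grade + trials$testing_year - 1
    agg <- stats::aggregate(vas_score ~ step + grade, data = trials, FUN = mean)
    fig <- file.path(dir, "fig_mean_functions.png")
    grDevices::png(fig, width = 900, height = 600, res = 120)
    print(ggplot2::ggplot(agg, ggplot2::aes(x = step, y = vas_score,
                                            color = factor(grade))) +
            ggplot2::geom_line() + ggplot2::geom_point() +
            ggplot2::labs(x = "continuum step", y = "mean VAS score",
                          color = "grade",
                          title = "Mean categorization function by grade"))
    grDevices::dev.off()
    figures <- c(figures, fig)
  }
  for (oc in c("slope_hat", "rv_hat")) {
    pfile <- file.path(dir, sprintf("predictions_%s.csv", oc))
    if (!file.exists(pfile)) next
    preds <- utils::read.csv(pfile)
    fig <- file.path(dir, sprintf("fig_trajectory_%s.png", oc))
    grDevices::png(fig, width = 900, height = 600, res = 120)
    print(ggplot2::ggplot(preds, ggplot2::aes(x = testing_year, y = predicted,
                                              color = factor(start_grade))) +
            ggplot2::geom_line() +
            ggplot2::geom_ribbon(ggplot2::aes(ymin = CI_low, ymax = CI_high,
                                              fill = factor(start_grade)),
                                 alpha = 0.15, color = NA) +
            ggplot2::labs(x = "testing year", y = oc, color = "start grade",
                          fill = "start grade",
                          title = sprintf("Predicted %s trajectories by cohort",
                                          oc)))
    grDevices::dev.off()
    figures <- c(figures, fig)
  }

  expected <- list(
    slope_hat = c(year_c = sign(truth$s_year), grade_c = sign(truth$s_grade),
                  inter = sign(truth$s_year_grade)),
    rv_hat = c(year_c = sign(truth$rv_year), grade_c = sign(truth$rv_grade),
               inter = sign(truth$rv_year_grade))
  )
  for (oc in c("slope_hat", "rv_hat")) {
    gfile <- file.path(dir, sprintf("growth_%s.csv", oc))
    if (!file.exists(gfile)) next
    cf <- utils::read.csv(gfile)
    lines <- c(lines, sprintf("## Growth model: %s", oc), "",
               utils::capture.output(print(cf, digits = 3)), "")
    if (!is.null(truth)) {
      for (term in c("year_c", "grade_c", "inter")) {
        got <- sign(cf$B[cf$term == term])
        want <- expected[[oc]][[term]]
        tag <- if (length(got) == 1 && got == want) "agrees with" else
          "DISAGREES with"
        lines <- c(lines, sprintf("sign of %s effect on %s %s generator truth",
                                  term, oc, tag))
      }
      lines <- c(lines, "")
    }
  }
  lines <- c(lines, sprintf("Figures: %d", length(figures)),
             paste(" -", basename(figures)))
  report <- file.path(dir, "report.md")
  writeLines(lines, report)
  invisible(list(report = report, figures = figures))
}
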