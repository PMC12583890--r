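# CSV dialect: UTF-8, comma separator, header row, "." decimal; steps are
# 1-based integers. All artifacts are plain text so runs are diffable.

#' Write a synthetic study to disk
#'
#' Writes the raw trial table, the latent ground-truth table and a JSON
#' sidecar recording the design, the population truth and the seed, so a
#' study can be regenerated or ingested exactly.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "vas_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trials = file.path(dir, "trials.csv"),
             truth = file.path(dir, "ground_truth.csv"),
             sidecar = file.path(dir, "study.json"))
  trials <- study$trials
  # 17 significant digits guarantee an exact numeric round-trip through text
  trials$raw_rating <- sprintf("%.17g", trials$raw_rating)
  utils::write.csv(trials, paths["trials"], row.names = FALSE)
  utils::write.csv(study$truth_table, paths["truth"], row.names = FALSE)
  sidecar <- list(design = unclass(study$design),
                  truth = unclass(study$truth),
                  seed = study$seed, attrition_rate = study$attrition_rate)
  jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a raw VAS trial table
#'
#' Reads a delimited trial file in the package's column layout
#' (`subject_id`, `start_grade`, `testing_year`, `day`, `continuum_id`,
#' `step`, `raw_rating`, `flipped`) and validates ranges.
#'
#' @param path CSV file path.
#' @return Data frame of trials.
#' @export
read_trials <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "start_grade", "testing_year", "day",
              "continuum_id", "step", "raw_rating", "flipped")
  missing <- setdiff(needed, names(d))
  if (length(missing)) {
    stop("trial file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  d$flipped <- as.logical(d$flipped)
  if (any(d$raw_rating < 0 | d$raw_rating > 100)) {
    stop("raw ratings outside [0, 100] in ", path, call. = FALSE)
  }
  d
}

growth_fit_to_csv <- function(fit, path) {
  utils::write.csv(fit$coefficients, path, row.names = FALSE)
  invisible(path)
}
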