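# Generator internals ---------------------------------------------------------

# Time-invariant latent quantities for one subject: deviations of the four
# curve parameters, an idiosyncratic per-year slope trend, and the RV level
# and per-year RV trend (both log scale). U > L is enforced by resampling.
draw_subject_latents <- function(truth, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    bL <- stats::rnorm(1, 0, truth$L_sd)
    bU <- stats::rnorm(1, 0, truth$U_sd)
    if (truth$U_mean + bU > truth$L_mean + bL) {
      return(list(
        bL = bL, bU = bU,
        bc = stats::rnorm(1, 0, truth$c_sd),
        bs = stats::rnorm(1, 0, truth$s_sd),
        g_s = stats::rnorm(1, 0, truth$s_yearslope_sd),
        r_rv = stats::rnorm(1, 0, truth$rv_subject_sd),
        k_rv = stats::rnorm(1, 0, truth$rv_yearslope_sd)
      ))
    }
  }
  stop("could not draw asymptotes with U > L within the resampling budget",
       call. = FALSE)
}

# Deterministic map from subject latents + design coordinates to that
# subject-year's psychometric parameters. RV trends are linear on the variance
# scale (floored away from zero), subject RV heterogeneity is multiplicative.
subject_params_at <- function(latents, truth, start_grade, testing_year,
                              design) {
  rv_floor <- min(if (is.null(truth$rv_floor)) 20 else truth$rv_floor,
                  truth$rv_mean)
  yc <- center_year(testing_year, design)
  gc <- center_grade(start_grade, design)
  slope <- truth$s_mean + latents$bs + truth$s_grade * gc +
    (truth$s_year + truth$s_year_grade * gc + latents$g_s) * yc
  rv_det <- truth$rv_mean + truth$rv_year * yc + truth$rv_grade * gc +
    truth$rv_year_grade * yc * gc
  rv <- max(rv_floor, rv_det) * exp(latents$r_rv + latents$k_rv * yc)
  steps <- seq_len(design$steps)
  out <- list(
    L = truth$L_mean + latents$bL,
    U = truth$U_mean + latents$bU,
    crossover = truth$c_mean + latents$bc,
    slope = slope,
    theta = log(rv / truth$rv_mean),
    rv = rv,
    w0 = truth_w0(truth, steps), w1 = truth$w1, w2 = truth$w2,
    mid = mid_step(design)
  )
  class(out) <- "psychometric_params"
  out
}

# Public operations ------------------------------------------------------------

#' Draw one subject-year's psychometric parameters from the population
#'
#' Samples a subject's latent deviations from the ground-truth populations and
#' applies the developmental trends for the requested start grade and testing
#' year. The returned object carries the four logistic parameters, the
#' subject's variance intercept `theta`, the implied step-averaged response
#' variability `rv`, and the population variance-profile coefficients needed
#' to simulate trials.
#'
#' @param truth A [vas_truth()] object.
#' @param start_grade Cohort start grade.
#' @param testing_year Testing year (1-based).
#' @param seed Optional integer seed.
#' @param design A [vas_design()] supplying centering constants and steps.
#' @return A `psychometric_params` list.
#' @export
draw_subject_params <- function(truth, start_grade, testing_year, seed = NULL,
                                design = vas_design()) {
  stopifnot(inherits(truth, "vas_truth"), inherits(design, "vas_design"))
  if (!is.null(seed)) set.seed(seed)
  latents <- draw_subject_latents(truth)
  subject_params_at(latents, truth, start_grade, testing_year, design)
}

#' Simulate a single VAS trial
#'
#' Draws one raw rating: the 4PL mean at the step plus zero-mean Gaussian
#' noise whose variance follows the subject's log-quadratic profile, clipped
#' to the physical 0-100 scale. For orientation-flipped blocks the recorded
#' (raw) rating is `100 - rating`, mimicking un-normalized session files.
#'
#' @param params A `psychometric_params` object (see [draw_subject_params()]).
#' @param step Continuum step (scalar or vector).
#' @param flipped Logical (recycled): was this block orientation-flipped?
#' @param seed Optional integer seed.
#' @return Numeric vector of raw ratings in \[0, 100\].
#' @export
simulate_trial <- function(params, step, flipped = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fourpl_mean(step, params$L, params$U, params$crossover, params$slope)
  s2 <- trial_sigma2(step, params$w0, params$w1, params$w2,
                     theta = params$theta, mid = params$mid)
  y <- pmin(100, pmax(0, mu + stats::rnorm(length(mu), 0, sqrt(s2))))
  ifelse(rep_len(flipped, length(y)), 100 - y, y)
}

#' Simulate a complete accelerated-longitudinal VAS study
#'
#' Generates raw trial records for every subject, cohort and testing year of a
#' design, together with the latent per-subject-year parameter table that
#' downstream stages are evaluated against. Item (continuum) random effects on
#' the four curve parameters are drawn once per study. Participant-years can
#' be dropped completely at random to mimic year-specific exclusions.
#'
#' @param design A [vas_design()] object.
#' @param truth A [vas_truth()] object.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param attrition_rate Probability that any participant-year is missing.
#' @return An object of class `vas_study`: a list with `trials` (one row per
#'   trial: `subject_id`, `start_grade`, `testing_year`, `day`,
#'   `continuum_id`, `step`, `raw_rating`, `flipped`), `truth_table` (one row
#'   per realized participant-year with the latent parameters), and
#'   `item_effects`.
#' @export
simulate_study <- function(design = vas_design(), truth = vas_truth(),
                           seed = 1L, attrition_rate = 0.015) {
  stopifnot(inherits(design, "vas_design"), inherits(truth, "vas_truth"))
  set.seed(seed)
  n_item <- length(design$continua)
  item_effects <- cbind(
    L = stats::rnorm(n_item, 0, truth$item_sd[["L"]]),
    U = stats::rnorm(n_item, 0, truth$item_sd[["U"]]),
    crossover = stats::rnorm(n_item, 0, truth$item_sd[["crossover"]]),
    slope = stats::rnorm(n_item, 0, truth$item_sd[["slope"]])
  )
  rownames(item_effects) <- design$continua

  trial_chunks <- list()
  truth_rows <- list()
  k <- 0L
  for (grade in design$cohorts) {
    for (i in seq_len(design$subjects_per_cohort)) {
      sid <- sprintf("g%d_s%03d", grade, i)
      latents <- draw_subject_latents(truth)
      for (year in seq_len(design$years)) {
        missing_year <- stats::runif(1) < attrition_rate
        grid_seed <- sample.int(.Machine$integer.max, 1)
        if (missing_year) next
        pars <- subject_params_at(latents, truth, grade, year, design)
        grid <- build_design(design, seed = grid_seed)
        ie <- item_effects[grid$continuum_id, , drop = FALSE]
        mu <- fourpl_mean(grid$step, pars$L + ie[, "L"], pars$U + ie[, "U"],
                          pars$crossover + ie[, "crossover"],
                          pars$slope + ie[, "slope"])
        s2 <- trial_sigma2(grid$step, pars$w0, pars$w1, pars$w2,
                           theta = pars$theta, mid = pars$mid)
        y <- pmin(100, pmax(0, mu + stats::rnorm(nrow(grid), 0, sqrt(s2))))
        raw <- ifelse(grid$flipped, 100 - y, y)
        k <- k + 1L
        trial_chunks[[k]] <- data.frame(
          subject_id = sid, start_grade = grade, testing_year = year,
          day = grid$day, continuum_id = grid$continuum_id, step = grid$step,
          raw_rating = raw, flipped = grid$flipped, stringsAsFactors = FALSE
        )
        truth_rows[[k]] <- data.frame(
          subject_id = sid, start_grade = grade, testing_year = year,
          L = pars$L, U = pars$U, crossover = pars$crossover,
          slope = pars$slope, theta = pars$theta, rv = pars$rv,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L) stop("attrition removed every participant-year", call. = FALSE)
  trials <- do.call(rbind, trial_chunks)
  rownames(trials) <- NULL
  truth_table <- do.call(rbind, truth_rows)
  rownames(truth_table) <- NULL
  structure(
    list(trials = trials, truth_table = truth_table,
         item_effects = item_effects, design = design, truth = truth,
         seed = seed, attrition_rate = attrition_rate,
         w0 = truth_w0(truth, seq_len(design$steps)), mid = mid_step(design)),
    class = "vas_study"
  )
}

#' @export
print.vas_study <- function(x, ...) {
  cat("Synthetic VAS study:", nrow(x$trials), "trials,",
      nrow(x$truth_table), "participant-years,",
      length(unique(x$trials$subject_id)), "subjects\n")
  invisible(x)
}
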