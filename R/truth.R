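#' Population ground truth for the synthetic-study generator
#'
#' Collects every latent quantity the generator needs: population means and
#' between-subject SDs of the four logistic parameters, item (continuum)
#' random-effect SDs, the shape of the log-variance quadratic, the scale and
#' spread of subjects' response variability (RV), and the developmental trends
#' that downstream growth-curve models are supposed to recover.
#'
#' Trends are parameterized on the scales the growth models use: the slope
#' trend in VAS/step per centered testing year and per centered start grade,
#' and the RV trend in squared-VAS units per centered year/grade. Default
#' trend magnitudes are the headline longitudinal estimates this package is
#' designed to recover (slope: year -1.39, grade +2.42, interaction -0.81;
#' RV: year -26.08, grade -36.78, interaction +26.52). Remaining defaults are
#' realistic for school-age children on a 0-100 VAS with a 7-step continuum:
#' asymptotes near but not at the scale edges, crossover mid-continuum,
#' average slope ~20 VAS/step, and mid-continuum trial SDs near 20 VAS points
#' (RV near 320).
#'
#' @param L_mean,L_sd Population mean/SD of the lower asymptote (VAS units).
#' @param U_mean,U_sd Population mean/SD of the upper asymptote.
#' @param c_mean,c_sd Population mean/SD of the crossover (step units).
#' @param s_mean,s_sd Population mean/SD of the slope at the crossover
#'   (VAS/step).
#' @param item_sd Named numeric vector of item random-effect SDs for
#'   `L`, `U`, `crossover`, `slope`.
#' @param w1,w2 Linear and quadratic coefficients of the log trial-variance
#'   profile in (step - mid). `w2 < 0` makes mid-continuum trials noisiest.
#' @param rv_mean Median step-averaged trial variance (squared VAS units) at
#'   the grand mean of year and grade.
#' @param rv_subject_sd Between-subject SD of the RV intercept, log scale.
#' @param s_year,s_grade,s_year_grade Slope trends per centered year, centered
#'   grade, and their interaction (VAS/step per unit).
#' @param s_yearslope_sd Between-subject SD of the per-year slope trend.
#' @param rv_year,rv_grade,rv_year_grade RV trends (squared-VAS units per
#'   centered year/grade and interaction).
#' @param rv_yearslope_sd Between-subject SD of the per-year RV trend, log
#'   scale.
#' @param rv_floor Lower bound (squared VAS units) applied to the
#'   deterministic RV trend surface so linear trends can never produce a
#'   non-positive variance target.
#' @return An object of class `vas_truth`.
#' @export
vas_truth <- function(L_mean = 8, L_sd = 5,
                      U_mean = 92, U_sd = 5,
                      c_mean = 4, c_sd = 0.5,
                      s_mean = 20, s_sd = 6,
                      item_sd = c(L = 3, U = 3, crossover = 0.3, slope = 2),
                      w1 = 0, w2 = -0.155,
                      rv_mean = 320, rv_subject_sd = 0.4,
                      s_year = -1.39, s_grade = 2.42, s_year_grade = -0.81,
                      s_yearslope_sd = 1.5,
                      rv_year = -26.08, rv_grade = -36.78,
                      rv_year_grade = 26.52,
                      rv_yearslope_sd = 0.03,
                      rv_floor = 20) {
  sds <- c(L_sd, U_sd, c_sd, s_sd, item_sd, rv_subject_sd, s_yearslope_sd,
           rv_yearslope_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (U_mean <= L_mean) stop("U_mean must exceed L_mean", call. = FALSE)
  if (rv_mean <= 0) stop("rv_mean must be positive", call. = FALSE)
  if (rv_floor <= 0) stop("rv_floor must be positive", call. = FALSE)
  stopifnot(all(c("L", "U", "crossover", "slope") %in% names(item_sd)))
  structure(
    list(L_mean = L_mean, L_sd = L_sd, U_mean = U_mean, U_sd = U_sd,
         c_mean = c_mean, c_sd = c_sd, s_mean = s_mean, s_sd = s_sd,
         item_sd = item_sd, w1 = w1, w2 = w2,
         rv_mean = rv_mean, rv_subject_sd = rv_subject_sd,
         s_year = s_year, s_grade = s_grade, s_year_grade = s_year_grade,
         s_yearslope_sd = s_yearslope_sd,
         rv_year = rv_year, rv_grade = rv_grade,
         rv_year_grade = rv_year_grade, rv_yearslope_sd = rv_yearslope_sd,
         rv_floor = rv_floor),
    class = "vas_truth"
  )
}

#' @export
print.vas_truth <- function(x, ...) {
  cat("VAS population ground truth:\n")
  cat(sprintf("  4PL: L %.1f (SD %.1f), U %.1f (SD %.1f), c %.2f (SD %.2f), s %.1f (SD %.1f)\n",
              x$L_mean, x$L_sd, x$U_mean, x$U_sd, x$c_mean, x$c_sd,
              x$s_mean, x$s_sd))
  cat(sprintf("  RV: median %.0f (log-SD %.2f); variance quadratic w1 %.2f, w2 %.3f\n",
              x$rv_mean, x$rv_subject_sd, x$w1, x$w2))
  cat(sprintf("  slope trends: year %.2f, grade %.2f, year x grade %.2f\n",
              x$s_year, x$s_grade, x$s_year_grade))
  cat(sprintf("  RV trends:    year %.2f, grade %.2f, year x grade %.2f\n",
              x$rv_year, x$rv_grade, x$rv_year_grade))
  invisible(x)
}

#' Population log-variance intercept implied by the RV scale
#'
#' Converts the ground-truth RV scale (`rv_mean`, a step-averaged variance)
#' into the population intercept `w0` of the log-variance quadratic, such that
#' a subject with variance intercept `theta = 0` has a step-averaged trial
#' variance exactly `rv_mean`.
#'
#' @param truth A [vas_truth()] object.
#' @param steps Integer vector of continuum steps (default `1:7`).
#' @return Scalar `w0`.
#' @export
truth_w0 <- function(truth, steps = 1:7) {
  mid <- (min(steps) + max(steps)) / 2
  d <- steps - mid
  log(truth$rv_mean) - log(mean(exp(truth$w1 * d + truth$w2 * d^2)))
}

# Centered design coordinates used by both the generator and the growth stage.
center_year <- function(year, design) year - (design$years + 1) / 2
center_grade <- function(grade, design) grade - mean(design$cohorts)
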