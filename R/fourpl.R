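#' Four-parameter logistic psychometric function
#'
#' Expected visual analogue scale (VAS) rating at a continuum step under the
#' four-parameter logistic (4PL) used throughout this package. The function is
#' parameterized directly in terms of the derivative at its midpoint, so the
#' quantity the growth-curve stage analyzes ("Slope") is a native parameter
#' rather than a post-hoc transform of a rate constant:
#' \deqn{\mu(x) = L + \frac{U - L}{1 + \exp\{-\frac{4s}{U-L}(x - c)\}}}
#' where \eqn{L} and \eqn{U} are the lower and upper asymptotes (VAS units),
#' \eqn{c} the crossover (step units) and \eqn{s} the slope at the crossover
#' (VAS units per step). By construction \eqn{\mu(c) = (L+U)/2} and
#' \eqn{\mu'(c) = s}.
#'
#' @param step Numeric vector of continuum steps (typically 1--7).
#' @param L,U Lower and upper asymptotes; must satisfy `U > L`.
#' @param crossover Crossover/boundary location in step units.
#' @param slope Derivative of the function at the crossover (VAS per step).
#' @return Numeric vector of expected VAS ratings, strictly between `L` and
#'   `U` when `slope > 0`.
#' @examples
#' fourpl_mean(1:7, L = 0, U = 100, crossover = 4, slope = 25)
#' @export
fourpl_mean <- function(step, L, U, crossover, slope) {
  if (any(!is.finite(c(L, U, crossover, slope)))) {
    stop("4PL parameters must be finite", call. = FALSE)
  }
  if (any(U <= L)) {
    stop("upper asymptote must exceed lower asymptote (U > L)", call. = FALSE)
  }
  k <- 4 * slope / (U - L)
  L + (U - L) / (1 + exp(-k * (step - crossover)))
}

#' Trial-level response variance profile
#'
#' Trial-by-trial response variance is modeled on the log scale as a quadratic
#' in continuum step, centered at the middle of the continuum: responses near
#' the category boundary are necessarily more variable than responses to clear
#' endpoint tokens. A subject-specific intercept `theta` shifts the whole
#' profile up or down (the subject's overall consistency):
#' \deqn{\sigma^2(x) = \exp\{\theta + w_0 + w_1 (x - m) + w_2 (x - m)^2\}}
#'
#' @param step Numeric vector of continuum steps.
#' @param w0,w1,w2 Population coefficients of the log-variance quadratic.
#' @param theta Subject-level variance intercept on the log scale (default 0).
#' @param mid Center of the quadratic in step units; defaults to the middle
#'   step of a 7-step continuum.
#' @return Numeric vector of trial variances (squared VAS units), always > 0.
#' @examples
#' trial_sigma2(1:7, w0 = 5.5, w1 = 0, w2 = -0.15)
#' @export
trial_sigma2 <- function(step, w0, w1, w2, theta = 0, mid = 4) {
  d <- step - mid
  exp(theta + w0 + w1 * d + w2 * d^2)
}

#' Step-averaged response variability index
#'
#' The Response Variability (RV) index for one subject is the trial variance
#' profile averaged over the continuum steps. On this scale 0 means perfectly
#' consistent responding and values of several hundred are possible for noisy
#' responders (a trial SD of ~23 VAS points corresponds to RV near 530).
#'
#' @inheritParams trial_sigma2
#' @param steps Integer vector of steps to average over (default `1:7`).
#' @return Scalar step-averaged variance (squared VAS units).
#' @export
response_variability <- function(w0, w1, w2, theta = 0, steps = 1:7,
                                 mid = (min(steps) + max(steps)) / 2) {
  mean(trial_sigma2(steps, w0, w1, w2, theta = theta, mid = mid))
}

#' Log-likelihood of an assembled year dataset
#'
#' Gaussian observation model used by the hierarchical fit: each trial's VAS
#' score is normal with mean given by the 4PL (population parameters plus the
#' trial's subject and item random intercepts on all four curve parameters)
#' and variance given by the log-quadratic profile (population coefficients
#' plus the subject's variance intercept).
#'
#' @param data A model-ready data frame as produced by
#'   [assemble_year_dataset()], with columns `vas_score`, `step`,
#'   `subject_index` and `item_index` (0-based contiguous codes).
#' @param pars A list with elements `L`, `U`, `crossover`, `slope`, `w0`,
#'   `w1`, `w2` (population scalars), `subject` (matrix with one row per
#'   subject and columns `L`, `U`, `crossover`, `slope`, `theta`) and `item`
#'   (matrix with one row per item and columns `L`, `U`, `crossover`,
#'   `slope`).
#' @param mid Center of the variance quadratic (step units).
#' @return Scalar log-likelihood.
#' @export
vas_loglik <- function(data, pars, mid = 4) {
  si <- data$subject_index + 1L
  ii <- data$item_index + 1L
  sub <- pars$subject
  itm <- pars$item
  L <- pars$L + sub[si, "L"] + itm[ii, "L"]
  U <- pars$U + sub[si, "U"] + itm[ii, "U"]
  cc <- pars$crossover + sub[si, "crossover"] + itm[ii, "crossover"]
  ss <- pars$slope + sub[si, "slope"] + itm[ii, "slope"]
  mu <- fourpl_mean(data$step, L, U, cc, ss)
  s2 <- trial_sigma2(data$step, pars$w0, pars$w1, pars$w2,
                     theta = sub[si, "theta"], mid = mid)
  ll <- stats::dnorm(data$vas_score, mean = mu, sd = sqrt(s2), log = TRUE)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1]
    stop("non-finite log-likelihood at trial index ", bad, call. = FALSE)
  }
  sum(ll)
}
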