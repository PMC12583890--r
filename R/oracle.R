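#' Independent per-subject 4PL fit (nonlinear least squares)
#'
#' Unpenalized Levenberg-Marquardt fit of the same four-parameter logistic to
#' a single subject-year's trials, with homoscedastic residual variance. This
#' deliberately shares no machinery with the hierarchical sampler: it is the
#' independent route used to cross-check hierarchical estimates on data-rich
#' synthetic subjects (expect shrinkage differences on noisy ones).
#'
#' @param trials Data frame with `vas_score` and `step` for one subject-year
#'   (at least 8 trials spanning the continuum).
#' @return A list with `L`, `U`, `crossover`, `slope`, `resid_var`,
#'   `converged`.
#' @export
oracle_subject_fit <- function(trials) {
  stopifnot(all(c("vas_score", "step") %in% names(trials)))
  if (nrow(trials) < 8 || length(unique(trials$step)) < 4) {
    stop("the oracle fit needs >= 8 trials spanning the continuum",
         call. = FALSE)
  }
  sm <- tapply(trials$vas_score, trials$step, mean)
  lo <- min(trials$step); hi <- max(trials$step)
  s_start <- max(1, (max(sm) - min(sm)) / (hi - lo) * 1.5)
  # multi-start on the crossover; keep the solution with the lowest SSE
  fit <- NULL
  for (cc0 in c((lo + hi) / 2, lo + (hi - lo) / 4, hi - (hi - lo) / 4)) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        vas_score ~ L + (U - L) / (1 + exp(-(4 * s / (U - L)) * (step - cc))),
        data = trials,
        start = list(L = min(sm), U = max(sm), cc = cc0, s = s_start),
        lower = c(L = -50, U = -50, cc = lo - 1, s = 0.01),
        upper = c(L = 150, U = 150, cc = hi + 1, s = 200),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    return(list(L = NA_real_, U = NA_real_, crossover = NA_real_,
                slope = NA_real_, resid_var = NA_real_, converged = FALSE))
  }
  cf <- stats::coef(fit)
  list(L = unname(cf["L"]), U = unname(cf["U"]),
       crossover = unname(cf["cc"]), slope = unname(cf["s"]),
       resid_var = sum(stats::resid(fit)^2) / stats::df.residual(fit),
       converged = TRUE)
}
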