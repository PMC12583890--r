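#' Build a growth-curve dataset from subject indices
#'
#' One row per participant-year with the chosen outcome and centered
#' predictors: testing year and start grade are centered at the grand mean of
#' the included rows, and the interaction is the product of the centered
#' predictors.
#'
#' @param indices Data frame of subject indices (e.g. stacked results of
#'   [extract_subject_indices()]) with columns `subject_id`, `testing_year`,
#'   `start_grade` and the outcome.
#' @param outcome Name of the outcome column (`"slope_hat"` or `"rv_hat"`).
#' @return A data frame with columns `subject_id`, `outcome`, `year_c`,
#'   `grade_c`, `inter`, carrying the centering constants as attributes
#'   `year_center` and `grade_center`.
#' @export
build_growth_dataset <- function(indices, outcome = "slope_hat") {
  stopifnot(all(c("subject_id", "testing_year", "start_grade", outcome)
                %in% names(indices)))
  d <- indices[is.finite(indices[[outcome]]), ]
  if (max(table(d$subject_id)) < 2) {
    stop("growth modeling needs at least one subject with >= 2 years",
         call. = FALSE)
  }
  yc <- mean(d$testing_year)
  gc <- mean(d$start_grade)
  out <- data.frame(subject_id = d$subject_id,
                    outcome = d[[outcome]],
                    year_c = d$testing_year - yc,
                    grade_c = d$start_grade - gc,
                    stringsAsFactors = FALSE)
  out$inter <- out$year_c * out$grade_c
  if (stats::sd(out$year_c) == 0 || stats::sd(out$grade_c) == 0) {
    stop("a centered predictor is constant; growth model is not identified",
         call. = FALSE)
  }
  attr(out, "year_center") <- yc
  attr(out, "grade_center") <- gc
  attr(out, "outcome_name") <- outcome
  out
}

# Fit the mixed model with a convergence fallback ladder: correlated random
# intercept + year slope -> uncorrelated -> intercept only -> (degenerate
# data only) fixed effects by ordinary least squares.
fit_growth_lmer <- function(data) {
  forms <- list(
    full = outcome ~ year_c + grade_c + inter + (1 + year_c | subject_id),
    uncorrelated = outcome ~ year_c + grade_c + inter + (1 + year_c || subject_id),
    intercept_only = outcome ~ year_c + grade_c + inter + (1 | subject_id)
  )
  quiet_fit <- function(fitter, form) {
    ok <- TRUE
    fit <- withCallingHandlers(
      tryCatch(fitter(form, data = data, REML = TRUE),
               error = function(e) NULL),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      },
      message = function(m) invokeRestart("muffleMessage"))
    list(fit = fit, ok = ok)
  }
  usable <- function(fit) {
    sm <- try(suppressWarnings(summary(fit)$coefficients), silent = TRUE)
    !inherits(sm, "try-error") && all(is.finite(sm[, "Std. Error"])) &&
      all(sm[, "Std. Error"] > 0)
  }
  last <- NULL
  for (nm in names(forms)) {
    r <- quiet_fit(lmerTest::lmer, forms[[nm]])
    if (is.null(r$fit) || !usable(r$fit)) r <- quiet_fit(lme4::lmer, forms[[nm]])
    if (is.null(r$fit) || !usable(r$fit)) next
    conv_ok <- r$ok && length(r$fit@optinfo$conv$lme4$messages) == 0
    last <- list(fit = r$fit, structure = nm, clean = conv_ok)
    if (conv_ok) return(last)
  }
  if (!is.null(last)) return(last)
  # zero-variance or otherwise degenerate outcomes: plain least squares
  fit <- stats::lm(outcome ~ year_c + grade_c + inter, data = data)
  list(fit = fit, structure = "fixed_only", clean = FALSE)
}

growth_coef_table <- function(fit, df_method, n_obs) {
  sm <- summary(fit)$coefficients
  # variance-covariance parameters: k(k+1)/2 per grouping term + residual
  n_vc <- if (inherits(fit, "merMod")) {
    sum(vapply(lme4::VarCorr(fit), function(m) {
      k <- nrow(m); k * (k + 1) / 2
    }, numeric(1))) + 1
  } else {
    1
  }
  df <- if (df_method == "satterthwaite" && "df" %in% colnames(sm)) {
    sm[, "df"]
  } else {
    rep(n_obs - nrow(sm) - n_vc, nrow(sm))
  }
  B <- sm[, "Estimate"]; SE <- sm[, "Std. Error"]
  t <- B / SE
  p <- 2 * stats::pt(-abs(t), df)
  crit <- stats::qt(0.975, df)
  data.frame(term = rownames(sm), B = B, SE = SE,
             CI_low = B - crit * SE, CI_high = B + crit * SE,
             t = t, df = df, p = p, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fit the longitudinal growth-curve model to a subject-index outcome
#'
#' Linear mixed-effects model of a per-subject-year outcome on centered
#' testing year, centered start grade and their interaction, with the maximal
#' converging random-effects structure on participants (random intercept and
#' random slope of testing year, with their correlation), estimated by
#' restricted maximum likelihood. If the maximal structure fails to converge
#' the correlation is dropped, then the random slope, and the simplification
#' is flagged in `meta`. Standardized coefficients come from refitting the
#' same model on the z-scored outcome and predictor columns.
#'
#' @param data A dataset from [build_growth_dataset()].
#' @param df_method `"residual"` (default): df = N - fixed effects -
#'   variance-covariance parameters; or `"satterthwaite"`.
#' @param standardize Also fit the z-scored model for standardized betas
#'   (skippable to halve the cost in large simulation loops).
#' @return An object of class `growth_fit`: `coefficients` (term, B, SE, CI,
#'   t, df, p, standardized beta with CI), `random_effects` (variances,
#'   correlation, residual variance), `meta`, and the underlying `model`.
#' @export
fit_growth_model <- function(data, df_method = c("residual", "satterthwaite"),
                             standardize = TRUE) {
  df_method <- match.arg(df_method)
  res <- fit_growth_lmer(data)
  fit <- res$fit
  n <- nrow(data)
  tab <- growth_coef_table(fit, df_method, n)

  if (standardize) {
    zdata <- data
    zdata$outcome <- as.vector(scale(data$outcome))
    zdata$year_c <- as.vector(scale(data$year_c))
    zdata$grade_c <- as.vector(scale(data$grade_c))
    zdata$inter <- as.vector(scale(data$inter))
    zres <- fit_growth_lmer(zdata)
    ztab <- growth_coef_table(zres$fit, df_method, n)
    tab$beta_std <- ztab$B
    tab$beta_CI_low <- ztab$CI_low
    tab$beta_CI_high <- ztab$CI_high
  } else {
    tab$beta_std <- tab$beta_CI_low <- tab$beta_CI_high <- NA_real_
  }

  re <- if (inherits(fit, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    pick <- function(v) {
      hit <- vc$grp != "Residual" & vc$var1 == v & is.na(vc$var2)
      if (any(hit, na.rm = TRUE)) sum(vc$vcov[which(hit)]) else 0
    }
    corr_row <- which(!is.na(vc$var2))
    list(var_intercept = pick("(Intercept)"),
         var_year_slope = pick("year_c"),
         cor_intercept_slope = if (length(corr_row))
           vc$sdcor[corr_row[1]] else NA_real_,
         resid_var = stats::sigma(fit)^2)
  } else {
    list(var_intercept = 0, var_year_slope = 0,
         cor_intercept_slope = NA_real_, resid_var = stats::sigma(fit)^2)
  }
  structure(
    list(coefficients = tab, random_effects = re,
         meta = list(method = "REML", df_method = df_method,
                     structure = res$structure,
                     converged = res$clean,
                     singular = inherits(fit, "merMod") && lme4::isSingular(fit),
                     n_obs = n,
                     outcome = attr(data, "outcome_name"),
                     year_center = attr(data, "year_center"),
                     grade_center = attr(data, "grade_center")),
         model = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Growth-curve model for", x$meta$outcome, "(", x$meta$n_obs,
      "participant-years,", x$meta$structure, "random effects )\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Fixed-effect marginal predictions over a year-by-grade grid
#'
#' Predicted outcome at each combination of testing year and start grade,
#' from the fixed effects alone, with delta-method confidence intervals
#' (using the fixed-effect covariance matrix). Useful for visualizing cohort
#' trajectories, e.g. the flattening of the oldest cohort's trend when a
#' positive interaction offsets a negative year effect.
#'
#' @param fit A `growth_fit`.
#' @param years,grades Grids on the original (uncentered) scales.
#' @param level Confidence level.
#' @return Data frame: `testing_year`, `start_grade`, `predicted`, `SE`,
#'   `CI_low`, `CI_high`.
#' @export
marginal_predictions <- function(fit, years = 1:4, grades = 1:3,
                                 level = 0.95) {
  stopifnot(inherits(fit, "growth_fit"))
  grid <- expand.grid(testing_year = years, start_grade = grades)
  yc <- grid$testing_year - fit$meta$year_center
  gc <- grid$start_grade - fit$meta$grade_center
  obs_df <- stats::model.frame(fit$model)
  if (max(abs(yc)) > max(abs(obs_df$year_c)) + 1e-9 ||
      max(abs(gc)) > max(abs(obs_df$grade_c)) + 1e-9) {
    warning("prediction grid extends beyond the observed predictor range",
            call. = FALSE)
  }
  X <- cbind(1, yc, gc, yc * gc)
  b <- if (inherits(fit$model, "merMod")) lme4::fixef(fit$model)
    else stats::coef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  grid$predicted <- as.vector(X %*% b)
  grid$SE <- sqrt(rowSums((X %*% V) * X))
  z <- stats::qnorm(1 - (1 - level) / 2)
  grid$CI_low <- grid$predicted - z * grid$SE
  grid$CI_high <- grid$predicted + z * grid$SE
  grid
}

#' Practice-effect contrast: first-session change versus later change
#'
#' If improvements in the indices reflected task familiarity rather than
#' development, the largest change should occur between the first and second
#' testing years. For every subject observed in years 1 and 2 and at least
#' one later consecutive pair, this computes (year-2 minus year-1 change)
#' minus the subject's average later year-to-year change, and tests whether
#' the mean contrast differs from zero. Steady development gives a contrast
#' near 0; a one-time practice jump gives a large value of the jump's sign.
#'
#' @param indices Subject-index data frame (`subject_id`, `testing_year`, and
#'   the outcome column).
#' @param outcome Outcome column name.
#' @return A list: `estimate`, `se`, `ci` (95%), `t`, `df`, `p`,
#'   `n_subjects`.
#' @export
first_session_contrast <- function(indices, outcome = "slope_hat") {
  stopifnot(all(c("subject_id", "testing_year", outcome) %in% names(indices)))
  if (length(unique(indices$testing_year)) < 3) {
    stop("the practice contrast needs at least 3 years of data",
         call. = FALSE)
  }
  per_subject <- vapply(split(indices, indices$subject_id), function(d) {
    d <- d[order(d$testing_year), ]
    y <- stats::setNames(d[[outcome]], d$testing_year)
    if (!all(c("1", "2") %in% names(y))) return(NA_real_)
    yrs <- as.integer(names(y))
    later <- vapply(yrs[yrs >= 2], function(t) {
      if ((t + 1) %in% yrs) y[[as.character(t + 1)]] - y[[as.character(t)]]
      else NA_real_
    }, numeric(1))
    later <- later[is.finite(later)]
    if (length(later) == 0) return(NA_real_)
    (y[["2"]] - y[["1"]]) - mean(later)
  }, numeric(1))
  cs <- per_subject[is.finite(per_subject)]
  if (length(cs) < 2) {
    stop("not enough subjects with year 1, 2 and a later consecutive pair",
         call. = FALSE)
  }
  n <- length(cs)
  est <- mean(cs)
  se <- stats::sd(cs) / sqrt(n)
  if (se == 0) {
    return(list(estimate = est, se = 0, ci = c(est, est),
                t = if (est == 0) 0 else sign(est) * Inf, df = n - 1,
                p = if (est == 0) 1 else 0, n_subjects = n))
  }
  tt <- est / se
  list(estimate = est, se = se,
       ci = est + c(-1, 1) * stats::qt(0.975, n - 1) * se,
       t = tt, df = n - 1, p = 2 * stats::pt(-abs(tt), n - 1),
       n_subjects = n)
}
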