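#' Sampler and prior settings for the hierarchical psychometric fit
#'
#' Weakly informative priors are centered on the known measurement scale:
#' asymptotes near 0 and 100 (scale 20), crossover mid-continuum (scale 2
#' steps), slope centered at 15 VAS/step (scale 15, soft positivity through
#' prior mass rather than a hard bound), and vague normals on the
#' log-variance coefficients. Random-intercept SDs get half-normal priors.
#'
#' @param chains Number of MCMC chains (run sequentially).
#' @param warmup Adaptation iterations per chain (discarded).
#' @param iter Post-warmup iterations per chain.
#' @param thin Keep every `thin`-th draw.
#' @param seed Integer seed; chain `i` uses `seed + i - 1`.
#' @param rhat_warn Potential-scale-reduction threshold above which a
#'   convergence warning is raised (never silently ignored).
#' @param pop_mean,pop_sd Prior means/SDs for the population parameters in the
#'   order `L0, U0, c0, s0, w0, w1, w2` (`c0`'s mean defaults to the
#'   mid-step at fit time when `NA`).
#' @param hn_subject Half-normal scales for the subject random-intercept SDs
#'   (`L, U, crossover, slope, theta`).
#' @param hn_item Half-normal scales for the item random-intercept SDs
#'   (`L, U, crossover, slope`).
#' @return A list of class `vas_fit_spec`.
#' @export
vas_fit_spec <- function(chains = 4L, warmup = 1500L, iter = 1500L, thin = 1L,
                         seed = 1L, rhat_warn = 1.05,
                         pop_mean = c(0, 100, NA, 15, 5, 0, 0),
                         pop_sd = c(20, 20, 2, 15, 3, 1, 1),
                         hn_subject = c(15, 15, 1.5, 10, 1.5),
                         hn_item = c(10, 10, 1, 5)) {
  stopifnot(chains >= 1, warmup >= 0, iter >= thin, thin >= 1,
            length(pop_mean) == 7, length(pop_sd) == 7,
            length(hn_subject) == 5, length(hn_item) == 4,
            all(pop_sd > 0), all(hn_subject > 0), all(hn_item > 0))
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_warn = rhat_warn,
                 pop_mean = pop_mean, pop_sd = pop_sd,
                 hn_subject = hn_subject, hn_item = hn_item),
            class = "vas_fit_spec")
}

pop_par_names <- c("L0", "U0", "c0", "s0", "w0", "w1", "w2")
sd_par_names <- c(paste0("sd_subj_", c("L", "U", "c", "s", "theta")),
                  paste0("sd_item_", c("L", "U", "c", "s")))

fit_par_names <- function(S, I) {
  c(pop_par_names, sd_par_names,
    as.vector(t(outer(c("L", "U", "c", "s", "theta"),
                      seq_len(S), function(p, j) sprintf("u_%s[%d]", p, j)))),
    as.vector(t(outer(c("L", "U", "c", "s"),
                      seq_len(I), function(p, k) sprintf("v_%s[%d]", p, k)))))
}

# Data-informed starting values shared by all chains (each chain jitters them).
fit_inits <- function(data, mid) {
  sm <- tapply(data$vas_score, data$step, mean)
  L0 <- min(sm); U0 <- max(sm)
  b <- stats::coef(stats::lm(vas_score ~ step, data = data))[["step"]]
  s0 <- max(2, 1.4 * b)
  resid_var <- stats::var(data$vas_score - sm[as.character(data$step)])
  c(L0, U0, mid, s0, log(max(resid_var, 1)), 0, -0.05)
}

#' Fit the hierarchical Bayesian psychometric model to one testing year
#'
#' Fits the four-parameter logistic with crossed subject and item random
#' intercepts on all four curve parameters, plus a subject random intercept on
#' the (log-quadratic-in-step) trial variance, to one testing year's
#' assembled dataset. Sampling uses the package's adaptive
#' Metropolis-within-Gibbs sampler with non-centered random effects; each
#' chain is seeded and the fit is fully reproducible. Split-chain potential
#' scale reduction and effective sample sizes are computed for every
#' population and scale parameter, and a warning is raised (never suppressed)
#' if any exceeds `spec$rhat_warn`.
#'
#' @param data Model-ready data frame from [assemble_year_dataset()].
#' @param spec A [vas_fit_spec()].
#' @param mid Center of the variance quadratic; defaults to the midpoint of
#'   the observed step range.
#' @return An object of class `vas_fit` with elements `draws`
#'   (a [coda::mcmc.list]), `summary` (population/scale parameter table),
#'   `diagnostics`, `subject_levels`, `item_levels`, `year`, `steps`, `mid`.
#' @export
fit_year <- function(data, spec = vas_fit_spec(),
                     mid = (min(data$step) + max(data$step)) / 2) {
  stopifnot(inherits(spec, "vas_fit_spec"),
            all(c("vas_score", "step", "subject_index", "item_index")
                %in% names(data)))
  S <- max(data$subject_index) + 1L
  I <- max(data$item_index) + 1L
  if (S < 2 || I < 2) {
    stop("the hierarchical fit needs at least 2 subjects and 2 items",
         call. = FALSE)
  }
  pop_mean <- spec$pop_mean
  if (is.na(pop_mean[3])) pop_mean[3] <- mid
  init0 <- fit_inits(data, mid)
  lsd_s0 <- log(pmax(0.05, spec$hn_subject / 3))
  lsd_i0 <- log(pmax(0.05, spec$hn_item / 3))
  jit <- c(3, 3, 0.3, 3, 0.3, 0.05, 0.02)

  chains <- vector("list", spec$chains)
  pnames <- fit_par_names(S, I)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + ch - 1L)
    out <- .vas_sampler(
      y = data$vas_score, x = as.numeric(data$step),
      subj = as.integer(data$subject_index), item = as.integer(data$item_index),
      S = S, I = I, mid = mid,
      pop_mean = pop_mean, pop_sd = spec$pop_sd,
      hn_subj = spec$hn_subject, hn_item = spec$hn_item,
      warmup = spec$warmup, iter = spec$iter, thin = spec$thin,
      pop_init = init0 + jit * stats::rnorm(7),
      lsd_s_init = lsd_s0 + stats::rnorm(5, 0, 0.3),
      lsd_i_init = lsd_i0 + stats::rnorm(4, 0, 0.3),
      z_jitter = 0.1)
    dm <- out$draws
    colnames(dm) <- pnames
    chains[[ch]] <- coda::mcmc(dm, start = spec$warmup + 1, thin = spec$thin)
  }
  draws <- coda::mcmc.list(chains)

  core <- c(pop_par_names, sd_par_names)
  core_draws <- draws[, core, drop = FALSE]
  rhat <- if (spec$chains > 1) {
    coda::gelman.diag(core_draws, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1]
  } else {
    stats::setNames(rep(NA_real_, length(core)), core)
  }
  ess <- coda::effectiveSize(core_draws)
  pooled <- as.matrix(core_draws)
  qs <- t(apply(pooled, 2, stats::quantile, probs = c(0.025, 0.975)))
  summary <- data.frame(
    parameter = core,
    mean = colMeans(pooled),
    sd = apply(pooled, 2, stats::sd),
    q2.5 = qs[, 1], q97.5 = qs[, 2],
    rhat = rhat[core], ess = ess[core],
    row.names = NULL, stringsAsFactors = FALSE
  )
  bad <- summary$parameter[!is.na(summary$rhat) & summary$rhat > spec$rhat_warn]
  diagnostics <- list(max_rhat = suppressWarnings(max(summary$rhat, na.rm = TRUE)),
                      min_ess = min(summary$ess),
                      flagged = bad, converged = length(bad) == 0)
  if (length(bad)) {
    warning("convergence diagnostics above threshold (",
            sprintf("%.3f", spec$rhat_warn), ") for: ",
            paste(bad, collapse = ", "), call. = FALSE)
  }

  grade_map <- NULL
  if ("start_grade" %in% names(data)) {
    first <- !duplicated(data$subject_id)
    grade_map <- stats::setNames(data$start_grade[first], data$subject_id[first])
  }
  structure(
    list(draws = draws, summary = summary, diagnostics = diagnostics,
         spec = spec, year = attr(data, "year"),
         subject_levels = attr(data, "subject_levels"),
         item_levels = attr(data, "item_levels"),
         steps = sort(unique(data$step)), mid = mid,
         grade_map = grade_map, n_obs = nrow(data)),
    class = "vas_fit"
  )
}

#' @export
print.vas_fit <- function(x, ...) {
  cat("Hierarchical VAS psychometric fit",
      if (!is.null(x$year)) paste0("(testing year ", x$year, ")"), "\n")
  cat("  ", length(x$subject_levels), "subjects,", length(x$item_levels),
      "items,", x$n_obs, "trials\n")
  cat(sprintf("  max Rhat %.3f, min ESS %.0f%s\n", x$diagnostics$max_rhat,
              x$diagnostics$min_ess,
              if (x$diagnostics$converged) "" else "  [convergence flagged]"))
  print(x$summary[x$summary$parameter %in% pop_par_names, ], digits = 3)
  invisible(x)
}

#' Posterior draws of one parameter across chains
#'
#' @param fit A `vas_fit`.
#' @param par Parameter name (e.g. `"s0"` or `"u_s[3]"`).
#' @return Numeric vector of pooled posterior draws.
#' @export
posterior_draws <- function(fit, par) {
  as.vector(as.matrix(fit$draws[, par, drop = FALSE]))
}

#' Extract per-subject Slope and Response Variability indices
#'
#' For every subject in the fit, Slope is the posterior mean of the
#' population slope plus that subject's slope intercept plus the average item
#' (continuum) slope intercept -- i.e. the subject's slope averaged over the
#' tested continua. Including the item average matters for identification:
#' the split between the population slope and the item mean is informed only
#' by the prior, so it can drift between independently fitted years, whereas
#' their sum is pinned by the data. Response Variability is the posterior
#' mean of the subject's trial variance averaged over the continuum steps (a
#' step-averaged \eqn{\sigma^2}; squared VAS units, so 0 means perfectly
#' consistent and several hundred is a noisy responder).
#'
#' @param fit A `vas_fit` from [fit_year()].
#' @return A data frame with one row per subject: `subject_id`,
#'   `testing_year`, `start_grade` (if known), `slope_hat`, `rv_hat`.
#' @export
extract_subject_indices <- function(fit) {
  stopifnot(inherits(fit, "vas_fit"))
  S <- length(fit$subject_levels)
  I <- length(fit$item_levels)
  pooled <- as.matrix(fit$draws)
  vbar <- rowMeans(pooled[, sprintf("v_s[%d]", seq_len(I)), drop = FALSE])
  s0 <- pooled[, "s0"] + vbar
  w0 <- pooled[, "w0"]; w1 <- pooled[, "w1"]; w2 <- pooled[, "w2"]
  d <- fit$steps - fit$mid
  slope_hat <- rv_hat <- numeric(S)
  for (j in seq_len(S)) {
    us <- pooled[, sprintf("u_s[%d]", j)]
    ut <- pooled[, sprintf("u_theta[%d]", j)]
    slope_hat[j] <- mean(s0 + us)
    # average the variance profile over steps within each draw, then average
    profile <- exp(outer(w0 + ut, rep(1, length(d))) +
                     outer(w1, d) + outer(w2, d^2))
    rv_hat[j] <- mean(rowMeans(profile))
  }
  out <- data.frame(subject_id = fit$subject_levels,
                    testing_year = if (is.null(fit$year)) NA_integer_ else fit$year,
                    slope_hat = slope_hat, rv_hat = rv_hat,
                    stringsAsFactors = FALSE)
  if (!is.null(fit$grade_map)) {
    out$start_grade <- unname(fit$grade_map[out$subject_id])
    out <- out[, c("subject_id", "start_grade", "testing_year",
                   "slope_hat", "rv_hat")]
  }
  out
}
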