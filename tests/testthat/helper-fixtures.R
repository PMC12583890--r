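# Shared fixtures. The hierarchical fits are the expensive pieces, so the
# data-rich fixture fit is built once and memoised for the whole test run.

# Single-year, single-cohort recovery conditions: no developmental trends, so
# the generator's population values are exactly the fit's estimands. The
# asymptotes sit well inside the scale and noise is moderate so that clipping
# at 0/100 is negligible and the Gaussian model is well specified -- interval
# calibration can only be checked where the generating process matches the
# model (the clipping-biased regime is exercised separately).
recovery_truth <- function(s_sd = 5, rv_mean = 120) {
  vas_truth(L_mean = 15, L_sd = 4, U_mean = 85, U_sd = 4,
            c_mean = 4, c_sd = 0.4, s_mean = 20, s_sd = s_sd,
            item_sd = c(L = 2, U = 2, crossover = 0.2, slope = 1.5),
            rv_mean = rv_mean, rv_subject_sd = 0.4,
            s_year = 0, s_grade = 0, s_year_grade = 0, s_yearslope_sd = 0,
            rv_year = 0, rv_grade = 0, rv_year_grade = 0, rv_yearslope_sd = 0)
}

recovery_design <- function(n_subjects = 30L, continua = c("beach-peach",
                                                           "sip-ship")) {
  vas_design(cohorts = 2L, years = 1L, continua = continua,
             steps = 7L, days = 2L, reps = 2L,
             subjects_per_cohort = n_subjects)
}

# Reduced sampler settings for tests: enough draws for stable posterior means
# and 95% intervals on fixtures of this size.
test_fit_spec <- function(seed = 1L, chains = 2L, warmup = 700L, iter = 700L) {
  vas_fit_spec(chains = chains, warmup = warmup, iter = iter, seed = seed)
}

assemble_recovery_year <- function(study) {
  clean <- normalize_orientation(study$trials)
  screen <- screen_subject_years(clean)
  assemble_year_dataset(clean, screen, 1L)
}

# 30 subjects x 4 continua x 112 trials: rich per-subject data, used for
# index-recovery, shrinkage and oracle cross-checks.
rich_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    design <- recovery_design(30L, c("beach-peach", "time-dime",
                                     "net-nut", "hat-hot"))
    study <- simulate_study(design, recovery_truth(), seed = 2024L,
                            attrition_rate = 0)
    dat <- assemble_recovery_year(study)
    fit <- suppressWarnings(fit_year(dat, test_fit_spec(seed = 5L)))
    indices <- extract_subject_indices(fit)
    cache <<- list(design = design, study = study, dat = dat, fit = fit,
                   indices = indices)
    cache
  }
})

# 40 subjects x 4 continua with a wide slope spread and moderate trial noise:
# the regime where the hierarchical and per-subject NLS routes must agree
# (latent slope variance well above either route's estimation noise).
oracle_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    design <- recovery_design(40L, c("beach-peach", "time-dime",
                                     "net-nut", "hat-hot"))
    study <- simulate_study(design, recovery_truth(s_sd = 8, rv_mean = 120),
                            seed = 4047L, attrition_rate = 0)
    dat <- assemble_recovery_year(study)
    fit <- suppressWarnings(fit_year(dat, test_fit_spec(seed = 8L,
                                                        warmup = 600L,
                                                        iter = 600L)))
    cache <<- list(study = study, dat = dat, fit = fit,
                   indices = extract_subject_indices(fit))
    cache
  }
})

# Balanced accelerated-longitudinal index table with known fixed effects and
# controllable noise, for growth-model tests that bypass the MCMC stage.
make_index_table <- function(n_subjects = 200, years = 4,
                             b0 = 20, b_year = 0, b_grade = 0, b_inter = 0,
                             sd_subject = 6, sd_yearslope = 1.5, sd_noise = 5,
                             outcome = "slope_hat", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("s%04d", seq_len(n_subjects))
  grade <- rep(rep(1:3, length.out = n_subjects))
  b <- stats::rnorm(n_subjects, 0, sd_subject)
  g <- stats::rnorm(n_subjects, 0, sd_yearslope)
  d <- expand.grid(subject_id = ids, testing_year = seq_len(years),
                   stringsAsFactors = FALSE)
  i <- match(d$subject_id, ids)
  d$start_grade <- grade[i]
  yc <- d$testing_year - mean(seq_len(years))
  gc <- d$start_grade - mean(grade)
  d[[outcome]] <- b0 + b[i] + (b_year + g[i]) * yc + b_grade * gc +
    b_inter * yc * gc + stats::rnorm(nrow(d), 0, sd_noise)
  d
}
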