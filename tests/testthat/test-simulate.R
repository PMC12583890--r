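test_that("zero-variance populations give every subject the mean parameters", {
  tr <- vas_truth(L_sd = 0, U_sd = 0, c_sd = 0, s_sd = 0,
                  item_sd = c(L = 0, U = 0, crossover = 0, slope = 0),
                  rv_subject_sd = 0, s_yearslope_sd = 0, rv_yearslope_sd = 0,
                  s_year = 0, s_grade = 0, s_year_grade = 0,
                  rv_year = 0, rv_grade = 0, rv_year_grade = 0)
  p <- draw_subject_params(tr, start_grade = 2, testing_year = 1, seed = 1)
  expect_equal(p$L, tr$L_mean)
  expect_equal(p$U, tr$U_mean)
  expect_equal(p$crossover, tr$c_mean)
  expect_equal(p$slope, tr$s_mean)
  expect_equal(p$theta, 0)
  expect_equal(p$rv, tr$rv_mean)
})

test_that("year trend on slope: year 4 vs year 1 differs by 3x the trend", {
  tr <- vas_truth()  # default slope trend -1.39/year
  set.seed(99)
  n <- 4000
  s1 <- replicate(n, draw_subject_params(tr, 2, 1)$slope)
  s4 <- replicate(n, draw_subject_params(tr, 2, 4)$slope)
  diff_hat <- mean(s4) - mean(s1)
  mc_se <- sqrt(var(s1) / n + var(s4) / n)
  expect_lt(abs(diff_hat - (-4.17)), 3 * mc_se)
})

test_that("drawn slope SD matches the configured population SD", {
  tr <- vas_truth(s_sd = 6, s_yearslope_sd = 0)
  set.seed(123)
  s <- replicate(10000, draw_subject_params(tr, 2, 1)$slope)
  # SE of an SD estimate is about sd/sqrt(2n)
  expect_lt(abs(sd(s) - 6), 3 * 6 / sqrt(2 * 10000))
})

test_that("noiseless trial at the crossover returns the curve midpoint", {
  p <- structure(list(L = 12, U = 84, crossover = 3.6, slope = 17,
                      theta = 0, w0 = -60, w1 = 0, w2 = 0, mid = 4),
                 class = "psychometric_params")
  expect_equal(simulate_trial(p, step = 3.6, seed = 1), (12 + 84) / 2,
               tolerance = 1e-9)
  # flipped block emits the mirror image
  expect_equal(simulate_trial(p, step = 3.6, flipped = TRUE, seed = 1),
               100 - (12 + 84) / 2, tolerance = 1e-9)
})

test_that("simulated rating means track the analytic 4PL at every step", {
  # interior asymptotes so clipping cannot bias the means
  p <- structure(list(L = 30, U = 70, crossover = 4, slope = 10,
                      theta = 0, w0 = log(25), w1 = 0, w2 = 0, mid = 4),
                 class = "psychometric_params")
  set.seed(7)
  for (step in 1:7) {
    y <- simulate_trial(p, rep(step, 20000))
    mu <- fourpl_mean(step, p$L, p$U, p$crossover, p$slope)
    expect_lt(abs(mean(y) - mu), 3 * sd(y) / sqrt(20000))
  }
})

test_that("trial variance peaks mid-continuum when w2 < 0", {
  p <- structure(list(L = 30, U = 70, crossover = 4, slope = 8,
                      theta = 0, w0 = log(150), w1 = 0, w2 = -0.25, mid = 4),
                 class = "psychometric_params")
  set.seed(8)
  v <- vapply(c(1, 4, 7), function(s) var(simulate_trial(p, rep(s, 5000))),
              numeric(1))
  expect_gt(v[2], v[1])
  expect_gt(v[2], v[3])
})

test_that("simulated studies have the right shape and are seed-deterministic", {
  des <- vas_design(cohorts = c(1L, 3L), subjects_per_cohort = 3L)
  tr <- vas_truth()
  st <- simulate_study(des, tr, seed = 5, attrition_rate = 0)
  expect_equal(nrow(st$truth_table), 3 * 2 * 4)
  expect_equal(nrow(st$trials), 3 * 2 * 4 * 140)
  expect_true(all(st$trials$raw_rating >= 0 & st$trials$raw_rating <= 100))
  expect_true(all(st$trials$step %in% 1:7))
  # one truth row per realized participant-year
  py <- unique(st$trials[c("subject_id", "testing_year")])
  expect_equal(nrow(py), nrow(st$truth_table))

  st2 <- simulate_study(des, tr, seed = 5, attrition_rate = 0)
  expect_identical(st$trials, st2$trials)
  expect_identical(st$truth_table, st2$truth_table)
  st3 <- simulate_study(des, tr, seed = 6, attrition_rate = 0)
  expect_false(identical(st$trials$raw_rating, st3$trials$raw_rating))
})

test_that("attrition drops whole participant-years at random", {
  des <- vas_design(cohorts = c(1L, 2L), subjects_per_cohort = 10L)
  st <- simulate_study(des, vas_truth(), seed = 9, attrition_rate = 0.3)
  expect_lt(nrow(st$truth_table), 20 * 4)
  counts <- table(st$trials$subject_id, st$trials$testing_year)
  expect_true(all(counts %in% c(0L, 140L)))
})

test_that("latent parameter table recovers the configured trends", {
  des <- vas_design(subjects_per_cohort = 60L,
                    continua = c("beach-peach", "sip-ship"))
  tr <- vas_truth()
  st <- simulate_study(des, tr, seed = 31, attrition_rate = 0)
  tt <- st$truth_table
  yc <- tt$testing_year - mean(tt$testing_year)
  gc <- tt$start_grade - mean(tt$start_grade)
  fit_s <- lm(tt$slope ~ yc * gc)
  expect_lt(abs(coef(fit_s)[["yc"]] - tr$s_year),
            3 * summary(fit_s)$coefficients["yc", "Std. Error"])
  expect_lt(abs(coef(fit_s)[["gc"]] - tr$s_grade),
            3 * summary(fit_s)$coefficients["gc", "Std. Error"])
  fit_v <- lm(tt$rv ~ yc * gc)
  se <- summary(fit_v)$coefficients
  # multiplicative subject heterogeneity inflates the mean RV level slightly;
  # trends stay linear in expectation up to that common factor
  infl <- exp(tr$rv_subject_sd^2 / 2)
  expect_lt(abs(coef(fit_v)[["yc"]] - infl * tr$rv_year), 3 * se["yc", 2])
  expect_lt(abs(coef(fit_v)[["yc:gc"]] - infl * tr$rv_year_grade),
            3 * se["yc:gc", 2])
})

test_that("asymptote resampling budget errors out when U > L is impossible", {
  tr <- vas_truth(L_sd = 1, U_sd = 1)
  tr$L_mean <- 95; tr$U_mean <- 5  # force an infeasible ordering
  expect_error(draw_subject_params(tr, 2, 1, seed = 2), "resampling budget")
})
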