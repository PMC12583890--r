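test_that("growth dataset centering is exact", {
  idx <- make_index_table(n_subjects = 30, seed = 1)
  gd <- build_growth_dataset(idx, "slope_hat")
  expect_setequal(unique(gd$year_c), c(-1.5, -0.5, 0.5, 1.5))
  expect_setequal(unique(gd$grade_c), c(-1, 0, 1))
  expect_lt(abs(mean(gd$year_c)), 1e-12)
  expect_lt(abs(mean(gd$grade_c)), 1e-12)
  expect_equal(gd$inter, gd$year_c * gd$grade_c)
})

test_that("noise-free linear data are recovered exactly", {
  idx <- make_index_table(n_subjects = 60, b0 = 5, b_year = -1.39,
                          sd_subject = 0, sd_yearslope = 0, sd_noise = 0,
                          seed = 2)
  gf <- fit_growth_model(build_growth_dataset(idx, "slope_hat"))
  cf <- setNames(gf$coefficients$B, gf$coefficients$term)
  expect_lt(abs(cf[["(Intercept)"]] - 5), 1e-8)
  expect_lt(abs(cf[["year_c"]] - (-1.39)), 1e-8)
  expect_lt(abs(cf[["grade_c"]]), 1e-8)
  expect_lt(abs(cf[["inter"]]), 1e-8)
})

test_that("standardized beta equals B * SD(x)/SD(y)", {
  idx <- make_index_table(n_subjects = 120, b_year = -1.5, b_grade = 2,
                          b_inter = -0.5, sd_noise = 4, seed = 3)
  gd <- build_growth_dataset(idx, "slope_hat")
  gf <- fit_growth_model(gd)
  cf <- gf$coefficients
  for (term in c("year_c", "grade_c", "inter")) {
    sdx <- sd(gd[[term]])
    expected <- cf$B[cf$term == term] * sdx / sd(gd$outcome)
    expect_equal(cf$beta_std[cf$term == term], expected, tolerance = 1e-6)
  }
})

test_that("coefficient table is complete and internally consistent", {
  idx <- make_index_table(n_subjects = 80, b_year = -1.39, b_grade = 2.42,
                          b_inter = -0.81, seed = 4)
  gf <- fit_growth_model(build_growth_dataset(idx, "slope_hat"))
  cf <- gf$coefficients
  expect_setequal(cf$term, c("(Intercept)", "year_c", "grade_c", "inter"))
  expect_true(all(cf$CI_low < cf$CI_high))
  expect_equal(cf$t, cf$B / cf$SE, tolerance = 1e-12)
  expect_true(all(cf$p >= 0 & cf$p <= 1))
  re <- gf$random_effects
  expect_gte(re$var_intercept, 0)
  expect_gte(re$var_year_slope, 0)
  expect_gte(re$resid_var, 0)
  if (is.finite(re$cor_intercept_slope)) {
    expect_lte(abs(re$cor_intercept_slope), 1)
  }
  # Satterthwaite df are available and <= residual-convention df
  gf2 <- fit_growth_model(build_growth_dataset(idx, "slope_hat"),
                          df_method = "satterthwaite")
  expect_true(all(gf2$coefficients$df <= cf$df + 1e-9))
})

test_that("marginal predictions reproduce the fixed-effect surface", {
  idx <- make_index_table(n_subjects = 90, b0 = 10, b_year = -2, b_grade = 3,
                          b_inter = 0, sd_subject = 0, sd_yearslope = 0,
                          sd_noise = 0, seed = 5)
  gf <- fit_growth_model(build_growth_dataset(idx, "slope_hat"))
  preds <- marginal_predictions(gf, years = 1:4, grades = 1:3)
  # prediction at the grand means equals the fitted intercept
  center <- marginal_predictions(gf, years = gf$meta$year_center,
                                 grades = gf$meta$grade_center)
  expect_equal(center$predicted,
               gf$coefficients$B[gf$coefficients$term == "(Intercept)"],
               tolerance = 1e-8)
  # no interaction: cohort lines are parallel
  byg <- split(preds, preds$start_grade)
  trends <- vapply(byg, function(d) diff(range(d$predicted)), numeric(1))
  expect_lt(max(trends) - min(trends), 1e-6)
})

test_that("a positive interaction on a negative year effect flattens the oldest cohort", {
  idx <- make_index_table(n_subjects = 120, b0 = 300, b_year = -26.08,
                          b_grade = -36.78, b_inter = 26.52, sd_subject = 0,
                          sd_yearslope = 0, sd_noise = 0, seed = 6,
                          outcome = "rv_hat")
  gf <- fit_growth_model(build_growth_dataset(idx, "rv_hat"))
  preds <- marginal_predictions(gf, years = 1:4, grades = 1:3)
  slope_of <- function(g) {
    d <- preds[preds$start_grade == g, ]
    coef(lm(predicted ~ testing_year, data = d))[["testing_year"]]
  }
  s1 <- slope_of(1); s3 <- slope_of(3)
  expect_lt(s1, 0)
  expect_lt(abs(s3), abs(s1))  # oldest cohort plateaus
  expect_warning(marginal_predictions(gf, years = 0:5, grades = 1:3),
                 "beyond the observed")
})

test_that("practice contrast is null on steady change and flags a jump", {
  # perfectly linear decline: contrast exactly zero
  lin <- make_index_table(n_subjects = 40, b_year = -1.39, sd_subject = 3,
                          sd_yearslope = 0, sd_noise = 0, seed = 7)
  ct <- first_session_contrast(lin, "slope_hat")
  expect_lt(abs(ct$estimate), 1e-10)

  # constant outcome: exactly zero as well
  const <- make_index_table(n_subjects = 40, b_year = 0, sd_subject = 3,
                            sd_yearslope = 0, sd_noise = 0, seed = 8)
  expect_equal(first_session_contrast(const, "slope_hat")$estimate, 0)

  # one-time jump between years 1 and 2 is detected with the right sign
  jump <- lin
  jump$slope_hat <- jump$slope_hat - 2.78 * (jump$testing_year >= 2)
  ctj <- first_session_contrast(jump, "slope_hat")
  expect_equal(ctj$estimate, -2.78, tolerance = 1e-10)

  short <- lin[lin$testing_year <= 2, ]
  expect_error(first_session_contrast(short, "slope_hat"), "3 years")
})

test_that("growth dataset construction validates inputs", {
  idx <- make_index_table(n_subjects = 10, seed = 9)
  expect_error(build_growth_dataset(idx[idx$testing_year == 1, ]),
               ">= 2 years")
  one_grade <- idx
  one_grade$start_grade <- 2L
  expect_error(build_growth_dataset(one_grade, "slope_hat"), "constant")
})
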