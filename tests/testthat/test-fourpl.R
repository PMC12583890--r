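test_that("4PL midpoint, monotonicity and bounds", {
  expect_equal(fourpl_mean(4, L = 10, U = 90, crossover = 4, slope = 20), 50)
  expect_equal(fourpl_mean(2.7, L = 3, U = 88, crossover = 2.7, slope = 11),
               (3 + 88) / 2)
  x <- seq(0, 8, by = 0.1)
  y <- fourpl_mean(x, L = 5, U = 95, crossover = 4, slope = 18)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > 5 & y < 95))
  expect_error(fourpl_mean(1, L = 50, U = 40, crossover = 4, slope = 10),
               "U > L")
})

test_that("slope parameter equals the derivative at the crossover", {
  set.seed(11)
  h <- 1e-5
  for (i in 1:200) {
    L <- runif(1, -10, 30); U <- L + runif(1, 30, 110)
    cc <- runif(1, 1, 7); s <- runif(1, 2, 40)
    fd <- (fourpl_mean(cc + h, L, U, cc, s) -
             fourpl_mean(cc - h, L, U, cc, s)) / (2 * h)
    expect_equal(fd, s, tolerance = 1e-6)
  }
})

test_that("4PL value matches an independently coded formula", {
  # direct arithmetic, written without reference to fourpl_mean internals
  L <- 0; U <- 100; cc <- 4; s <- 25; x <- 7
  k <- 4 * s / (U - L)
  expected <- L + (U - L) * (1 / (1 + exp(-k * (x - cc))))
  expect_equal(fourpl_mean(x, L, U, cc, s), expected, tolerance = 1e-12)
  expect_equal(expected, 95.257413, tolerance = 1e-6)
})

test_that("variance profile: constancy, peak location, symmetry", {
  expect_equal(trial_sigma2(1:7, w0 = 2, w1 = 0, w2 = 0, theta = 0.5),
               rep(exp(2.5), 7))
  s2 <- trial_sigma2(seq(1, 7, 0.1), w0 = 5, w1 = 0, w2 = -0.2)
  expect_equal(seq(1, 7, 0.1)[which.max(s2)], 4)
  for (delta in c(0.5, 1, 2.3)) {
    expect_equal(trial_sigma2(4 + delta, 5, 0, -0.2),
                 trial_sigma2(4 - delta, 5, 0, -0.2))
  }
  expect_true(all(trial_sigma2(1:7, w0 = -10, w1 = 3, w2 = 2) > 0))
})

test_that("response variability index is the step-averaged variance", {
  w0 <- 5.5; w2 <- -0.15
  expect_equal(response_variability(w0, 0, w2),
               mean(exp(w0 + w2 * ((1:7) - 4)^2)))
  # trial SD of ~23 VAS points sits in the reported hundreds range
  rv <- response_variability(w0 = log(23^2), w1 = 0, w2 = 0)
  expect_equal(rv, 529)
})

make_loglik_pars <- function(S = 1, I = 1) {
  list(L = 10, U = 90, crossover = 4, slope = 20, w0 = 0, w1 = 0, w2 = 0,
       subject = matrix(0, S, 5,
                        dimnames = list(NULL, c("L", "U", "crossover",
                                                "slope", "theta"))),
       item = matrix(0, I, 4,
                     dimnames = list(NULL, c("L", "U", "crossover", "slope"))))
}

test_that("log-likelihood of a single trial at its mean with unit variance", {
  pars <- make_loglik_pars()
  d <- data.frame(vas_score = 50, step = 4, subject_index = 0L,
                  item_index = 0L)
  expect_equal(vas_loglik(d, pars), -0.5 * log(2 * pi), tolerance = 1e-12)
})

test_that("log-likelihood matches an independent per-trial density sum", {
  set.seed(21)
  pars <- make_loglik_pars(S = 3, I = 2)
  pars$subject[] <- rnorm(15, 0, c(3, 3, 0.3, 2, 0.3))
  pars$item[] <- rnorm(8, 0, 1)
  pars$w0 <- 5; pars$w2 <- -0.1
  d <- data.frame(step = sample(1:7, 10, replace = TRUE),
                  subject_index = sample(0:2, 10, replace = TRUE),
                  item_index = sample(0:1, 10, replace = TRUE))
  d$vas_score <- runif(10, 0, 100)
  # brute-force oracle: explicit normal density, one trial at a time
  oracle <- 0
  for (n in 1:10) {
    j <- d$subject_index[n] + 1; k <- d$item_index[n] + 1
    L <- pars$L + pars$subject[j, "L"] + pars$item[k, "L"]
    U <- pars$U + pars$subject[j, "U"] + pars$item[k, "U"]
    cc <- pars$crossover + pars$subject[j, "crossover"] + pars$item[k, "crossover"]
    s <- pars$slope + pars$subject[j, "slope"] + pars$item[k, "slope"]
    mu <- L + (U - L) / (1 + exp(-(4 * s / (U - L)) * (d$step[n] - cc)))
    s2 <- exp(pars$subject[j, "theta"] + pars$w0 +
                pars$w1 * (d$step[n] - 4) + pars$w2 * (d$step[n] - 4)^2)
    oracle <- oracle - 0.5 * (log(2 * pi * s2) + (d$vas_score[n] - mu)^2 / s2)
  }
  expect_equal(vas_loglik(d, pars), unname(oracle), tolerance = 1e-10)
})

test_that("log-likelihood is additive in trials", {
  pars <- make_loglik_pars()
  pars$w0 <- 4
  d <- data.frame(vas_score = c(20, 60, 85), step = c(1, 4, 7),
                  subject_index = 0L, item_index = 0L)
  base <- vas_loglik(d, pars)
  dup <- vas_loglik(rbind(d, d[2, ]), pars)
  expect_equal(dup - base, vas_loglik(d[2, , drop = FALSE], pars),
               tolerance = 1e-12)
})
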