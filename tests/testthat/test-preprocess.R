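test_that("orientation normalization is an involution on [0, 100]", {
  d <- data.frame(raw_rating = c(30, 30), flipped = c(TRUE, FALSE))
  out <- normalize_orientation(d)
  expect_equal(out$vas_score, c(70, 30))
  # flip(flip(x)) = x over a full sweep
  sweep <- data.frame(raw_rating = 0:100, flipped = TRUE)
  once <- normalize_orientation(sweep)
  twice <- normalize_orientation(data.frame(raw_rating = once$vas_score,
                                            flipped = TRUE))
  expect_equal(twice$vas_score, sweep$raw_rating)
  expect_true(all(once$vas_score >= 0 & once$vas_score <= 100))
  expect_error(normalize_orientation(data.frame(raw_rating = 101,
                                                flipped = FALSE)),
               "\\[0, 100\\]")
})

screen_trials <- function(scores_by_step, subject_id = "s1", year = 1L,
                          continuum = "beach-peach") {
  steps <- rep(seq_along(scores_by_step), lengths(scores_by_step))
  data.frame(subject_id = subject_id, testing_year = year,
             continuum_id = continuum, step = steps,
             vas_score = unlist(scores_by_step), stringsAsFactors = FALSE)
}

test_that("screening keeps ramping profiles and drops flat ones", {
  ramp <- screen_trials(lapply(seq(5, 95, length.out = 7), rep, times = 4))
  rep1 <- screen_subject_years(ramp)
  expect_true(rep1$kept)
  expect_equal(rep1$reason, "ok")

  flat <- screen_trials(lapply(runif(7, 40, 60), rep, times = 4),
                        subject_id = "s2")
  rep2 <- screen_subject_years(flat)
  expect_false(rep2$kept)
  expect_equal(rep2$reason, "flat")
})

test_that("screening criteria are inclusive at exactly 25 and 75", {
  edge <- screen_trials(lapply(c(25, 50, 75), rep, times = 2))
  rep <- screen_subject_years(edge)
  expect_true(rep$kept)
  # one unit short on either side fails
  low <- screen_trials(lapply(c(26, 50, 75), rep, times = 2))
  expect_false(screen_subject_years(low)$kept)
  high <- screen_trials(lapply(c(25, 50, 74), rep, times = 2))
  expect_false(screen_subject_years(high)$kept)
})

test_that("screening is year-specific for the same participant", {
  good <- lapply(seq(5, 95, length.out = 7), rep, times = 4)
  flat <- lapply(rep(50, 7), rep, times = 4)
  d <- rbind(screen_trials(good, year = 1L), screen_trials(flat, year = 2L),
             screen_trials(good, year = 3L))
  rep <- screen_subject_years(d)
  expect_equal(rep$kept[order(rep$testing_year)], c(TRUE, FALSE, TRUE))
})

test_that("pooled and per-continuum screening can disagree", {
  good <- screen_trials(lapply(seq(0, 100, length.out = 7), rep, times = 4),
                        continuum = "beach-peach")
  flat <- screen_trials(lapply(rep(50, 7), rep, times = 4),
                        continuum = "sip-ship")
  d <- rbind(good, flat)
  expect_true(screen_subject_years(d)$kept)  # pooled means still span 25/75
  expect_false(screen_subject_years(d, per_continuum = TRUE)$kept)
})

test_that("simulated flat responders are screened out", {
  des <- recovery_design(20L)
  tr <- recovery_truth()
  tr$s_mean <- 0; tr$s_sd <- 0; tr$L_mean <- 45; tr$U_mean <- 55
  tr$L_sd <- 1; tr$U_sd <- 1
  tr$rv_mean <- 30  # tight responding around the center
  st <- simulate_study(des, tr, seed = 13, attrition_rate = 0)
  rep <- screen_subject_years(normalize_orientation(st$trials))
  expect_true(all(!rep$kept))
})

test_that("screening errors when an endpoint step has no trials", {
  full <- screen_trials(lapply(c(10, 50, 90), rep, times = 2))
  partial <- screen_trials(lapply(c(10, 50, 90), rep, times = 2),
                           subject_id = "s2")
  expect_error(screen_subject_years(rbind(full, partial[partial$step != 3, ])),
               "endpoint")
})

test_that("assembled year datasets carry contiguous 0-based codes", {
  des <- recovery_design(10L)
  st <- simulate_study(des, recovery_truth(), seed = 17, attrition_rate = 0)
  clean <- normalize_orientation(st$trials)
  screen <- screen_subject_years(clean)
  # force two additional exclusions
  screen$kept[which(screen$kept)[1:2]] <- FALSE
  dropped <- screen$subject_id[!screen$kept]
  n_kept <- sum(screen$kept)
  dat <- assemble_year_dataset(clean, screen, 1L)
  expect_length(attr(dat, "subject_levels"), n_kept)
  expect_false(any(dropped %in% dat$subject_id))
  expect_setequal(unique(dat$subject_index), 0:(n_kept - 1))
  expect_setequal(unique(dat$item_index), 0:1)
  # bijection: each code maps to exactly one id
  expect_equal(nrow(unique(dat[c("subject_id", "subject_index")])), n_kept)

  # re-assembly with one more participant leaves existing scores unchanged
  screen$kept[which(!screen$kept)[1]] <- TRUE
  dat2 <- assemble_year_dataset(clean, screen, 1L)
  common <- intersect(dat$subject_id, dat2$subject_id)
  a <- dat[dat$subject_id %in% common, c("subject_id", "step", "vas_score")]
  b <- dat2[dat2$subject_id %in% common, c("subject_id", "step", "vas_score")]
  expect_equal(a[order(a$subject_id, a$step, a$vas_score), ],
               b[order(b$subject_id, b$step, b$vas_score), ],
               ignore_attr = TRUE)
})

test_that("assembly errors when screening removes everyone", {
  d <- normalize_orientation(data.frame(
    subject_id = "s1", start_grade = 1L, testing_year = 1L, day = 1L,
    continuum_id = "x", step = rep(1:7, 2), raw_rating = 50, flipped = FALSE))
  screen <- screen_subject_years(d)
  expect_error(assemble_year_dataset(d, screen, 1L), "survive screening")
})
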