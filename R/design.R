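#' Accelerated-longitudinal VAS study design
#'
#' Describes the design grid of a longitudinal visual analogue scale (VAS)
#' categorization study: several age cohorts (identified by the school grade
#' in which they enter the study) are each tested yearly, and in every testing
#' year a participant rates each step of each speech continuum several times
#' across two laboratory days. With the defaults (5 continua, 7 steps, 2 days,
#' 2 repetitions) a participant contributes 28 trials per continuum and 140
#' trials per testing year.
#'
#' @param cohorts Integer vector of start grades, one per cohort.
#' @param years Number of testing years each participant is followed.
#' @param continua Character vector of continuum labels (minimal pairs).
#' @param steps Number of continuum steps (>= 2).
#' @param days Laboratory sessions per testing year.
#' @param reps Repetitions of each step per continuum per day.
#' @param subjects_per_cohort Number of participants recruited per cohort.
#' @return An object of class `vas_design` (a validated list).
#' @examples
#' d <- vas_design()
#' trials_per_year(d)  # 140
#' @export
vas_design <- function(cohorts = c(1L, 2L, 3L),
                       years = 4L,
                       continua = c("beach-peach", "time-dime", "net-nut",
                                    "hat-hot", "sip-ship"),
                       steps = 7L,
                       days = 2L,
                       reps = 2L,
                       subjects_per_cohort = 25L) {
  counts <- c(years = years, steps = steps, days = days, reps = reps,
              subjects_per_cohort = subjects_per_cohort,
              n_continua = length(continua), n_cohorts = length(cohorts))
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("all design counts must be positive integers", call. = FALSE)
  }
  if (steps < 2) stop("a continuum needs at least 2 steps", call. = FALSE)
  structure(
    list(cohorts = as.integer(cohorts), years = as.integer(years),
         continua = as.character(continua), steps = as.integer(steps),
         days = as.integer(days), reps = as.integer(reps),
         subjects_per_cohort = as.integer(subjects_per_cohort)),
    class = "vas_design"
  )
}

#' @export
print.vas_design <- function(x, ...) {
  cat("VAS study design:\n")
  cat("  cohorts (start grades):", paste(x$cohorts, collapse = ", "), "\n")
  cat("  testing years:", x$years, "\n")
  cat("  continua:", length(x$continua), "(", paste(x$continua, collapse = ", "), ")\n")
  cat("  steps x days x reps:", x$steps, "x", x$days, "x", x$reps, "\n")
  cat("  subjects per cohort:", x$subjects_per_cohort, "\n")
  cat("  trials per participant-year:", trials_per_year(x), "\n")
  invisible(x)
}

#' Trials per participant-year implied by a design
#'
#' @param design A [vas_design()] object.
#' @return Integer: `steps * days * reps * n_continua`.
#' @export
trials_per_year <- function(design) {
  stopifnot(inherits(design, "vas_design"))
  design$steps * design$days * design$reps * length(design$continua)
}

#' Middle step of the continuum
#'
#' Center used for the variance-profile quadratic: the midpoint of the step
#' range (step 4 for a 7-step continuum).
#' @param design A [vas_design()] object.
#' @return Numeric scalar.
#' @export
mid_step <- function(design) {
  (1 + design$steps) / 2
}

#' Build the trial grid for one participant-year
#'
#' Lays out the unrealized trial coordinates for a single participant in a
#' single testing year: for each continuum and day, a block of
#' `reps * steps` trials in a seeded random order. Endpoint images are placed
#' on a random side on day 1 (per continuum) and swapped on day 2, so exactly
#' half of a participant's blocks for each continuum are orientation-flipped.
#'
#' @param design A [vas_design()] object.
#' @param seed Integer seed controlling block ordering and day-1 orientation.
#' @return A data frame with one row per trial and columns `continuum_id`,
#'   `day`, `step`, `flipped`.
#' @export
build_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "vas_design"))
  set.seed(seed)
  day1_flip <- stats::setNames(sample(c(TRUE, FALSE), length(design$continua),
                                      replace = TRUE), design$continua)
  blocks <- vector("list", length(design$continua) * design$days)
  b <- 0L
  for (cid in design$continua) {
    for (day in seq_len(design$days)) {
      steps <- sample(rep(seq_len(design$steps), design$reps))
      flip <- if (day %% 2L == 1L) day1_flip[[cid]] else !day1_flip[[cid]]
      b <- b + 1L
      blocks[[b]] <- data.frame(continuum_id = cid, day = day, step = steps,
                                flipped = flip, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, blocks)
  rownames(grid) <- NULL
  grid
}
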