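#' Normalize VAS orientation
#'
#' On half the blocks the endpoint pictures sit on opposite sides of the
#' scale, so the recorded rating runs the "wrong way". This transform makes
#' high values always correspond to the top continuum step by subtracting
#' flipped ratings from 100. Applying it twice returns the original ratings
#' (it is an involution).
#'
#' @param trials Data frame of raw trials with at least `raw_rating` and
#'   `flipped` columns (e.g. the `trials` element of a [simulate_study()]
#'   result).
#' @return The input data frame with a `vas_score` column added.
#' @export
normalize_orientation <- function(trials) {
  stopifnot(all(c("raw_rating", "flipped") %in% names(trials)))
  if (any(trials$raw_rating < 0 | trials$raw_rating > 100)) {
    stop("raw ratings must lie in [0, 100]", call. = FALSE)
  }
  trials$vas_score <- ifelse(trials$flipped, 100 - trials$raw_rating,
                             trials$raw_rating)
  trials
}

#' Screen participant-years for minimally valid categorization
#'
#' Computes each participant-year's mean normalized VAS score per continuum
#' step (pooled over continua by default) and keeps the dataset only if the
#' empirical asymptotes reach the screening criteria: the lowest step mean
#' must reach down to `lower` and the highest step mean up to `upper`
#' (inclusive). Flat or inverted responders -- for whom one cannot tell
#' whether the child failed to perceive the endpoints or misunderstood the
#' task -- are excluded. Screening is year-specific: a participant excluded in
#' one testing year is unaffected in other years.
#'
#' @param trials Data frame of orientation-normalized trials (must contain
#'   `vas_score`, `subject_id`, `testing_year`, `step`, `continuum_id`).
#' @param lower,upper Screening criteria on the 0-100 VAS scale.
#' @param per_continuum If `TRUE`, the criteria must hold within every
#'   continuum separately instead of on the pooled step means.
#' @return A `screen_report` data frame with one row per participant-year:
#'   `subject_id`, `testing_year`, `min_step_mean`, `max_step_mean`, `kept`,
#'   `reason`.
#' @export
screen_subject_years <- function(trials, lower = 25, upper = 75,
                                 per_continuum = FALSE) {
  stopifnot("vas_score" %in% names(trials))
  steps <- sort(unique(trials$step))
  ends <- c(min(steps), max(steps))
  key <- interaction(trials$subject_id, trials$testing_year, drop = TRUE)
  out <- lapply(split(trials, key), function(d) {
    present <- unique(d$step)
    if (!all(ends %in% present)) {
      stop(sprintf("participant %s year %d has no trials at an endpoint step",
                   d$subject_id[1], d$testing_year[1]), call. = FALSE)
    }
    eval_block <- function(block) {
      m <- tapply(block$vas_score, block$step, mean)
      c(lo = min(m), hi = max(m))
    }
    if (per_continuum) {
      ranges <- vapply(split(d, d$continuum_id), eval_block, numeric(2))
      lo <- max(ranges["lo", ]); hi <- min(ranges["hi", ])
    } else {
      r <- eval_block(d); lo <- r[["lo"]]; hi <- r[["hi"]]
    }
    low_ok <- lo <= lower
    high_ok <- hi >= upper
    reason <- if (low_ok && high_ok) "ok"
      else if (!low_ok && !high_ok) "flat"
      else if (!low_ok) sprintf("lower asymptote above %g", lower)
      else sprintf("upper asymptote below %g", upper)
    data.frame(subject_id = d$subject_id[1],
               testing_year = d$testing_year[1],
               min_step_mean = lo, max_step_mean = hi,
               kept = low_ok && high_ok, reason = reason,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, out)
  rep <- rep[order(rep$subject_id, rep$testing_year), ]
  rownames(rep) <- NULL
  class(rep) <- c("screen_report", "data.frame")
  rep
}

#' Assemble the model-ready dataset for one testing year
#'
#' Restricts the normalized trials to participant-years that passed screening
#' for the requested testing year and attaches 0-based contiguous integer
#' codes for subjects and items, as required by the hierarchical fit.
#'
#' @param trials Orientation-normalized trial data frame.
#' @param screen A `screen_report` from [screen_subject_years()].
#' @param year Testing year to assemble.
#' @return A data frame with the original columns plus `subject_index` and
#'   `item_index` (0-based), with attributes `subject_levels` and
#'   `item_levels` giving the code-to-id maps and `year` recording the
#'   testing year.
#' @export
assemble_year_dataset <- function(trials, screen, year) {
  kept_ids <- screen$subject_id[screen$kept & screen$testing_year == year]
  d <- trials[trials$testing_year == year & trials$subject_id %in% kept_ids, ]
  if (nrow(d) == 0) {
    stop("no participant-years survive screening for year ", year,
         call. = FALSE)
  }
  subject_levels <- sort(unique(d$subject_id))
  item_levels <- sort(unique(d$continuum_id))
  d$subject_index <- match(d$subject_id, subject_levels) - 1L
  d$item_index <- match(d$continuum_id, item_levels) - 1L
  rownames(d) <- NULL
  attr(d, "subject_levels") <- subject_levels
  attr(d, "item_levels") <- item_levels
  attr(d, "year") <- year
  d
}
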