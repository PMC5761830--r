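#' Extract foraging trips from a presence vector
#'
#' A foraging trip is a maximal run of absence windows. Runs touching the
#' session start or end are flagged as truncated: their true duration is
#' unknown, so they are never classified and never enter statistics; the
#' exclusion stage masks their window span for both pair members.
#'
#' @param present Logical presence vector for one bird-session (gap-free).
#' @param pair_id,session_id,bird_role Identifiers copied into the output.
#' @param bin_minutes Window width in minutes.
#' @return Data frame with one row per trip: `pair_id`, `session_id`,
#'   `bird_role`, `start_window`, `n_windows`, `duration_h`,
#'   `truncated_start`, `truncated_end`, `trip_type` (initially
#'   `"unclassified"`). A bird that never leaves returns zero rows.
#' @export
extract_trips <- function(present, pair_id, session_id, bird_role,
                          bin_minutes = 10) {
  runs <- presence_runs(present)
  ab <- runs[runs$state == "absent", , drop = FALSE]
  n <- length(present)
  out <- data.frame(
    pair_id = rep(as.character(pair_id), nrow(ab)),
    session_id = rep(as.character(session_id), nrow(ab)),
    bird_role = rep(bird_role, nrow(ab)),
    start_window = ab$start_window,
    n_windows = ab$n_windows,
    duration_h = ab$n_windows * bin_minutes / 60,
    truncated_start = ab$start_window == 0L,
    truncated_end = ab$start_window + ab$n_windows == n,
    trip_type = rep("unclassified", nrow(ab)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Estimate the short/long trip cut-off by log-variance minimisation
#'
#' Foraging-trip durations in dual-foraging seabirds are bimodal and
#' log-normal within mode. The cut-off separating short (ST) from long (LT)
#' trips is the value that minimises the sum of the within-class sample
#' variances of natural-log duration. Because that objective is piecewise
#' constant between data points, it is evaluated exactly at the midpoints of
#' consecutive distinct sorted log-durations; ties in the objective resolve to
#' the smallest cut-off.
#'
#' @param durations_h Numeric vector of trip durations in hours (all > 0),
#'   pooled over birds, sessions and years.
#' @param min_class_size Smallest class size allowed on either side of a
#'   candidate split (at least 2, since the variance needs two points).
#' @return An object of class `"cutoff_result"`: a list with `cutoff_h` (the
#'   cut-off in hours, `exp()` of the optimal log split), `cutoff_log`,
#'   `objective` (summed within-class variances at the optimum), `n_short`,
#'   `n_long`, and `candidates`, the full candidate table.
#' @examples
#' estimate_cutoff(c(1, 1, 1, 10, 10, 10))$cutoff_h # exp(mean(log(c(1,10))))
#' @export
estimate_cutoff <- function(durations_h, min_class_size = 2) {
  durations_h <- as.numeric(durations_h)
  if (anyNA(durations_h) || any(durations_h <= 0)) {
    stop("trip durations must be positive and non-missing")
  }
  min_class_size <- as.integer(min_class_size)
  if (min_class_size < 2L) stop("min_class_size must be at least 2")
  if (length(durations_h) < 2L * min_class_size) {
    stop("need at least ", 2L * min_class_size, " trip durations")
  }
  logd <- log(durations_h)
  distinct <- sort(unique(logd))
  if (length(distinct) < 2L) {
    stop("all durations identical; no split exists")
  }
  mids <- (distinct[-1L] + distinct[-length(distinct)]) / 2

  obj <- vapply(mids, function(m) {
    lo <- logd[logd < m]
    hi <- logd[logd >= m]
    if (length(lo) < min_class_size || length(hi) < min_class_size) {
      return(NA_real_)
    }
    stats::var(lo) + stats::var(hi)
  }, 0)

  cand <- data.frame(
    cutoff_log = mids,
    cutoff_h = exp(mids),
    n_short = vapply(mids, function(m) sum(logd < m), 0L),
    n_long = vapply(mids, function(m) sum(logd >= m), 0L),
    objective = obj
  )
  feasible <- which(!is.na(obj))
  if (!length(feasible)) {
    stop("no candidate split leaves at least ", min_class_size,
         " trips in each class")
  }
  best <- feasible[which.min(obj[feasible])]
  structure(
    list(cutoff_h = cand$cutoff_h[best],
         cutoff_log = cand$cutoff_log[best],
         objective = cand$objective[best],
         n_short = cand$n_short[best],
         n_long = cand$n_long[best],
         candidates = cand),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    "<cutoff_result> ST/LT cut-off: %.2f h (log %.3f)\n", x$cutoff_h,
    x$cutoff_log))
  cat(sprintf("  objective (sum of log-variances): %.4f; n_short=%d, n_long=%d\n",
              x$objective, x$n_short, x$n_long))
  invisible(x)
}

#' Classify trips as short or long
#'
#' Durations strictly below the cut-off are short trips (ST); durations at or
#' above it are long trips (LT). Truncated trips stay unclassified. The rule
#' is unit-agnostic as long as trips and cut-off share the unit.
#'
#' @param trips Trip table from [extract_trips()].
#' @param cutoff_h Cut-off in hours (from [estimate_cutoff()] or supplied).
#' @return The trip table with `trip_type` filled in.
#' @export
classify_trips <- function(trips, cutoff_h) {
  if (inherits(cutoff_h, "cutoff_result")) cutoff_h <- cutoff_h$cutoff_h
  if (!is.numeric(cutoff_h) || length(cutoff_h) != 1L || cutoff_h <= 0) {
    stop("cutoff_h must be a single positive number")
  }
  free <- !(trips$truncated_start | trips$truncated_end)
  trips$trip_type <- ifelse(
    free, ifelse(trips$duration_h < cutoff_h, "ST", "LT"), "unclassified")
  trips
}

#' Build an activity timeline from classified trips
#'
#' Present windows become `CO`; each trip's window span takes its class
#' (`ST`/`LT`); truncated trips, whose class is unknowable, are `MASKED`
#' outright.
#'
#' @param present Logical presence vector for the bird-session.
#' @param trips Classified trip table for the same bird-session.
#' @param pair_id,session_id,bird_role Identifiers; default to the values in
#'   `trips` (required explicitly when the bird made no trips).
#' @return An [activity_timeline()].
#' @export
timeline_from_trips <- function(present, trips, pair_id = trips$pair_id[1],
                                session_id = trips$session_id[1],
                                bird_role = trips$bird_role[1]) {
  labels <- rep("CO", length(present))
  if (nrow(trips)) {
    if (any(trips$trip_type == "unclassified" &
            !(trips$truncated_start | trips$truncated_end))) {
      stop("untruncated trips must be classified before building a timeline")
    }
    for (i in seq_len(nrow(trips))) {
      span <- trips$start_window[i] + seq_len(trips$n_windows[i])
      labels[span] <- if (trips$truncated_start[i] || trips$truncated_end[i]) {
        "MASKED"
      } else {
        trips$trip_type[i]
      }
    }
  }
  activity_timeline(pair_id, session_id, bird_role, labels)
}

#' Bundle a pair's two timelines for one observation session
#'
#' @param female,male [activity_timeline()] objects of equal length for the
#'   two pair members.
#' @param female_trips,male_trips Classified trip tables for the two birds.
#' @param bin_minutes Window width in minutes.
#' @param chick_age_days Mean chick age during the session (optional).
#' @param faded_marks Metadata flag: `TRUE` if a colour mark had faded, which
#'   excludes the whole pair-session.
#' @return An object of class `"pair_session"`.
#' @export
pair_session <- function(female, male, female_trips, male_trips,
                         bin_minutes = 10, chick_age_days = NA_real_,
                         faded_marks = FALSE) {
  stopifnot(inherits(female, "activity_timeline"),
            inherits(male, "activity_timeline"))
  if (length(female$labels) != length(male$labels)) {
    stop("pair members must share the session grid")
  }
  structure(
    list(pair_id = female$pair_id, session_id = female$session_id,
         female = female, male = male,
         female_trips = female_trips, male_trips = male_trips,
         n_windows = length(female$labels),
         bin_minutes = as.integer(bin_minutes),
         chick_age_days = chick_age_days,
         faded_marks = isTRUE(faded_marks),
         masked_applied = FALSE, excluded = FALSE,
         exclusion_reasons = character(0)),
    class = "pair_session"
  )
}

#' @export
print.pair_session <- function(x, ...) {
  cat(sprintf("<pair_session> pair %s, session %s: %d windows\n",
              x$pair_id, x$session_id, x$n_windows))
  cat(sprintf("  exclusions applied: %s; excluded: %s%s\n",
              x$masked_applied, x$excluded,
              if (length(x$exclusion_reasons))
                paste0(" (", paste(x$exclusion_reasons, collapse = "; "), ")")
              else ""))
  invisible(x)
}

#' Apply the truncation-masking and desertion exclusion rules
#'
#' Three rules govern which records enter the statistics: (a) any window span
#' covered by a truncated trip is masked in *both* birds' timelines, keeping
#' the two series aligned; (b) a session in which the female fed at most once
#' (one or zero feeding events) is excluded entirely, reflecting female brood
#' desertion late in chick rearing; (c) a session flagged for faded colour
#' marks is excluded. Exclusion is a flag, never a deletion.
#'
#' @param ps A [pair_session()].
#' @param partner_masking If `FALSE` (diagnostic only), a truncated trip masks
#'   the bird's own windows but not the partner's.
#' @return The pair session with masked timelines and the `excluded` flag and
#'   `exclusion_reasons` set.
#' @export
apply_exclusions <- function(ps, partner_masking = TRUE) {
  stopifnot(inherits(ps, "pair_session"))
  n <- ps$n_windows
  mask_of <- function(trips) {
    m <- rep(FALSE, n)
    tr <- trips[trips$truncated_start | trips$truncated_end, , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      m[tr$start_window[i] + seq_len(tr$n_windows[i])] <- TRUE
    }
    m
  }
  mf <- mask_of(ps$female_trips)
  mm <- mask_of(ps$male_trips)
  if (partner_masking) {
    mf <- mm <- mf | mm
  }
  ps$female$labels[mf] <- "MASKED"
  ps$male$labels[mm] <- "MASKED"

  reasons <- character(0)
  n_female_feeds <- nrow(feedings_from_trips(ps$female_trips))
  if (n_female_feeds <= 1L) {
    reasons <- c(reasons, sprintf("female desertion (%d feeding%s)",
                                  n_female_feeds,
                                  if (n_female_feeds == 1L) "" else "s"))
  }
  if (ps$faded_marks) reasons <- c(reasons, "faded colour marks")

  ps$masked_applied <- TRUE
  ps$excluded <- length(reasons) > 0L
  ps$exclusion_reasons <- reasons
  ps
}

#' Derive feeding events from trips
#'
#' The chick is fed at the end of every completed foraging trip (birds return
#' with a full gular pouch), so each trip that does not run past the session
#' end yields exactly one feeding event in the first colony window after the
#' trip.
#'
#' @param trips Trip table for one bird-session (or several, already stacked).
#' @return Data frame of feeding events (`pair_id`, `session_id`, `bird_role`,
#'   `window_index`), sorted by window.
#' @export
feedings_from_trips <- function(trips) {
  keep <- !trips$truncated_end
  ev <- data.frame(
    pair_id = trips$pair_id[keep],
    session_id = trips$session_id[keep],
    bird_role = trips$bird_role[keep],
    window_index = trips$start_window[keep] + trips$n_windows[keep],
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$pair_id, ev$session_id, ev$window_index), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
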