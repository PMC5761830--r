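#' Describe the layout of an observation file
#'
#' Observation files are delimited text with one row per (pair, session, bird,
#' 10-minute window). Column names, the delimiter, how presence is encoded and
#' whether windows are given as 0-based indices or as elapsed clock times are
#' all site-specific, so [read_observations()] takes a dialect object built
#' here. The defaults match the files written by [write_observations()] and
#' [simulate_corpus()].
#'
#' @param delimiter Field separator.
#' @param pair_col,session_col,role_col,window_col,present_col Column names in
#'   the file for the pair identifier, session identifier, bird role
#'   (`"female"`/`"male"`), window, and presence status.
#' @param true_values Character values (case-insensitive) of `present_col`
#'   that mean "bird observed at the colony". Everything else is absence.
#' @param windows_as Either `"index"` (0-based 10-minute window index) or
#'   `"clock"` (elapsed time from session start as `"H:MM"`/`"HH:MM"`, which
#'   must fall on the bin grid).
#' @param implicit_absence If `TRUE`, windows missing from the file are taken
#'   as absences; if `FALSE` (default) a gap in the window coverage is an
#'   error.
#' @param bin_minutes Width of one window in minutes.
#' @return A list of class `"obs_dialect"`.
#' @seealso [read_observations()]
#' @export
obs_dialect <- function(delimiter = ",",
                        pair_col = "pair_id",
                        session_col = "session_id",
                        role_col = "bird_role",
                        window_col = "window_index",
                        present_col = "present",
                        true_values = c("1", "true", "t", "yes", "present"),
                        windows_as = c("index", "clock"),
                        implicit_absence = FALSE,
                        bin_minutes = 10) {
  windows_as <- match.arg(windows_as)
  stopifnot(bin_minutes > 0)
  structure(
    list(delimiter = delimiter, pair_col = pair_col, session_col = session_col,
         role_col = role_col, window_col = window_col,
         present_col = present_col, true_values = tolower(true_values),
         windows_as = windows_as, implicit_absence = implicit_absence,
         bin_minutes = as.integer(bin_minutes)),
    class = "obs_dialect"
  )
}

parse_clock_minutes <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("clock times must be 'H:MM' elapsed from session start; offending: ",
         paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
}

#' Read binned presence/absence observation records
#'
#' Reads a delimited observation file into the canonical record layout used by
#' the rest of the pipeline, and builds one session grid per session. Window
#' coverage must be gap-free for every (pair, session, bird) unless the
#' dialect declares absence implicit, in which case missing windows are filled
#' in as absences.
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect An [obs_dialect()] describing the file layout.
#' @param n_windows Session length in windows. If `NULL`, inferred per session
#'   as one more than the largest window index seen in that session (a
#'   standard 48-h session on a 10-minute grid has 288 windows).
#' @return A list with components `records` (data frame with columns
#'   `pair_id`, `session_id`, `bird_role`, `window_index`, `present`) and
#'   `grids` (data frame with `session_id`, `n_windows`, `bin_minutes`,
#'   `chick_age_days`; chick age is `NA` unless supplied later).
#' @export
read_observations <- function(path, dialect = obs_dialect(), n_windows = NULL) {
  stopifnot(inherits(dialect, "obs_dialect"))
  raw <- utils::read.csv(path, sep = dialect$delimiter,
                         stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(dialect$pair_col, dialect$session_col, dialect$role_col,
              dialect$window_col, dialect$present_col)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("observation file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }

  role <- as.character(raw[[dialect$role_col]])
  bad_role <- setdiff(unique(role), BIRD_ROLES)
  if (length(bad_role)) {
    stop("unknown bird_role value(s): ", paste(bad_role, collapse = ", "),
         " (expected female/male)")
  }

  if (dialect$windows_as == "clock") {
    mins <- parse_clock_minutes(raw[[dialect$window_col]])
    if (any(mins %% dialect$bin_minutes != 0)) {
      stop("clock times do not fall on the ", dialect$bin_minutes,
           "-minute grid")
    }
    window <- as.integer(mins %/% dialect$bin_minutes)
  } else {
    window <- as.integer(raw[[dialect$window_col]])
  }
  if (anyNA(window) || any(window < 0L)) {
    stop("window indices must be non-negative integers")
  }

  pres_raw <- raw[[dialect$present_col]]
  present <- if (is.logical(pres_raw)) {
    pres_raw
  } else {
    tolower(trimws(as.character(pres_raw))) %in% dialect$true_values
  }

  records <- data.frame(
    pair_id = as.character(raw[[dialect$pair_col]]),
    session_id = as.character(raw[[dialect$session_col]]),
    bird_role = role,
    window_index = window,
    present = present,
    stringsAsFactors = FALSE
  )

  key <- paste(records$pair_id, records$session_id, records$bird_role,
               records$window_index, sep = "\r")
  if (anyDuplicated(key)) {
    first_dup <- records[which(duplicated(key))[1L], ]
    stop(sprintf(
      "duplicate observation for (pair %s, session %s, %s, window %d)",
      first_dup$pair_id, first_dup$session_id, first_dup$bird_role,
      first_dup$window_index))
  }

  sessions <- sort(unique(records$session_id))
  grids <- data.frame(
    session_id = sessions,
    n_windows = vapply(sessions, function(s) {
      if (!is.null(n_windows)) as.integer(n_windows)
      else max(records$window_index[records$session_id == s]) + 1L
    }, 1L),
    bin_minutes = dialect$bin_minutes,
    chick_age_days = NA_real_,
    stringsAsFactors = FALSE,
    row.names = NULL
  )

  records <- check_window_coverage(records, grids, dialect$implicit_absence)
  records <- records[order(records$pair_id, records$session_id,
                           records$bird_role, records$window_index), ]
  rownames(records) <- NULL
  list(records = records, grids = grids)
}

check_window_coverage <- function(records, grids, implicit_absence) {
  nw <- stats::setNames(grids$n_windows, grids$session_id)
  bird_key <- paste(records$pair_id, records$session_id, records$bird_role,
                    sep = "\r")
  filled <- lapply(split(records, bird_key), function(df) {
    n <- nw[[df$session_id[1L]]]
    if (any(df$window_index >= n)) {
      stop("window index beyond session length (", n, " windows) for pair ",
           df$pair_id[1L], ", session ", df$session_id[1L])
    }
    gaps <- setdiff(0:(n - 1L), df$window_index)
    if (!length(gaps)) return(df)
    if (!implicit_absence) {
      stop(sprintf(
        "non-contiguous windows for (pair %s, session %s, %s); missing: %s%s",
        df$pair_id[1L], df$session_id[1L], df$bird_role[1L],
        paste(utils::head(gaps, 10L), collapse = ", "),
        if (length(gaps) > 10L) ", ..." else ""))
    }
    rbind(df, data.frame(
      pair_id = df$pair_id[1L], session_id = df$session_id[1L],
      bird_role = df$bird_role[1L], window_index = gaps, present = FALSE,
      stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  out
}

#' Write observation records to a delimited file
#'
#' Writes records in the default dialect (`pair_id, session_id, bird_role,
#' window_index, present` with presence as 0/1) so that
#' `read_observations(write_observations(x))` reproduces `x` exactly.
#'
#' @param records Observation record data frame (see [read_observations()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(records, path) {
  stopifnot(all(c("pair_id", "session_id", "bird_role", "window_index",
                  "present") %in% names(records)))
  out <- records[order(records$pair_id, records$session_id,
                       records$bird_role, records$window_index),
                 c("pair_id", "session_id", "bird_role", "window_index",
                   "present")]
  out$present <- as.integer(out$present)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read chick body-mass records
#'
#' Chick-mass files have columns `pair_id`, `day_of_life`, `mass_g`. In the
#' study design chicks are weighed about every 3 days starting from day 13 or
#' 14 of life; deviations from that cadence are reported as a warning, not an
#' error.
#'
#' @param path CSV file path.
#' @return Data frame with `pair_id`, `day_of_life`, `mass_g`.
#' @export
read_chick_mass <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("pair_id", "day_of_life", "mass_g")
  if (!all(needed %in% names(df))) {
    stop("chick-mass file needs columns: ", paste(needed, collapse = ", "))
  }
  df$pair_id <- as.character(df$pair_id)
  df$day_of_life <- as.integer(df$day_of_life)
  df$mass_g <- as.numeric(df$mass_g)
  if (any(df$mass_g <= 0, na.rm = TRUE)) stop("chick mass must be positive")
  if (any(df$day_of_life < 0, na.rm = TRUE)) stop("day_of_life must be >= 0")
  first_days <- vapply(split(df$day_of_life, df$pair_id), min, 1L)
  if (any(first_days > 14L)) {
    warning("some chicks have no measurement by day 14; ",
            "day 14-16 mass may be missing for them")
  }
  df[order(df$pair_id, df$day_of_life), , drop = FALSE]
}

#' Run-length encode a presence/absence vector
#'
#' Collapses a gap-free logical presence vector into alternating runs of
#' colony presence and absence; absence runs are the raw material for foraging
#' trips. Runs partition `[0, n_windows)` and adjacent runs always differ in
#' state.
#'
#' @param present Logical vector, one element per 10-minute window.
#' @return Data frame with columns `state` (`"present"`/`"absent"`),
#'   `start_window` (0-based) and `n_windows`.
#' @examples
#' presence_runs(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE))
#' @export
presence_runs <- function(present) {
  stopifnot(is.logical(present), length(present) >= 1L, !anyNA(present))
  r <- rle(present)
  ends <- cumsum(r$lengths)
  data.frame(
    state = ifelse(r$values, "present", "absent"),
    start_window = ends - r$lengths,
    n_windows = r$lengths,
    stringsAsFactors = FALSE
  )
}

#' Construct an activity timeline
#'
#' An activity timeline is the per-bird, per-session sequence of 10-minute
#' windows labelled `CO` (at the colony), `ST` (short trip), `LT` (long trip)
#' or `MASKED` (window excluded from analysis, e.g. covered by a truncated
#' trip).
#'
#' @param pair_id,session_id,bird_role Identifiers.
#' @param labels Character vector over windows with values in
#'   `CO`/`ST`/`LT`/`MASKED`.
#' @return An object of class `"activity_timeline"`.
#' @export
activity_timeline <- function(pair_id, session_id, bird_role, labels) {
  if (!all(labels %in% ACTIVITY_LEVELS)) {
    stop("timeline labels must be CO, ST, LT or MASKED")
  }
  if (!bird_role %in% BIRD_ROLES) stop("bird_role must be female or male")
  structure(
    list(pair_id = as.character(pair_id),
         session_id = as.character(session_id),
         bird_role = bird_role,
         labels = as.character(labels)),
    class = "activity_timeline"
  )
}

#' @export
print.activity_timeline <- function(x, ...) {
  tab <- table(factor(x$labels, levels = ACTIVITY_LEVELS))
  cat(sprintf("<activity_timeline> pair %s, session %s, %s: %d windows\n",
              x$pair_id, x$session_id, x$bird_role, length(x$labels)))
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = "  "), "\n",
      sep = "")
  invisible(x)
}
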