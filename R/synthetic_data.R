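#' Parameters for the synthetic colony-attendance generator
#'
#' The defaults emulate the study system: 48-h observation sessions on a
#' 10-minute grid; each bird alternates colony bouts (truncated log-normal,
#' mean 49 min, range 10-80 min) with foraging trips whose durations are
#' log-normal and bimodal (short trips mean 1.9 h, long trips mean 12.8 h);
#' a feeding at the end of every trip; about 25 pairs with 1-5 sessions each
#' (median 3). `meanlog` values are derived from the target arithmetic means,
#' and the colony-bout `meanlog` is solved so that the truncated mean equals
#' `co_mean_min`.
#'
#' `kappa` is the coordination coupling: at each trip start the probability
#' that the trip is long is `p_lt * (1 - kappa * [partner currently on a long
#' trip])`. `kappa = 0` gives independent birds (the null); `kappa = 1`
#' forbids starting a long trip while the partner is on one.
#' `growth_effect_beta` shifts a chick's peak mass down by `beta` times its
#' session-mean inter-feeding-interval CV (default 0: growth independent of
#' coordination).
#'
#' @param n_pairs Number of breeding pairs.
#' @param sessions_per_pair Integer vector recycled over pairs, or `NULL` to
#'   draw 1-5 sessions per pair with median 3 (study-shaped).
#' @param session_hours,bin_minutes Session length and window width.
#' @param st_mean_h,st_sdlog Short-trip duration: arithmetic mean (h) and
#'   log-sd.
#' @param lt_mean_h,lt_sdlog Long-trip duration: arithmetic mean (h) and
#'   log-sd.
#' @param co_mean_min,co_min_min,co_max_min,co_sdlog Colony-bout duration:
#'   truncated log-normal mean and range (min) and log-sd.
#' @param p_lt Baseline probability that the next trip is long.
#' @param kappa Coordination coupling in `[0, 1]`.
#' @param growth_effect_beta Effect of interval CV on chick peak mass (g per
#'   unit CV).
#' @param mass_noise_sd Gaussian measurement noise on chick mass (g).
#' @param seed RNG seed recorded and used by [simulate_corpus()].
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(n_pairs = 25, sessions_per_pair = NULL,
                       session_hours = 48, bin_minutes = 10,
                       st_mean_h = 1.9, st_sdlog = 0.5,
                       lt_mean_h = 12.8, lt_sdlog = 0.4,
                       co_mean_min = 49, co_min_min = 10, co_max_min = 80,
                       co_sdlog = 0.5,
                       p_lt = 0.25, kappa = 0.6, growth_effect_beta = 0,
                       mass_noise_sd = 3, seed = NULL) {
  stopifnot(n_pairs >= 1, session_hours > 0, bin_minutes > 0,
            st_mean_h > 0, lt_mean_h > 0, st_sdlog > 0, lt_sdlog > 0,
            co_min_min > 0, co_max_min > co_min_min,
            co_mean_min > co_min_min, co_mean_min < co_max_min,
            p_lt > 0, p_lt < 1, kappa >= 0, kappa <= 1, mass_noise_sd >= 0)
  co_meanlog <- stats::uniroot(
    function(mu) tlnorm_mean(mu, co_sdlog, co_min_min, co_max_min) -
      co_mean_min,
    lower = log(co_min_min) - 2, upper = log(co_max_min) + 2)$root
  structure(
    list(n_pairs = as.integer(n_pairs),
         sessions_per_pair = sessions_per_pair,
         session_hours = session_hours,
         bin_minutes = as.integer(bin_minutes),
         n_windows = as.integer(round(session_hours * 60 / bin_minutes)),
         st_meanlog = log(st_mean_h) - st_sdlog^2 / 2, st_sdlog = st_sdlog,
         lt_meanlog = log(lt_mean_h) - lt_sdlog^2 / 2, lt_sdlog = lt_sdlog,
         st_mean_h = st_mean_h, lt_mean_h = lt_mean_h,
         co_meanlog = co_meanlog, co_sdlog = co_sdlog,
         co_mean_min = co_mean_min, co_min_min = co_min_min,
         co_max_min = co_max_min,
         p_lt = p_lt, kappa = kappa,
         growth_effect_beta = growth_effect_beta,
         mass_noise_sd = mass_noise_sd, seed = seed),
    class = "sim_params"
  )
}

# mean of a log-normal truncated to [a, b]
tlnorm_mean <- function(mu, sdlog, a, b) {
  za <- (log(a) - mu) / sdlog
  zb <- (log(b) - mu) / sdlog
  exp(mu + sdlog^2 / 2) *
    (stats::pnorm(zb - sdlog) - stats::pnorm(za - sdlog)) /
    (stats::pnorm(zb) - stats::pnorm(za))
}

rtlnorm <- function(n, meanlog, sdlog, a, b) {
  u <- stats::runif(n, stats::plnorm(a, meanlog, sdlog),
                    stats::plnorm(b, meanlog, sdlog))
  stats::qlnorm(u, meanlog, sdlog)
}

draw_co_windows <- function(params) {
  mins <- rtlnorm(1L, params$co_meanlog, params$co_sdlog,
                  params$co_min_min, params$co_max_min)
  max(1L, as.integer(round(mins / params$bin_minutes)))
}

draw_trip_windows <- function(params, long) {
  h <- if (long) stats::rlnorm(1L, params$lt_meanlog, params$lt_sdlog)
       else stats::rlnorm(1L, params$st_meanlog, params$st_sdlog)
  max(1L, as.integer(round(h * 60 / params$bin_minutes)))
}

#' Simulate one pair's 48-h observation session
#'
#' Both birds run an alternating colony-bout/foraging-trip process, jointly
#' simulated in event time from a 24-h lead-in so the session starts
#' mid-behaviour and boundary-truncated trips arise naturally. At every trip
#' start the trip is long with probability
#' `p_lt * (1 - kappa * [partner currently on a long trip])`, short
#' otherwise; all durations are drawn from the configured distributions and
#' rounded to whole windows, so generator and pipeline share the grid
#' resolution.
#'
#' @param params A [sim_params()] object.
#' @param pair_id,session_id Identifiers for the emitted records.
#' @return A list: `records` (observation records for both birds), `truth`
#'   (data frame of true trips with types and truncation flags),
#'   `true_overlap` (ST-while-LT windows under the true types),
#'   `both_lt_windows` (simultaneous-LT windows), and `true_feed_windows`
#'   (pooled true feeding windows).
#' @export
simulate_pair_session <- function(params, pair_id, session_id) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_windows
  lead <- as.integer(round(24 * 60 / params$bin_minutes))
  horizon <- n

  # per-bird growing segment stores; state: next event is CO bout or trip
  t_cur <- c(-lead, -lead)
  seg_type <- list(integer(0), integer(0))  # CODE_CO / CODE_ST / CODE_LT
  seg_start <- list(integer(0), integer(0))
  seg_len <- list(integer(0), integer(0))
  next_is_co <- c(TRUE, TRUE)

  partner_on_lt <- function(i, t) {
    j <- 3L - i
    k <- length(seg_type[[j]])
    k > 0L && t_cur[j] > t && seg_type[[j]][k] == CODE_LT
  }

  while (min(t_cur) < horizon) {
    i <- if (t_cur[1] <= t_cur[2]) 1L else 2L
    t <- t_cur[i]
    if (next_is_co[i]) {
      len <- draw_co_windows(params)
      ty <- CODE_CO
    } else {
      p <- params$p_lt * (1 - params$kappa * partner_on_lt(i, t))
      long <- stats::runif(1L) < p
      len <- draw_trip_windows(params, long)
      ty <- if (long) CODE_LT else CODE_ST
    }
    seg_type[[i]] <- c(seg_type[[i]], ty)
    seg_start[[i]] <- c(seg_start[[i]], t)
    seg_len[[i]] <- c(seg_len[[i]], len)
    t_cur[i] <- t + len
    next_is_co[i] <- !next_is_co[i]
  }

  records <- list()
  truth <- list()
  true_labels <- list()
  for (i in 1:2) {
    role <- BIRD_ROLES[i]
    ty <- seg_type[[i]]
    st <- seg_start[[i]]
    le <- seg_len[[i]]
    en <- st + le
    keep <- en > 0L & st < n
    ty <- ty[keep]; st <- st[keep]; en <- en[keep]

    labels <- rep(CODE_CO, n)
    for (k in seq_along(ty)) {
      if (ty[k] == CODE_CO) next
      span <- (max(st[k], 0L) + 1L):min(en[k], n)
      labels[span] <- ty[k]
    }
    true_labels[[i]] <- labels

    trips <- ty != CODE_CO
    truth[[i]] <- data.frame(
      pair_id = pair_id, session_id = session_id, bird_role = role,
      start_window = pmax(st[trips], 0L),
      n_windows = pmin(en[trips], n) - pmax(st[trips], 0L),
      true_type = ifelse(ty[trips] == CODE_LT, "LT", "ST"),
      true_duration_h = (en[trips] - st[trips]) * params$bin_minutes / 60,
      # a trip flush with a session boundary is observationally truncated:
      # the adjacent colony attendance falls outside the recorded windows
      truncated_start = st[trips] <= 0L,
      truncated_end = en[trips] >= n,
      stringsAsFactors = FALSE
    )
    records[[i]] <- data.frame(
      pair_id = pair_id, session_id = session_id, bird_role = role,
      window_index = 0:(n - 1L),
      present = labels == CODE_CO,
      stringsAsFactors = FALSE
    )
  }

  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  feed <- truth_df$start_window + truth_df$n_windows
  feed <- sort(feed[!truth_df$truncated_end & feed < n])
  list(
    records = do.call(rbind, records),
    truth = truth_df,
    true_overlap = overlap_code(true_labels[[1]], true_labels[[2]]),
    both_lt_windows = sum(true_labels[[1]] == CODE_LT &
                            true_labels[[2]] == CODE_LT),
    true_feed_windows = feed
  )
}

#' Simulate a chick's mass trajectory
#'
#' A saturating (logistic) rise to a peak near day 20 followed by a linear
#' recession to fledging between days 23 and 30, sampled every 3 days from
#' day 13 or 14 with Gaussian measurement noise — the cadence of the field
#' protocol. The peak mass is shifted down by `growth_effect_beta` times the
#' chick's session-mean inter-feeding-interval CV, so a non-zero beta builds
#' a true coordination-to-growth link into the data.
#'
#' @param params A [sim_params()] object.
#' @param pair_id Identifier.
#' @param cv_mean The chick's session-mean inter-feeding-interval CV (used
#'   only when `growth_effect_beta != 0`).
#' @return A list: `masses` (`pair_id`, `day_of_life`, `mass_g`),
#'   `nest_checks` (`pair_id`, `day_of_life`, `chick_present`), and `truth`
#'   (one-row data frame with the noiseless trajectory's peak mass/day on the
#'   measurement grid, fledge day and fledge mass).
#' @export
simulate_chick_growth <- function(params, pair_id, cv_mean = 0) {
  stopifnot(inherits(params, "sim_params"))
  peak_day_true <- sample(18:22, 1L)
  fledge_day <- sample(23:30, 1L)
  asymptote <- stats::rnorm(1L, 150, 8) -
    params$growth_effect_beta * cv_mean
  recession <- max(0, stats::rnorm(1L, 15, 4))
  m_peak <- asymptote / (1 + exp(-(peak_day_true - 8) / 3))
  m_fledge <- min(asymptote - recession, m_peak)

  traj <- function(d) {
    ifelse(d <= peak_day_true,
           asymptote / (1 + exp(-(d - 8) / 3)),
           m_peak - (m_peak - m_fledge) * (d - peak_day_true) /
             (fledge_day - peak_day_true))
  }

  start_day <- sample(13:14, 1L)
  days <- seq(start_day, fledge_day, by = 3L)
  true_mass <- traj(days)
  noise <- stats::rnorm(length(days), 0, params$mass_noise_sd)
  masses <- data.frame(
    pair_id = pair_id, day_of_life = as.integer(days),
    mass_g = pmax(true_mass + noise, 1),
    stringsAsFactors = FALSE
  )
  check_days <- seq(start_day, fledge_day + 3L, by = 3L)
  nest_checks <- data.frame(
    pair_id = pair_id, day_of_life = as.integer(check_days),
    chick_present = check_days < fledge_day,
    stringsAsFactors = FALSE
  )
  peak_idx <- which.max(true_mass)
  truth <- data.frame(
    pair_id = pair_id,
    true_peak_mass = true_mass[peak_idx],
    true_peak_day = as.integer(days[peak_idx]),
    true_fledge_day = as.integer(fledge_day),
    true_fledge_mass = true_mass[length(days)],
    cv_mean = cv_mean,
    stringsAsFactors = FALSE
  )
  list(masses = masses, nest_checks = nest_checks, truth = truth)
}

#' Simulate a study-shaped corpus
#'
#' Generates the full file set the pipeline consumes: observation records for
#' every pair-session, per-session metadata (chick ages), chick-mass and
#' nest-check tables, and the generator's ground truth. Deterministic under
#' `params$seed`.
#'
#' @param params A [sim_params()] object.
#' @param out_dir Optional directory; when given, writes `observations.csv`,
#'   `chick_mass.csv`, `nest_checks.csv`, `session_meta.csv`, `truth.json`
#'   and `params.json` there.
#' @return A list of class `"sim_corpus"`: `records`, `grids`,
#'   `session_meta`, `masses`, `nest_checks`, `truth` (list with `trips`,
#'   `growth`, `session_stats`), and `params`.
#' @export
simulate_corpus <- function(params = sim_params(), out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)

  ns <- if (is.null(params$sessions_per_pair)) {
    sample(1:5, params$n_pairs, replace = TRUE,
           prob = c(0.08, 0.20, 0.36, 0.20, 0.16))
  } else {
    rep_len(params$sessions_per_pair, params$n_pairs)
  }
  age_base <- c(9, 15, 20, 23, 25)

  pair_ids <- sprintf("pair%02d", seq_len(params$n_pairs))
  records <- list()
  meta <- list()
  trips <- list()
  stats_rows <- list()
  masses <- list()
  checks <- list()
  gtruth <- list()

  for (pi in seq_along(pair_ids)) {
    p <- pair_ids[pi]
    cvs <- numeric(0)
    for (j in seq_len(ns[pi])) {
      sid <- sprintf("s%d", j)
      age <- min(max(age_base[j] + round(stats::rnorm(1, 0, 1.5)), 5), 29)
      sim <- simulate_pair_session(params, p, sid)
      records[[length(records) + 1L]] <- sim$records
      trips[[length(trips) + 1L]] <- sim$truth
      meta[[length(meta) + 1L]] <- data.frame(
        pair_id = p, session_id = sid, chick_age_days = age,
        stringsAsFactors = FALSE)
      w <- unique(sim$true_feed_windows)
      cv <- if (length(w) >= 3L) interfeed_cv(diff(w) * params$bin_minutes)
            else NA_real_
      cvs <- c(cvs, cv)
      stats_rows[[length(stats_rows) + 1L]] <- data.frame(
        pair_id = p, session_id = sid, true_overlap = sim$true_overlap,
        both_lt_windows = sim$both_lt_windows, true_cv = cv,
        n_true_feeds = length(w), stringsAsFactors = FALSE)
    }
    growth <- simulate_chick_growth(params, p,
                                    cv_mean = mean(cvs, na.rm = TRUE))
    masses[[pi]] <- growth$masses
    checks[[pi]] <- growth$nest_checks
    gtruth[[pi]] <- growth$truth
  }

  sessions <- sort(unique(unlist(lapply(meta, `[[`, "session_id"))))
  corpus <- structure(
    list(
      records = do.call(rbind, records),
      grids = data.frame(session_id = sessions,
                         n_windows = params$n_windows,
                         bin_minutes = params$bin_minutes,
                         chick_age_days = NA_real_,
                         stringsAsFactors = FALSE),
      session_meta = do.call(rbind, meta),
      masses = do.call(rbind, masses),
      nest_checks = do.call(rbind, checks),
      truth = list(trips = do.call(rbind, trips),
                   growth = do.call(rbind, gtruth),
                   session_stats = do.call(rbind, stats_rows)),
      params = params
    ),
    class = "sim_corpus"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create output directory ", out_dir)
    }
    write_observations(corpus$records, file.path(out_dir, "observations.csv"))
    utils::write.csv(corpus$masses, file.path(out_dir, "chick_mass.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(corpus$nest_checks,
                     file.path(out_dir, "nest_checks.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(corpus$session_meta,
                     file.path(out_dir, "session_meta.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(corpus$truth, file.path(out_dir, "truth.json"),
                         dataframe = "columns", digits = NA)
    jsonlite::write_json(unclass(params), file.path(out_dir, "params.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  corpus
}

#' @export
print.sim_corpus <- function(x, ...) {
  cat(sprintf(
    "<sim_corpus> %d pairs, %d pair-sessions, %d windows/session (kappa=%.2f)\n",
    x$params$n_pairs, nrow(x$session_meta), x$params$n_windows,
    x$params$kappa))
  invisible(x)
}
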