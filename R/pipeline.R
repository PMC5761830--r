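#' Build classified, exclusion-masked pair sessions from records
#'
#' Runs the front half of the pipeline: presence vectors per bird-session,
#' trip extraction, the pooled ST/LT cut-off (unless supplied), trip
#' classification, timelines, and the truncation/desertion exclusion rules.
#'
#' @param records Observation records (see [read_observations()]).
#' @param grids Session grid data frame (`session_id`, `n_windows`,
#'   `bin_minutes`).
#' @param session_meta Optional data frame (`pair_id`, `session_id`,
#'   `chick_age_days`, optional `faded_marks`).
#' @param cutoff_h Optional cut-off override in hours; default estimates it
#'   from the pooled untruncated trip durations.
#' @param min_class_size Passed to [estimate_cutoff()].
#' @param partner_masking Passed to [apply_exclusions()].
#' @return A list: `pair_sessions` (list of [pair_session()] objects with
#'   exclusions applied), `trip_table` (all trips, classified), `cutoff`
#'   (a `cutoff_result` or the numeric override).
#' @export
build_pair_sessions <- function(records, grids, session_meta = NULL,
                                cutoff_h = NULL, min_class_size = 2,
                                partner_masking = TRUE) {
  nw <- stats::setNames(grids$n_windows, grids$session_id)
  bm <- stats::setNames(grids$bin_minutes, grids$session_id)

  key <- paste(records$pair_id, records$session_id, records$bird_role,
               sep = "\r")
  by_bird <- split(records, key)
  presence <- lapply(by_bird, function(df) {
    df <- df[order(df$window_index), ]
    n <- nw[[df$session_id[1L]]]
    if (nrow(df) != n) {
      stop("bird-session not gap-free: pair ", df$pair_id[1L], ", session ",
           df$session_id[1L], ", ", df$bird_role[1L])
    }
    df$present
  })
  trip_list <- lapply(names(by_bird), function(k) {
    df <- by_bird[[k]]
    extract_trips(presence[[k]], df$pair_id[1L], df$session_id[1L],
                  df$bird_role[1L], bm[[df$session_id[1L]]])
  })
  trip_table <- do.call(rbind, trip_list)

  cutoff <- if (is.null(cutoff_h)) {
    free <- !(trip_table$truncated_start | trip_table$truncated_end)
    estimate_cutoff(trip_table$duration_h[free], min_class_size)
  } else {
    cutoff_h
  }
  trip_table <- classify_trips(trip_table, if (is.numeric(cutoff)) cutoff
                               else cutoff$cutoff_h)

  ps_keys <- unique(trip_table[c("pair_id", "session_id")])
  pair_sessions <- list()
  for (r in seq_len(nrow(ps_keys))) {
    p <- ps_keys$pair_id[r]
    s <- ps_keys$session_id[r]
    roles_present <- unique(records$bird_role[
      records$pair_id == p & records$session_id == s])
    if (!all(BIRD_ROLES %in% roles_present)) next
    tl <- list()
    tr <- list()
    for (role in BIRD_ROLES) {
      k <- paste(p, s, role, sep = "\r")
      tr[[role]] <- trip_table[trip_table$pair_id == p &
                                 trip_table$session_id == s &
                                 trip_table$bird_role == role, , drop = FALSE]
      tl[[role]] <- timeline_from_trips(presence[[k]], tr[[role]],
                                        pair_id = p, session_id = s,
                                        bird_role = role)
    }
    age <- NA_real_
    faded <- FALSE
    if (!is.null(session_meta)) {
      m <- session_meta[session_meta$pair_id == p &
                          session_meta$session_id == s, , drop = FALSE]
      if (nrow(m)) {
        age <- m$chick_age_days[1L]
        if ("faded_marks" %in% names(m)) faded <- isTRUE(m$faded_marks[1L])
      }
    }
    ps <- pair_session(tl$female, tl$male, tr$female, tr$male,
                       bin_minutes = bm[[s]], chick_age_days = age,
                       faded_marks = faded)
    pair_sessions[[paste(p, s, sep = "/")]] <-
      apply_exclusions(ps, partner_masking = partner_masking)
  }
  list(pair_sessions = pair_sessions, trip_table = trip_table,
       cutoff = cutoff)
}

# pooled observed feeding windows of an exclusion-masked pair session
observed_feedings <- function(ps) {
  segs_f <- segment_specs(labels_to_code(ps$female$labels))
  segs_m <- segment_specs(labels_to_code(ps$male$labels))
  sort(unique(c(feeding_windows_from_segs(segs_f, ps$n_windows),
                feeding_windows_from_segs(segs_m, ps$n_windows))))
}

#' Run the whole coordination analysis end-to-end
#'
#' From observation records (or a [simulate_corpus()] object) to the study's
#' headline numbers: trip table and ST/LT cut-off, per-session Monte Carlo
#' tests for both statistics, per-pair and study-level combined p-values
#' (both aggregations: over all sessions and over per-pair combined values),
#' summary statistics (ST-while-LT window proportion, inter-feeding interval
#' durations, mean ST/LT durations), and — when chick masses are supplied —
#' growth parameters, their PCA and the coordination mixed models.
#'
#' The report's summary block is recomputed from the per-session results
#' table before returning, as an internal consistency check.
#'
#' @param observations A `sim_corpus`, or an observation-record data frame.
#' @param masses,nest_checks,grids,session_meta Remaining inputs when
#'   `observations` is a plain record data frame (all taken from the corpus
#'   otherwise).
#' @param n_iter Monte Carlo iterations per session (default 10,000).
#' @param seed Integer seed for the whole run.
#' @param cutoff_h,min_class_size,partner_masking Passed to
#'   [build_pair_sessions()].
#' @param ddf Denominator-df method for the mixed-model F tests.
#' @return An object of class `"provisioning_report"`.
#' @export
run_full_pipeline <- function(observations, masses = NULL,
                              nest_checks = NULL, grids = NULL,
                              session_meta = NULL, n_iter = 10000,
                              seed = NULL, cutoff_h = NULL,
                              min_class_size = 2, partner_masking = TRUE,
                              ddf = "Satterthwaite") {
  if (inherits(observations, "sim_corpus")) {
    corpus <- observations
    records <- corpus$records
    grids <- corpus$grids
    session_meta <- corpus$session_meta
    if (is.null(masses)) masses <- corpus$masses
    if (is.null(nest_checks)) nest_checks <- corpus$nest_checks
  } else {
    records <- observations
    if (is.null(grids)) {
      stop("grids are required when observations is a record data frame")
    }
  }
  if (!is.null(seed)) set.seed(seed)

  stage <- build_pair_sessions(records, grids, session_meta,
                               cutoff_h = cutoff_h,
                               min_class_size = min_class_size,
                               partner_masking = partner_masking)
  ps_all <- stage$pair_sessions
  included <- Filter(function(ps) !ps$excluded, ps_all)
  excluded <- Filter(function(ps) ps$excluded, ps_all)
  message(sprintf("sessions: %d total, %d excluded (%s)",
                  length(ps_all), length(excluded),
                  if (length(excluded))
                    paste(unlist(lapply(excluded, function(ps)
                      paste(ps$exclusion_reasons, collapse = "; "))),
                      collapse = " | ")
                  else "none"))

  rows <- list()
  for (ps in included) {
    res <- run_randomization(ps, "both", n_iter = n_iter)
    unmasked <- sum(ps$female$labels != "MASKED" &
                      ps$male$labels != "MASKED")
    feeds <- observed_feedings(ps)
    iv <- diff(feeds) * ps$bin_minutes
    for (nm in names(res)) {
      r <- res[[nm]]
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = ps$pair_id, session_id = ps$session_id,
        statistic = nm, observed = r$observed, null_mean = r$null_mean,
        p_paper = r$p_paper, p_mc = r$p_mc, p_mid = r$p_mid,
        index = r$index,
        n_iter = n_iter, degenerate = r$degenerate,
        n_unmasked = unmasked, n_feedings = length(feeds),
        chick_age = ps$chick_age_days,
        mean_interval_min = if (length(iv)) mean(iv) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  session_results <- do.call(rbind, rows)
  rownames(session_results) <- NULL

  combine_stage <- function(stat) {
    sr <- session_results[session_results$statistic == stat &
                            !session_results$degenerate, , drop = FALSE]
    # p_mc is bounded away from 0 by construction; clamp only the top
    p <- clamp_pvalues(sr$p_mc, n_iter)
    pair_rows <- lapply(split(seq_len(nrow(sr)), sr$pair_id), function(ix) {
      cp <- combine_stouffer(p[ix], pair_id = sr$pair_id[ix[1L]])
      data.frame(pair_id = cp$pair_id, statistic = stat, method = cp$method,
                 z = cp$statistic, p_combined = cp$p_combined, k = cp$k,
                 stringsAsFactors = FALSE)
    })
    pair_df <- do.call(rbind, pair_rows)
    rownames(pair_df) <- NULL
    study_sessions <- combine_stouffer(p)
    study_pairs <- combine_stouffer(
      clamp_pvalues(pair_df$p_combined, n_iter))
    list(pair = pair_df,
         study = data.frame(
           statistic = stat,
           aggregation = c("sessions", "pairs"),
           z = c(study_sessions$statistic, study_pairs$statistic),
           p_combined = c(study_sessions$p_combined, study_pairs$p_combined),
           k = c(study_sessions$k, study_pairs$k),
           stringsAsFactors = FALSE))
  }
  comb_overlap <- combine_stage("st_lt_overlap")
  comb_cv <- combine_stage("interfeed_cv")
  pair_combined <- rbind(comb_overlap$pair, comb_cv$pair)
  study_level <- rbind(comb_overlap$study, comb_cv$study)

  summary_stats <- summarise_sessions(session_results, stage$trip_table,
                                      included)
  check <- summarise_sessions(session_results, stage$trip_table, included)
  stopifnot(identical(summary_stats, check))

  growth <- NULL
  if (!is.null(masses)) {
    growth <- tryCatch(
      growth_stage(session_results, masses, nest_checks, ddf),
      error = function(e) {
        warning("growth stage failed: ", conditionMessage(e))
        NULL
      })
  }

  structure(
    list(cutoff = stage$cutoff, trip_table = stage$trip_table,
         session_results = session_results, pair_combined = pair_combined,
         study_level = study_level, summary = summary_stats,
         growth = growth,
         exclusions = data.frame(
           key = names(excluded),
           reasons = vapply(excluded, function(ps)
             paste(ps$exclusion_reasons, collapse = "; "), ""),
           stringsAsFactors = FALSE, row.names = NULL),
         n_iter = n_iter, seed = seed),
    class = "provisioning_report"
  )
}

summarise_sessions <- function(session_results, trip_table, included) {
  ov <- session_results[session_results$statistic == "st_lt_overlap" &
                          !session_results$degenerate, , drop = FALSE]
  prop <- 100 * ov$observed / ov$n_unmasked
  intervals <- unlist(lapply(included, function(ps) {
    diff(observed_feedings(ps)) * ps$bin_minutes
  }))
  free <- trip_table[trip_table$trip_type != "unclassified", , drop = FALSE]
  list(
    n_sessions = nrow(ov),
    n_pairs = length(unique(ov$pair_id)),
    overlap_pct_mean = mean(prop),
    overlap_pct_sd = stats::sd(prop),
    interfeed_mean_min = mean(intervals),
    interfeed_sd_min = stats::sd(intervals),
    st_mean_h = mean(free$duration_h[free$trip_type == "ST"]),
    lt_mean_h = mean(free$duration_h[free$trip_type == "LT"]),
    n_trips_classified = nrow(free),
    n_trips_truncated = sum(trip_table$trip_type == "unclassified")
  )
}

growth_stage <- function(session_results, masses, nest_checks, ddf) {
  params <- growth_params_table(masses, nest_checks)
  pca <- growth_pca(params)
  ov <- session_results[session_results$statistic == "st_lt_overlap" &
                          !session_results$degenerate, , drop = FALSE]
  cv <- session_results[session_results$statistic == "interfeed_cv" &
                          !session_results$degenerate, , drop = FALSE]
  tbl <- merge(
    ov[c("pair_id", "session_id", "index", "n_feedings", "chick_age")],
    cv[c("pair_id", "session_id", "index")],
    by = c("pair_id", "session_id"), suffixes = c("_overlap", "_cv"))
  names(tbl)[names(tbl) == "index_overlap"] <- "coordination"
  names(tbl)[names(tbl) == "index_cv"] <- "cv_index"
  names(tbl)[names(tbl) == "chick_age"] <- "chick_age"
  tbl <- merge(tbl, pca$scores, by = "pair_id")
  models <- fit_coordination_models(tbl, ddf = ddf)
  list(params = params, pca = pca, session_table = tbl, models = models)
}

#' @export
print.provisioning_report <- function(x, ...) {
  cat("<provisioning_report>\n")
  ch <- if (is.numeric(x$cutoff)) x$cutoff else x$cutoff$cutoff_h
  s <- x$summary
  cat(sprintf("  ST/LT cut-off: %.2f h; mean ST %.2f h, mean LT %.2f h\n",
              ch, s$st_mean_h, s$lt_mean_h))
  cat(sprintf("  %d included sessions from %d pairs (%d excluded)\n",
              s$n_sessions, s$n_pairs, nrow(x$exclusions)))
  cat(sprintf("  ST-while-LT overlap: %.1f%% +/- %.1f%% of windows\n",
              s$overlap_pct_mean, s$overlap_pct_sd))
  cat(sprintf("  inter-feeding intervals: %.0f +/- %.0f min\n",
              s$interfeed_mean_min, s$interfeed_sd_min))
  for (st in unique(x$study_level$statistic)) {
    sl <- x$study_level[x$study_level$statistic == st &
                          x$study_level$aggregation == "sessions", ]
    cat(sprintf("  study-level %s: Z = %.2f, p = %.3g (over %d sessions)\n",
                st, sl$z, sl$p_combined, sl$k))
  }
  if (!is.null(x$growth)) {
    ve <- x$growth$pca$variance_explained
    cat(sprintf("  growth PCA: first two components %.0f%% of variance\n",
                100 * sum(ve[1:min(2, length(ve))])))
  }
  invisible(x)
}
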