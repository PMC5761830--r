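# trips table straight from a label vector with no truncated runs
trips_from_labels <- function(labels, role, pair = "p1", sess = "s1") {
  r <- rle(labels)
  e <- cumsum(r$lengths)
  s <- e - r$lengths
  k <- r$values != "CO"
  data.frame(
    pair_id = rep(pair, sum(k)), session_id = rep(sess, sum(k)),
    bird_role = rep(role, sum(k)),
    start_window = s[k], n_windows = r$lengths[k],
    duration_h = r$lengths[k] / 6,
    truncated_start = rep(FALSE, sum(k)), truncated_end = rep(FALSE, sum(k)),
    trip_type = r$values[k], stringsAsFactors = FALSE
  )
}

# pair_session from two aligned label vectors, bypassing the desertion rule
# so that micro-instances (single-trip birds) remain usable
ps_from_labels <- function(f, m, pair = "p1", sess = "s1") {
  stopifnot(length(f) == length(m))
  ps <- pair_session(
    activity_timeline(pair, sess, "female", f),
    activity_timeline(pair, sess, "male", m),
    trips_from_labels(f, "female", pair, sess),
    trips_from_labels(m, "male", pair, sess)
  )
  ps$masked_applied <- TRUE
  ps
}

string_key <- function(strings) {
  paste(strings$category, strings$n_windows, sep = ":", collapse = "|")
}

# one simulated, classified, exclusion-masked pair session (or NULL if the
# session came out excluded/degenerate)
sim_session_ps <- function(params, cutoff_h = 7.1, pair = "p1",
                           sess = "s1") {
  sim <- simulate_pair_session(params, pair, sess)
  by_role <- split(sim$records, sim$records$bird_role)
  tl <- list()
  tr <- list()
  for (role in names(by_role)) {
    df <- by_role[[role]][order(by_role[[role]]$window_index), ]
    trips <- classify_trips(
      extract_trips(df$present, pair, sess, role), cutoff_h)
    tr[[role]] <- trips
    tl[[role]] <- timeline_from_trips(df$present, trips, pair, sess, role)
  }
  ps <- pair_session(tl$female, tl$male, tr$female, tr$male)
  ps <- apply_exclusions(ps)
  if (ps$excluded) return(NULL)
  ps
}
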