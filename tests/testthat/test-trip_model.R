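test_that("trips are extracted with correct spans and truncation flags", {
  tr <- extract_trips(c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                      "p1", "s1", "female")
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$start_window, 2L)
  expect_equal(tr$n_windows, 3L)
  expect_equal(tr$duration_h, 0.5)
  expect_false(tr$truncated_start)
  expect_false(tr$truncated_end)

  tr2 <- extract_trips(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE),
                       "p1", "s1", "male")
  expect_true(tr2$truncated_start)
  expect_false(tr2$truncated_end)

  expect_equal(nrow(extract_trips(rep(TRUE, 12), "p1", "s1", "female")), 0L)
})

test_that("zero-variance clusters give the symmetric midpoint cut-off", {
  res <- estimate_cutoff(c(1, 1, 1, 10, 10, 10))
  expect_equal(res$objective, 0)
  expect_equal(res$cutoff_h, exp(mean(log(c(1, 10)))), tolerance = 1e-12)
  expect_equal(res$n_short, 3L)
  expect_equal(res$n_long, 3L)
})

test_that("cut-off equals an exhaustive brute-force scan", {
  # independent oracle: evaluate the objective from first principles at every
  # midpoint of consecutive distinct sorted log-durations
  brute_cutoff <- function(d, mcs = 2) {
    ld <- sort(log(d))
    u <- unique(ld)
    best <- list(obj = Inf, cut = NA)
    for (i in seq_len(length(u) - 1)) {
      cand <- (u[i] + u[i + 1]) / 2
      lo <- ld[ld < cand]
      hi <- ld[ld >= cand]
      if (length(lo) < mcs || length(hi) < mcs) next
      v <- function(x) sum((x - mean(x))^2) / (length(x) - 1)
      obj <- v(lo) + v(hi)
      if (obj < best$obj) best <- list(obj = obj, cut = exp(cand))
    }
    best
  }
  for (seed in 1:4) {
    set.seed(seed)
    d <- c(rlnorm(200, log(1.9), 0.5), rlnorm(100, log(12.8), 0.4))
    res <- estimate_cutoff(d)
    oracle <- brute_cutoff(d)
    expect_equal(res$cutoff_h, oracle$cut, tolerance = 1e-12)
    expect_equal(res$objective, oracle$obj, tolerance = 1e-12)
  }
})

test_that("perfectly separated clusters put the cut-off strictly between", {
  set.seed(8)
  d <- c(runif(20, 0.5, 2), runif(20, 10, 14))
  res <- estimate_cutoff(d)
  expect_gt(res$cutoff_h, 2)
  expect_lt(res$cutoff_h, 10)
})

test_that("cut-off estimation rejects degenerate inputs", {
  expect_error(estimate_cutoff(c(1, 2, 3)), "at least 4")
  expect_error(estimate_cutoff(rep(2, 10)), "identical")
  expect_error(estimate_cutoff(c(1, 2, -1, 4)), "positive")
})

test_that("classification uses the strict-below rule and is unit-invariant", {
  tr <- data.frame(duration_h = c(1.9, 12.8, 7.1),
                   truncated_start = FALSE, truncated_end = FALSE,
                   trip_type = "unclassified")
  out <- classify_trips(tr, 7.1)
  expect_equal(out$trip_type, c("ST", "LT", "LT"))  # tie goes to LT

  tr_min <- tr
  tr_min$duration_h <- tr$duration_h * 60
  expect_equal(classify_trips(tr_min, 7.1 * 60)$trip_type, out$trip_type)

  tr$truncated_end <- c(FALSE, TRUE, FALSE)
  expect_equal(classify_trips(tr, 7.1)$trip_type[2], "unclassified")
  expect_error(classify_trips(tr, -1), "positive")
})

test_that("truncated-trip spans are masked for both pair members", {
  # male start-truncated over windows 0-11; female clean
  f <- c(rep(TRUE, 20), rep(FALSE, 6), rep(TRUE, 10))
  m <- c(rep(FALSE, 12), rep(TRUE, 10), rep(FALSE, 6), rep(TRUE, 8))
  ft <- classify_trips(extract_trips(f, "p1", "s1", "female"), 1.5)
  mt <- classify_trips(extract_trips(m, "p1", "s1", "male"), 1.5)
  ps <- pair_session(
    timeline_from_trips(f, ft), timeline_from_trips(m, mt), ft, mt)
  ps <- apply_exclusions(ps)
  expect_true(all(ps$female$labels[1:12] == "MASKED"))
  expect_true(all(ps$male$labels[1:12] == "MASKED"))
  expect_identical(ps$female$labels == "MASKED", ps$male$labels == "MASKED")

  # without partner masking only the male is masked
  ps2 <- pair_session(
    timeline_from_trips(f, ft), timeline_from_trips(m, mt), ft, mt)
  ps2 <- apply_exclusions(ps2, partner_masking = FALSE)
  expect_true(all(ps2$female$labels[1:12] != "MASKED"))
})

test_that("female desertion and faded marks exclude the pair-session", {
  f_gone <- rep(TRUE, 36)  # female never leaves: zero feedings
  m <- c(rep(TRUE, 6), rep(FALSE, 6), rep(TRUE, 6), rep(FALSE, 6),
         rep(TRUE, 12))
  ft <- classify_trips(extract_trips(f_gone, "p1", "s1", "female"), 1.5)
  mt <- classify_trips(extract_trips(m, "p1", "s1", "male"), 1.5)
  ps <- apply_exclusions(pair_session(
    timeline_from_trips(f_gone, ft, "p1", "s1", "female"),
    timeline_from_trips(m, mt), ft, mt))
  expect_true(ps$excluded)
  expect_match(ps$exclusion_reasons, "desertion")

  # clean session with >= 2 female feedings stays included and unchanged
  f <- m
  ft <- classify_trips(extract_trips(f, "p1", "s1", "female"), 1.5)
  ps2 <- apply_exclusions(pair_session(
    timeline_from_trips(f, ft, "p1", "s1", "female"),
    timeline_from_trips(m, mt), ft, mt))
  expect_false(ps2$excluded)
  expect_false(any(ps2$female$labels == "MASKED"))

  ps3 <- apply_exclusions(pair_session(
    timeline_from_trips(f, ft, "p1", "s1", "female"),
    timeline_from_trips(m, mt), ft, mt, faded_marks = TRUE))
  expect_true(ps3$excluded)
  expect_match(paste(ps3$exclusion_reasons, collapse = " "), "faded")
})

test_that("feeding events sit in the first colony window after each trip", {
  pr <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  tr <- extract_trips(pr, "p1", "s1", "female")
  ev <- feedings_from_trips(tr)
  expect_equal(ev$window_index, 5L)

  pr_end <- c(TRUE, TRUE, FALSE, FALSE)
  tr_end <- extract_trips(pr_end, "p1", "s1", "female")
  expect_equal(nrow(feedings_from_trips(tr_end)), 0L)
})

test_that("extracted trips match the generator's ground truth", {
  co <- simulate_corpus(sim_params(n_pairs = 3, seed = 77))
  key <- function(df) paste(df$pair_id, df$session_id, df$bird_role,
                            sep = "\r")
  by_bird <- split(co$records, key(co$records))
  for (k in names(by_bird)) {
    df <- by_bird[[k]][order(by_bird[[k]]$window_index), ]
    tr <- extract_trips(df$present, df$pair_id[1], df$session_id[1],
                        df$bird_role[1])
    tru <- co$truth$trips[key(co$truth$trips) == k, ]
    expect_equal(tr$start_window, tru$start_window)
    expect_equal(tr$n_windows, tru$n_windows)
    expect_equal(tr$truncated_start, tru$truncated_start)
    expect_equal(tr$truncated_end, tru$truncated_end)
    # untruncated trips carry their true duration
    free <- !(tr$truncated_start | tr$truncated_end)
    expect_equal(tr$duration_h[free], tru$true_duration_h[free])
  }
})
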