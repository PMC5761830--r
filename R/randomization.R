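## Monte Carlo randomization engine.
##
## The shuffling unit is the activity string: a maximal run of consecutive
## windows sharing one category (CO, ST or LT). A colony attendance series is
## strictly alternating — every foraging trip ends at the colony, so exactly
## one CO string separates consecutive trip strings — and a shuffle preserves
## that skeleton: trip strings are permuted uniformly among the trip
## positions and CO strings uniformly among the CO positions, all sampled
## without replacement. Keeping the skeleton (including whether the series
## begins/ends with a CO string) makes the observed series exchangeable with
## the null draws whenever trip types and durations are sequentially
## independent, which is what the test assumes under its null; randomising
## the skeleton as well (e.g. scattering boundary CO strings) would make the
## null more positionally dispersed than any alternation process can be and
## anti-conservative for the overlap statistic. Every shuffle conserves the
## multiset of strings, per-category window totals and the series length.
## Masked spans (truncated trips and their partner's concurrent records) are
## excised first: they split the session into sub-series that are shuffled
## separately and re-placed in their original slots, so shuffled trips never
## bleed across excluded spans.

labels_to_code <- function(labels) {
  code <- match(labels, ACTIVITY_LEVELS)  # CO=1, ST=2, LT=3, MASKED=4
  code[code == 4L] <- CODE_MASKED
  code
}

# maximal unmasked spans of a coded timeline, each run-length encoded
segment_specs <- function(code) {
  r <- rle(code != CODE_MASKED)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based
  segs <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    span <- (starts[i] + 1L):ends[i]
    rl <- rle(code[span])
    segs[[length(segs) + 1L]] <- list(start = starts[i], cat = rl$values,
                                      len = rl$lengths)
  }
  segs
}

# shuffle one segment's strings, preserving the alternation skeleton:
# trip strings permuted among trip positions, CO strings among CO positions;
# cat/len are parallel vectors (category codes / window counts)
shuffle_cl <- function(cat, len) {
  is_trip <- cat != CODE_CO
  t_idx <- which(is_trip)
  c_idx <- which(!is_trip)
  ord <- seq_along(cat)
  if (length(t_idx) > 1L) ord[t_idx] <- t_idx[sample.int(length(t_idx))]
  if (length(c_idx) > 1L) ord[c_idx] <- c_idx[sample.int(length(c_idx))]
  list(cat = cat[ord], len = len[ord])
}

#' Run-length encode a timeline into activity strings
#'
#' Converts a timeline's label sequence into its ordered list of activity
#' strings — the units the randomization shuffles. The timeline must contain
#' no `MASKED` windows: masked spans are excised beforehand, splitting the
#' series (see [run_randomization()]).
#'
#' @param x An [activity_timeline()] or a character label vector.
#' @return Data frame with columns `category` (`CO`/`ST`/`LT`) and
#'   `n_windows`; concatenating the strings reproduces the input.
#' @export
timeline_to_strings <- function(x) {
  labels <- if (inherits(x, "activity_timeline")) x$labels else x
  if (any(labels == "MASKED")) {
    stop("timeline contains MASKED windows; excise masked spans first")
  }
  r <- rle(labels)
  data.frame(category = r$values, n_windows = r$lengths,
             stringsAsFactors = FALSE)
}

#' Shuffle activity strings under the between-trip CO constraint
#'
#' One random draw from the null used by the coordination tests: trip strings
#' are permuted uniformly among the trip positions and CO strings uniformly
#' among the CO positions, all sampled without replacement. The alternation
#' skeleton is preserved — every pair of consecutive trip strings keeps
#' exactly one (randomly sampled) CO string between them, and the series
#' keeps its boundary structure — so each draw is a new admissible colony
#' attendance series with the same string pool, and an observed series
#' generated by any sequentially independent alternation process is
#' exchangeable with the draws.
#'
#' @param strings Data frame from [timeline_to_strings()], in series order.
#' @return A data frame of the same shape: same multiset of strings, new
#'   order.
#' @export
shuffle_strings <- function(strings) {
  stopifnot(all(c("category", "n_windows") %in% names(strings)))
  cat <- match(strings$category, ACTIVITY_LEVELS)
  if (anyNA(cat) || any(cat == 4L)) stop("categories must be CO, ST or LT")
  if (all(cat == CODE_CO)) {
    warning("no trip strings to shuffle; returning CO strings in random order")
  }
  s <- shuffle_cl(cat, as.integer(strings$n_windows))
  data.frame(category = ACTIVITY_LEVELS[s$cat], n_windows = s$len,
             stringsAsFactors = FALSE)
}

#' Count ST-while-LT overlap windows
#'
#' The coordination statistic: the number of 10-minute windows in which one
#' pair member is on a short trip while the other is on a long trip (in
#' either role assignment). Windows masked for either bird contribute
#' nothing.
#'
#' @param a,b Aligned [activity_timeline()] objects or label vectors of equal
#'   length.
#' @return Integer count.
#' @export
st_lt_overlap <- function(a, b) {
  la <- if (inherits(a, "activity_timeline")) a$labels else a
  lb <- if (inherits(b, "activity_timeline")) b$labels else b
  if (length(la) != length(lb)) stop("timelines differ in length")
  sum((la == "ST" & lb == "LT") | (la == "LT" & lb == "ST"))
}

overlap_code <- function(ca, cb) {
  sum((ca == CODE_ST & cb == CODE_LT) | (ca == CODE_LT & cb == CODE_ST))
}

# interval CV of a pooled (possibly duplicated, unsorted) set of feeding
# windows; coincident events collapse; NA below 3 distinct events
cv_of_windows <- function(w) {
  if (length(w) > 1L) {
    w <- sort.int(w)
    w <- w[c(TRUE, diff(w) != 0L)]
  }
  if (length(w) < 3L) return(NA_real_)
  iv <- diff(w)
  m <- mean(iv)
  sqrt(sum((iv - m)^2) / (length(iv) - 1)) / m
}

#' Build a feeding series for one nest
#'
#' Pools the feeding events of both parents at one nest and derives the
#' inter-feeding intervals. Two parents can return within the same 10-minute
#' window; such coincident events collapse to a single time point so that all
#' intervals are positive.
#'
#' @param event_windows Integer window indices of feeding events (both
#'   parents pooled).
#' @param pair_id,session_id Identifiers.
#' @param bin_minutes Window width in minutes.
#' @return Object of class `"feeding_series"` with sorted unique
#'   `event_windows` and `intervals_min`.
#' @export
feeding_series <- function(event_windows, pair_id = NA_character_,
                           session_id = NA_character_, bin_minutes = 10) {
  w <- sort(unique(as.integer(event_windows)))
  structure(
    list(pair_id = pair_id, session_id = session_id, event_windows = w,
         intervals_min = diff(w) * bin_minutes),
    class = "feeding_series"
  )
}

#' Coefficient of variation of inter-feeding intervals
#'
#' The evenness statistic: sample standard deviation of the inter-feeding
#' intervals divided by their mean. Low values mean the chick is fed at a
#' steady rhythm. Needs at least three feeding events (two intervals); the CV
#' is scale-invariant, so the interval unit does not matter.
#'
#' @param x A [feeding_series()] or a numeric vector of intervals.
#' @return The coefficient of variation.
#' @export
interfeed_cv <- function(x) {
  iv <- if (inherits(x, "feeding_series")) x$intervals_min else as.numeric(x)
  if (length(iv) < 2L) {
    stop("interfeed_cv needs at least 2 intervals (3 feeding events)")
  }
  stats::sd(iv) / mean(iv)
}

# 0-based end windows of all trips in a segment list; a trip feeds iff its
# end lies inside the session (an end flush with the session boundary would
# be a truncated trip)
feeding_windows_from_segs <- function(segs, n_windows) {
  ends <- unlist(lapply(segs, function(s) {
    e <- s$start + cumsum(s$len)
    e[s$cat != CODE_CO]
  }))
  if (is.null(ends)) ends <- integer(0)
  sort(ends[ends < n_windows])
}

count_trips <- function(segs) {
  sum(vapply(segs, function(s) sum(s$cat != CODE_CO), 0L))
}

new_randomization_result <- function(statistic_name, observed, null_samples,
                                     tail, n_iter, seed, degenerate = FALSE) {
  valid <- null_samples[!is.na(null_samples)]
  if (degenerate || !length(valid) || is.na(observed)) {
    res <- list(statistic_name = statistic_name, observed = observed,
                null_samples = null_samples, null_mean = NA_real_,
                p_paper = NA_real_, p_mc = NA_real_, p_mid = NA_real_,
                index = NA_real_,
                tail = tail, n_iter = n_iter, seed = seed, degenerate = TRUE)
    return(structure(res, class = "randomization_result"))
  }
  n_val <- length(valid)
  n_beyond <- if (tail == "greater") sum(valid > observed)
              else sum(valid < observed)
  n_tie <- sum(valid == observed)
  null_mean <- mean(valid)
  structure(
    list(statistic_name = statistic_name, observed = observed,
         null_samples = null_samples, null_mean = null_mean,
         # strictly-beyond proportion: fidelity to the "higher than" rule
         p_paper = n_beyond / n_val,
         # standard valid Monte Carlo p: ties count, observed counts itself
         p_mc = (n_beyond + n_tie + 1) / (n_val + 1),
         # mid-p: half the tie mass; its size is alpha under exchangeability
         p_mid = (n_beyond + 0.5 * n_tie) / n_val,
         index = if (null_mean != 0) (observed - null_mean) / null_mean
                 else NA_real_,
         tail = tail, n_iter = n_iter, seed = seed, degenerate = FALSE),
    class = "randomization_result"
  )
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("<randomization_result> %s (%s tail, %d iterations)\n",
              x$statistic_name, x$tail, x$n_iter))
  if (x$degenerate) {
    cat("  degenerate session: no p-value\n")
  } else {
    cat(sprintf("  observed %.4g, null mean %.4g, index %+.3f\n",
                x$observed, x$null_mean, x$index))
    cat(sprintf(
      "  p = %.4g (strict tail), %.4g (Monte Carlo), %.4g (mid-p)\n",
      x$p_paper, x$p_mc, x$p_mid))
  }
  invisible(x)
}

#' Monte Carlo randomization test for one pair-session
#'
#' Shuffles both birds' activity-string series independently (default 10,000
#' times), rebuilds the aligned timelines after every shuffle and recomputes
#' the test statistic, giving its null distribution for this pair-session.
#' The alternative is one-tailed: strictly greater for `st_lt_overlap`
#' (coordination means more overlap than chance), strictly lower for
#' `interfeed_cv` (evenness means a lower CV than chance).
#'
#' Because the statistics are discrete, tie handling matters and three
#' p-values are reported: `p_paper`, the proportion of null values strictly
#' beyond the observed one (the literal "higher than" rule, anti-conservative
#' under heavy ties); `p_mc`, the standard valid Monte Carlo p-value
#' `(n_beyond + n_tie + 1)/(n + 1)` in which ties count and the observed
#' arrangement counts itself (never anti-conservative under exchangeability;
#' used for downstream combination); and `p_mid`, the mid-p that counts half
#' the tie mass and whose rejection rate equals the nominal level under
#' exchangeability (the calibration reference). The coordination index is
#' `(observed - null_mean)/null_mean`.
#'
#' For `interfeed_cv`, feeding events are re-derived from the shuffled trip
#' ends of both birds and pooled, exactly as for the observed series.
#'
#' @param ps A [pair_session()] with exclusions applied and not excluded.
#' @param statistic `"st_lt_overlap"`, `"interfeed_cv"` or `"both"` (one set
#'   of shuffles scoring both statistics).
#' @param n_iter Number of shuffles.
#' @param seed Optional integer seed for reproducibility.
#' @return A `randomization_result`, or for `statistic = "both"` a named list
#'   of two.
#' @export
run_randomization <- function(ps,
                              statistic = c("st_lt_overlap", "interfeed_cv",
                                            "both"),
                              n_iter = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ps, "pair_session"))
  if (!ps$masked_applied) {
    stop("apply_exclusions() must run before the randomization")
  }
  if (ps$excluded) {
    stop("pair-session is excluded (", paste(ps$exclusion_reasons,
                                             collapse = "; "), ")")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 1L) stop("n_iter must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  n <- ps$n_windows
  code_f <- labels_to_code(ps$female$labels)
  code_m <- labels_to_code(ps$male$labels)
  segs_f <- segment_specs(code_f)
  segs_m <- segment_specs(code_m)

  do_overlap <- statistic %in% c("st_lt_overlap", "both")
  do_cv <- statistic %in% c("interfeed_cv", "both")

  degenerate <- count_trips(segs_f) == 0L || count_trips(segs_m) == 0L
  obs_overlap <- overlap_code(code_f, code_m)
  obs_feeds <- sort(c(feeding_windows_from_segs(segs_f, n),
                      feeding_windows_from_segs(segs_m, n)))
  obs_cv <- cv_of_windows(obs_feeds)
  cv_degenerate <- degenerate || is.na(obs_cv)
  if (degenerate) {
    warning("degenerate session: a bird has no usable trips; no p-value")
  }

  null_overlap <- if (do_overlap) rep(NA_real_, n_iter) else NULL
  null_cv <- if (do_cv) rep(NA_real_, n_iter) else NULL

  if (!degenerate) {
    spans_f <- lapply(segs_f, function(s) (s$start + 1L):(s$start +
                                                            sum(s$len)))
    spans_m <- lapply(segs_m, function(s) (s$start + 1L):(s$start +
                                                            sum(s$len)))
    shuffle_bird <- function(code, segs, spans) {
      ends <- integer(0)
      for (k in seq_along(segs)) {
        s <- segs[[k]]
        sh <- shuffle_cl(s$cat, s$len)
        code[spans[[k]]] <- rep.int(sh$cat, sh$len)
        if (do_cv) {
          e <- s$start + cumsum(sh$len)
          ends <- c(ends, e[sh$cat != CODE_CO & e < n])
        }
      }
      list(code = code, ends = ends)
    }
    for (it in seq_len(n_iter)) {
      a <- shuffle_bird(code_f, segs_f, spans_f)
      b <- shuffle_bird(code_m, segs_m, spans_m)
      if (do_overlap) null_overlap[it] <- overlap_code(a$code, b$code)
      if (do_cv) null_cv[it] <- cv_of_windows(c(a$ends, b$ends))
    }
  }

  out <- list()
  if (do_overlap) {
    out$st_lt_overlap <- new_randomization_result(
      "st_lt_overlap", obs_overlap, null_overlap, "greater", n_iter, seed,
      degenerate)
  }
  if (do_cv) {
    out$interfeed_cv <- new_randomization_result(
      "interfeed_cv", obs_cv, null_cv, "less", n_iter, seed, cv_degenerate)
  }
  if (statistic == "both") out else out[[statistic]]
}

# trip end windows of a rebuilt coded series, restricted to the given spans
code_trip_ends <- function(code, segs, n_windows) {
  ends <- unlist(lapply(segs, function(s) {
    span <- (s$start + 1L):(s$start + sum(s$len))
    r <- rle(code[span])
    e <- s$start + cumsum(r$lengths)
    e[r$values != CODE_CO]
  }))
  if (is.null(ends)) ends <- integer(0)
  ends[ends < n_windows]
}

## ---- exact enumeration oracle -------------------------------------------

perm_all <- function(n) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  sub <- perm_all(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    m <- sub
    m[m >= k] <- m[m >= k] + 1L
    out <- rbind(out, cbind(rep(k, nrow(m)), m))
  }
  out
}

# number of equally likely sampler outcomes for one segment
seg_outcome_count <- function(cat) {
  t <- sum(cat != CODE_CO)
  factorial(t) * factorial(length(cat) - t)
}

# all orderings (index vectors into cat/len) a shuffle can produce, each with
# equal probability 1/seg_outcome_count
seg_outcomes <- function(cat, len) {
  is_trip <- cat != CODE_CO
  t_idx <- which(is_trip)
  c_idx <- which(!is_trip)
  TP <- perm_all(length(t_idx))
  CP <- perm_all(length(c_idx))
  outs <- vector("list", nrow(TP) * nrow(CP))
  k <- 0L
  base <- seq_along(cat)
  for (ti in seq_len(nrow(TP))) {
    for (ci in seq_len(nrow(CP))) {
      ord <- base
      ord[t_idx] <- t_idx[TP[ti, ]]
      ord[c_idx] <- c_idx[CP[ci, ]]
      k <- k + 1L
      outs[[k]] <- ord
    }
  }
  outs
}

# all full coded series one bird can produce, with probabilities (collapsed
# over sampler outcomes yielding the same series)
bird_exact_series <- function(code, segs) {
  seq_list <- list(code)
  prob <- 1
  for (s in segs) {
    span <- (s$start + 1L):(s$start + sum(s$len))
    ords <- seg_outcomes(s$cat, s$len)
    new_list <- vector("list", length(seq_list) * length(ords))
    k <- 0L
    for (base in seq_list) {
      for (o in ords) {
        k <- k + 1L
        v <- base
        v[span] <- rep.int(s$cat[o], s$len[o])
        new_list[[k]] <- v
      }
    }
    seq_list <- new_list
    prob <- prob / length(ords)
  }
  keys <- vapply(seq_list, paste, "", collapse = ",")
  agg <- tapply(rep(prob, length(keys)), keys, sum)
  uniq <- seq_list[!duplicated(keys)]
  names(uniq) <- keys[!duplicated(keys)]
  list(series = uniq, prob = as.numeric(agg[names(uniq)]))
}

#' Exact null distribution by full enumeration (small instances)
#'
#' Enumerates every admissible shuffled arrangement of both birds' activity
#' strings with its exact probability, giving the exact null distribution of
#' the test statistic. Feasible only for small string pools; used as the
#' oracle against which the Monte Carlo engine is validated.
#'
#' @param ps A [pair_session()] with exclusions applied.
#' @param statistic `"st_lt_overlap"` or `"interfeed_cv"`.
#' @param limit Maximum number of joint arrangements (default `1e5`).
#' @return A list with `distribution` (data frame of `value`, `prob`),
#'   `observed`, `p_exact` (strict-tail rule) and `n_arrangements`.
#' @export
exact_null_small <- function(ps, statistic = c("st_lt_overlap",
                                               "interfeed_cv"),
                             limit = 1e5) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(ps, "pair_session"))
  if (!ps$masked_applied) {
    stop("apply_exclusions() must run before enumeration")
  }
  n <- ps$n_windows
  code_f <- labels_to_code(ps$female$labels)
  code_m <- labels_to_code(ps$male$labels)
  segs_f <- segment_specs(code_f)
  segs_m <- segment_specs(code_m)

  count_bird <- function(segs) {
    prod(vapply(segs, function(s) seg_outcome_count(s$cat), 0))
  }
  n_arr <- count_bird(segs_f) * count_bird(segs_m)
  if (n_arr > limit) {
    stop("instance has ", format(n_arr, big.mark = ","),
         " joint arrangements, above the limit of ", limit)
  }

  A <- bird_exact_series(code_f, segs_f)
  B <- bird_exact_series(code_m, segs_m)

  stat_of <- function(ca, cb) {
    if (statistic == "st_lt_overlap") {
      overlap_code(ca, cb)
    } else {
      cv_of_windows(c(code_trip_ends(ca, segs_f, n),
                      code_trip_ends(cb, segs_m, n)))
    }
  }

  nA <- length(A$series)
  nB <- length(B$series)
  vals <- numeric(nA * nB)
  pr <- numeric(nA * nB)
  k <- 0L
  for (i in seq_len(nA)) {
    for (j in seq_len(nB)) {
      k <- k + 1L
      vals[k] <- stat_of(A$series[[i]], B$series[[j]])
      pr[k] <- A$prob[i] * B$prob[j]
    }
  }
  u <- unique(vals)
  idx <- match(vals, u)
  dist <- data.frame(
    value = u,
    prob = vapply(seq_along(u), function(t) sum(pr[idx == t]), 0))
  dist <- dist[order(dist$value), , drop = FALSE]
  rownames(dist) <- NULL

  observed <- if (statistic == "st_lt_overlap") {
    overlap_code(code_f, code_m)
  } else {
    stat_of(code_f, code_m)
  }
  valid <- !is.na(dist$value)
  p_exact <- if (is.na(observed)) NA_real_ else {
    pv <- dist$prob[valid] / sum(dist$prob[valid])
    vv <- dist$value[valid]
    if (statistic == "st_lt_overlap") sum(pv[vv > observed])
    else sum(pv[vv < observed])
  }
  list(statistic_name = statistic, distribution = dist, observed = observed,
       p_exact = p_exact, n_arrangements = n_arr)
}
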