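#' Clamp Monte Carlo p-values away from 0 and 1
#'
#' A randomization p of exactly 0 (observed beyond every null sample) or 1
#' breaks the combination methods, which need p strictly inside (0, 1). The
#' conventional bound for an `n_iter`-draw Monte Carlo test is
#' `1/(n_iter + 1)`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param n_iter Number of Monte Carlo iterations that produced them.
#' @return `p` clamped to `[1/(n_iter+1), n_iter/(n_iter+1)]`.
#' @export
clamp_pvalues <- function(p, n_iter = 10000) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), n_iter >= 1)
  pmin(pmax(p, 1 / (n_iter + 1)), n_iter / (n_iter + 1))
}

check_p_input <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("no p-values to combine")
  if (anyNA(p) || any(p <= 0 | p >= 1)) {
    stop("p-values must lie strictly in (0, 1); clamp Monte Carlo zeros ",
         "with clamp_pvalues() first")
  }
  p
}

new_combined_p <- function(method, statistic, p_combined, k,
                           pair_id = NA_character_) {
  structure(
    list(pair_id = pair_id, method = method, statistic = statistic,
         p_combined = p_combined, k = k),
    class = "combined_p"
  )
}

#' @export
print.combined_p <- function(x, ...) {
  cat(sprintf("<combined_p> %s over k=%d: statistic %.3f, p = %.4g\n",
              x$method, x$k, x$statistic, x$p_combined))
  invisible(x)
}

#' Combine one-tailed p-values by the Stouffer Z-method
#'
#' Each p-value is converted to a standard-normal upper-tail quantile
#' `z_i = qnorm(1 - p_i)`; the combined statistic is `Z = sum(z_i)/sqrt(k)`
#' and the combined p-value its upper-tail probability. Sessions are treated
#' as independent and unweighted. At `k = 1` the input p is returned
#' unchanged.
#'
#' @param p_values One-tailed p-values in (0, 1), one per observation session.
#' @param pair_id Optional identifier carried into the result.
#' @return A `combined_p` object (`statistic` is the Z value).
#' @examples
#' combine_stouffer(c(0.05, 0.05)) # Z = 2 * 1.6449 / sqrt(2), p ~ 0.0100
#' @export
combine_stouffer <- function(p_values, pair_id = NA_character_) {
  p <- check_p_input(p_values)
  k <- length(p)
  z <- stats::qnorm(p, lower.tail = FALSE)
  Z <- sum(z) / sqrt(k)
  new_combined_p("stouffer_z", Z, stats::pnorm(Z, lower.tail = FALSE), k,
                 pair_id)
}

#' Combine p-values by Fisher's method
#'
#' The statistic `-2 * sum(log(p_i))` is referred to a chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @inheritParams combine_stouffer
#' @return A `combined_p` object.
#' @export
combine_fisher <- function(p_values, pair_id = NA_character_) {
  p <- check_p_input(p_values)
  k <- length(p)
  X <- -2 * sum(log(p))
  new_combined_p("fisher", X, stats::pchisq(X, df = 2 * k,
                                            lower.tail = FALSE), k, pair_id)
}

#' Combine p-values by the logit method
#'
#' The statistic `-sum(log(p_i/(1 - p_i))) / C` with
#' `C = sqrt(k * pi^2 * (5k + 2) / (3 * (5k + 4)))` is referred to a t
#' distribution with `5k + 4` degrees of freedom (the standard convention for
#' this method family). Because the t reference is an approximation, the
#' `k = 1` identity holds only approximately (to about 1e-2), unlike the
#' Stouffer and Fisher methods where it is exact.
#'
#' @inheritParams combine_stouffer
#' @return A `combined_p` object.
#' @export
combine_logit <- function(p_values, pair_id = NA_character_) {
  p <- check_p_input(p_values)
  k <- length(p)
  C <- sqrt(k * pi^2 * (5 * k + 2) / (3 * (5 * k + 4)))
  tstat <- -sum(log(p / (1 - p))) / C
  new_combined_p("logit", tstat,
                 stats::pt(tstat, df = 5 * k + 4, lower.tail = FALSE), k,
                 pair_id)
}

#' Combine p-values by a chosen method
#'
#' @inheritParams combine_stouffer
#' @param method `"stouffer_z"` (default), `"fisher"` or `"logit"`.
#' @return A `combined_p` object.
#' @export
combine_pvalues <- function(p_values,
                            method = c("stouffer_z", "fisher", "logit"),
                            pair_id = NA_character_) {
  method <- match.arg(method)
  switch(method,
         stouffer_z = combine_stouffer(p_values, pair_id),
         fisher = combine_fisher(p_values, pair_id),
         logit = combine_logit(p_values, pair_id))
}
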