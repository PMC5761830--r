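#' Specific Growth Rate between two mass measurements
#'
#' `SGR = (ln(m2) - ln(m1)) / ((t2 - t1) * 100)` in the `"paper_literal"`
#' convention, where m1 and m2 are body masses (g) at days t1 < t2. The
#' `"percent_per_day"` convention is the textbook form
#' `100 * (ln(m2) - ln(m1)) / (t2 - t1)`; the two differ by exactly a factor
#' of 1e4 and, because the growth variables are Z-scaled before the PCA and
#' models, the choice does not affect any downstream result.
#'
#' @param m1,m2 Body masses in grams (positive).
#' @param t1,t2 Days of life, `t2 > t1`.
#' @param convention `"paper_literal"` (default) or `"percent_per_day"`.
#' @return The growth rate; the convention is attached as attribute
#'   `"convention"`.
#' @export
sgr <- function(m1, m2, t1, t2,
                convention = c("paper_literal", "percent_per_day")) {
  convention <- match.arg(convention)
  if (any(c(m1, m2) <= 0)) stop("masses must be positive")
  if (any(t2 <= t1)) stop("t2 must be later than t1")
  lr <- log(m2) - log(m1)
  out <- switch(convention,
                paper_literal = lr / ((t2 - t1) * 100),
                percent_per_day = 100 * lr / (t2 - t1))
  attr(out, "convention") <- convention
  out
}

#' Derive growth parameters for one chick
#'
#' Computes the chick growth indicators used in place of growth-curve
#' fitting: raw mass on day 14-16 (earliest such measurement), peak mass and
#' its day (earliest day on ties), fledging mass (last measurement), mass
#' recession (peak minus fledging mass), fledge day, and two Specific Growth
#' Rates — SGR1 from the day 14-16 mass to the peak and SGR2 from the peak to
#' fledging, both over measurement days.
#'
#' The fledge day is interval-censored by the nest-check cadence: with
#' nest-check records it is the midpoint between the last day the chick was
#' seen and the first day it was missing (fledging counted only after day
#' 21); without them it is the last measurement day plus `fledge_offset`.
#'
#' @param mass_records Data frame with `day_of_life` and `mass_g` for one
#'   chick (at least 2 rows).
#' @param nest_checks Optional data frame with `day_of_life` and
#'   `chick_present` (logical) for the same nest.
#' @param fledge_offset Days added to the last measurement day when no
#'   nest-check records are available (default 1.5, half the 3-day check
#'   interval).
#' @param sgr_convention Passed to [sgr()].
#' @return One-row data frame with `mass_d14_16`, `peak_mass`, `fledge_mass`,
#'   `mass_recession`, `peak_day`, `fledge_day`, `sgr1`, `sgr2`.
#' @export
derive_growth_params <- function(mass_records, nest_checks = NULL,
                                 fledge_offset = 1.5,
                                 sgr_convention = "paper_literal") {
  stopifnot(all(c("day_of_life", "mass_g") %in% names(mass_records)))
  rec <- mass_records[order(mass_records$day_of_life), , drop = FALSE]
  if (nrow(rec) < 2L) stop("need at least two mass records per chick")
  if (any(rec$mass_g <= 0)) stop("chick mass must be positive")

  in_window <- rec$day_of_life >= 14 & rec$day_of_life <= 16
  if (any(in_window)) {
    d14_idx <- which(in_window)[1L]
    mass_d14_16 <- rec$mass_g[d14_idx]
    d14_day <- rec$day_of_life[d14_idx]
  } else {
    warning("no measurement on day 14-16; mass_d14_16 (and sgr1) missing")
    mass_d14_16 <- NA_real_
    d14_day <- NA_real_
  }

  peak_idx <- which.max(rec$mass_g)  # earliest day on ties
  peak_mass <- rec$mass_g[peak_idx]
  peak_day <- rec$day_of_life[peak_idx]
  fledge_mass <- rec$mass_g[nrow(rec)]
  last_day <- rec$day_of_life[nrow(rec)]

  fledge_day <- if (!is.null(nest_checks)) {
    ck <- nest_checks[order(nest_checks$day_of_life), , drop = FALSE]
    gone <- ck$day_of_life[!ck$chick_present & ck$day_of_life > 21]
    seen <- ck$day_of_life[ck$chick_present]
    if (length(gone) && length(seen)) {
      (max(seen[seen < min(gone)]) + min(gone)) / 2
    } else {
      last_day + fledge_offset
    }
  } else {
    last_day + fledge_offset
  }

  sgr1 <- if (!is.na(mass_d14_16) && peak_day > d14_day) {
    as.numeric(sgr(mass_d14_16, peak_mass, d14_day, peak_day,
                   sgr_convention))
  } else NA_real_
  sgr2 <- if (last_day > peak_day) {
    as.numeric(sgr(peak_mass, fledge_mass, peak_day, last_day,
                   sgr_convention))
  } else NA_real_

  data.frame(
    mass_d14_16 = mass_d14_16, peak_mass = peak_mass,
    fledge_mass = fledge_mass, mass_recession = peak_mass - fledge_mass,
    peak_day = peak_day, fledge_day = fledge_day,
    sgr1 = sgr1, sgr2 = sgr2
  )
}

#' Growth parameters for every chick in a mass table
#'
#' @param masses Chick-mass data frame (`pair_id`, `day_of_life`, `mass_g`).
#' @param nest_checks Optional nest-check data frame (`pair_id`,
#'   `day_of_life`, `chick_present`).
#' @inheritParams derive_growth_params
#' @return Data frame with one row per `pair_id` and the eight growth
#'   parameters.
#' @export
growth_params_table <- function(masses, nest_checks = NULL,
                                fledge_offset = 1.5,
                                sgr_convention = "paper_literal") {
  pairs <- sort(unique(masses$pair_id))
  rows <- lapply(pairs, function(p) {
    ck <- if (!is.null(nest_checks)) {
      nest_checks[nest_checks$pair_id == p, , drop = FALSE]
    } else NULL
    cbind(data.frame(pair_id = p, stringsAsFactors = FALSE),
          derive_growth_params(masses[masses$pair_id == p, , drop = FALSE],
                               ck, fledge_offset, sgr_convention))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' PCA reduction of the chick growth parameters
#'
#' Because the growth indicators are strongly inter-correlated, they are
#' Z-transformed (centred, unit variance) and reduced by principal component
#' analysis; the scores on the first two components serve as the chick
#' body-condition responses in the mixed models. Rows with missing parameters
#' are dropped (complete-case), and zero-variance variables are dropped with
#' a warning.
#'
#' @param params Growth-parameter table from [growth_params_table()].
#' @param n_components Number of score columns returned (default 2).
#' @return Object of class `"growth_pca"`: `scores` (data frame with
#'   `pair_id` and `PC1..PCn`), `variance_explained` (proportions over all
#'   components), `loadings`, `n_used`, `dropped_rows`, `dropped_vars`.
#' @export
growth_pca <- function(params, n_components = 2) {
  vars <- setdiff(names(params), "pair_id")
  complete <- stats::complete.cases(params[vars])
  dropped_rows <- params$pair_id[!complete]
  if (length(dropped_rows)) {
    message("growth_pca: dropping ", length(dropped_rows),
            " chick(s) with incomplete parameters: ",
            paste(dropped_rows, collapse = ", "))
  }
  dat <- params[complete, vars, drop = FALSE]
  if (nrow(dat) < 3L) stop("PCA needs at least 3 chicks with complete data")
  sds <- vapply(dat, stats::sd, 0)
  dropped_vars <- names(sds)[sds == 0]
  if (length(dropped_vars)) {
    warning("growth_pca: dropping zero-variance variable(s): ",
            paste(dropped_vars, collapse = ", "))
    dat <- dat[, sds > 0, drop = FALSE]
  }
  fit <- stats::prcomp(dat, center = TRUE, scale. = TRUE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  n_components <- min(n_components, ncol(fit$x))
  scores <- cbind(
    data.frame(pair_id = params$pair_id[complete], stringsAsFactors = FALSE),
    as.data.frame(fit$x[, seq_len(n_components), drop = FALSE]))
  structure(
    list(scores = scores, variance_explained = ve, loadings = fit$rotation,
         n_used = nrow(dat), dropped_rows = dropped_rows,
         dropped_vars = dropped_vars),
    class = "growth_pca"
  )
}

#' @export
print.growth_pca <- function(x, ...) {
  cat(sprintf("<growth_pca> %d chicks, %d components\n", x$n_used,
              length(x$variance_explained)))
  cat(sprintf("  variance explained: %s (first two: %.1f%%)\n",
              paste(sprintf("%.1f%%", 100 * x$variance_explained),
                    collapse = ", "),
              100 * sum(x$variance_explained[1:min(2,
                length(x$variance_explained))])))
  invisible(x)
}

#' Fit the four coordination mixed models
#'
#' Linear mixed models (maximum likelihood, breeding pair as random
#' intercept) for the downstream questions: (a) coordination level vs chick
#' age; (b) relative inter-feeding-interval CV vs coordination level; (c)
#' chick body condition (PC1, PC2) vs coordination level, controlling for the
#' total number of feedings per session; (d) body condition vs relative CV,
#' same control. Fixed-effect F tests use the `lmerTest` machinery with a
#' configurable denominator-df method.
#'
#' @param session_tbl Data frame with one row per included pair-session:
#'   `pair_id`, `coordination` (overlap index), `cv_index` (relative CV),
#'   `chick_age`, `n_feedings`, and (joined per pair) `PC1`, `PC2`. The
#'   feeding count is Z-scaled internally before fitting (its scale
#'   otherwise dwarfs the PC scores and destabilises the optimiser); F tests
#'   and p-values are invariant to that linear rescaling.
#' @param ddf Denominator degrees-of-freedom method for the F tests
#'   (`"Satterthwaite"` default, or `"Kenward-Roger"`).
#' @return Object of class `"coordination_models"`: a list of fitted models
#'   and a tidy coefficient/F-test table.
#' @export
fit_coordination_models <- function(session_tbl, ddf = "Satterthwaite") {
  needed <- c("pair_id", "coordination", "cv_index", "chick_age",
              "n_feedings", "PC1", "PC2")
  missing_cols <- setdiff(needed, names(session_tbl))
  if (length(missing_cols)) {
    stop("session_tbl lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  # Z-scale the wide-ranged covariates; F tests are invariant to this
  for (v in c("n_feedings", "chick_age")) {
    if (stats::sd(session_tbl[[v]], na.rm = TRUE) > 0) {
      session_tbl[[v]] <- as.numeric(scale(session_tbl[[v]]))
    }
  }
  specs <- list(
    age = coordination ~ chick_age + (1 | pair_id),
    cv = cv_index ~ coordination + (1 | pair_id),
    growth_pc1_coordination = PC1 ~ coordination + n_feedings + (1 | pair_id),
    growth_pc2_coordination = PC2 ~ coordination + n_feedings + (1 | pair_id),
    growth_pc1_cv = PC1 ~ cv_index + n_feedings + (1 | pair_id),
    growth_pc2_cv = PC2 ~ cv_index + n_feedings + (1 | pair_id)
  )
  fits <- list()
  rows <- list()
  for (nm in names(specs)) {
    dat <- session_tbl[stats::complete.cases(
      session_tbl[all.vars(specs[[nm]])]), , drop = FALSE]
    # lmerTest's model conversion can fail on degenerate data (e.g. a
    # constant response); fall back to plain lme4 and report slopes only
    fit <- tryCatch(
      lmerTest::lmer(specs[[nm]], data = dat, REML = FALSE),
      error = function(e) tryCatch(
        suppressWarnings(lme4::lmer(specs[[nm]], data = dat, REML = FALSE)),
        error = function(e2) e2))
    fits[[nm]] <- fit
    if (inherits(fit, "error")) {
      rows[[nm]] <- data.frame(model = nm, term = NA_character_,
                               estimate = NA_real_, F = NA_real_,
                               df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                               singular = NA, note = conditionMessage(fit))
      next
    }
    fe <- lme4::fixef(fit)
    terms <- if (inherits(fit, "lmerModLmerTest")) {
      an <- stats::anova(fit, ddf = ddf)
      rownames(an)
    } else {
      character(0)
    }
    if (!length(terms)) {
      # degenerate fit (constant response or dropped predictors): report
      # slope estimates without F tests
      terms <- setdiff(names(fe), "(Intercept)")
      nr <- max(length(terms), 1L)
      rows[[nm]] <- data.frame(
        model = rep(nm, nr),
        term = if (length(terms)) terms else NA_character_,
        estimate = if (length(terms)) as.numeric(fe[terms]) else NA_real_,
        F = rep(NA_real_, nr), df1 = rep(NA_real_, nr),
        df2 = rep(NA_real_, nr), p = rep(NA_real_, nr),
        singular = rep(lme4::isSingular(fit), nr),
        note = rep("degenerate fit", nr),
        stringsAsFactors = FALSE)
      next
    }
    rows[[nm]] <- data.frame(
      model = nm, term = terms,
      estimate = as.numeric(fe[terms]),
      F = an[["F value"]], df1 = an[["NumDF"]], df2 = an[["DenDF"]],
      p = an[["Pr(>F)"]],
      singular = lme4::isSingular(fit), note = "",
      stringsAsFactors = FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(fits = fits, table = table, ddf = ddf),
            class = "coordination_models")
}

#' @export
print.coordination_models <- function(x, ...) {
  cat("<coordination_models> linear mixed models (ML, pair random intercept),",
      "\n  F tests:", x$ddf, "denominator df\n")
  print(x$table, digits = 3)
  invisible(x)
}
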