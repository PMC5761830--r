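test_that("SGR matches hand arithmetic in both conventions", {
  expect_equal(as.numeric(sgr(100, 100, 14, 17)), 0)
  expect_equal(as.numeric(sgr(100, 100, 14, 17, "percent_per_day")), 0)

  lit <- as.numeric(sgr(100, 120, 14, 17))
  expect_equal(lit, log(1.2) / 300, tolerance = 1e-12)  # ~6.077e-4
  pct <- as.numeric(sgr(100, 120, 14, 17, "percent_per_day"))
  expect_equal(pct, 100 * log(1.2) / 3, tolerance = 1e-12)  # ~6.077

  # the two conventions differ by exactly 1e4
  expect_equal(pct / lit, 1e4, tolerance = 1e-10)

  # antisymmetry over equal spans
  expect_equal(as.numeric(sgr(100, 120, 14, 17)),
               -as.numeric(sgr(120, 100, 14, 17)))

  expect_error(sgr(100, 120, 17, 14), "later")
  expect_error(sgr(-1, 120, 14, 17), "positive")
})

test_that("growth parameters follow their definitions on a hand trajectory", {
  rec <- data.frame(day_of_life = c(14, 17, 20, 23),
                    mass_g = c(100, 120, 118, 110))
  checks <- data.frame(day_of_life = c(20, 23, 26),
                       chick_present = c(TRUE, TRUE, FALSE))
  gp <- derive_growth_params(rec, checks)
  expect_equal(gp$mass_d14_16, 100)
  expect_equal(gp$peak_mass, 120)
  expect_equal(gp$peak_day, 17)
  expect_equal(gp$mass_recession, 10)
  expect_equal(gp$fledge_mass, 110)
  expect_equal(gp$fledge_day, (23 + 26) / 2)  # interval-censored midpoint
  expect_equal(gp$sgr1, log(120 / 100) / (3 * 100))
  expect_equal(gp$sgr2, log(110 / 120) / (6 * 100))

  # without nest checks the fledge day falls back to last day + offset
  gp2 <- derive_growth_params(rec, fledge_offset = 1.5)
  expect_equal(gp2$fledge_day, 24.5)
})

test_that("monotonically increasing masses give zero recession", {
  rec <- data.frame(day_of_life = c(14, 17, 20), mass_g = c(90, 110, 130))
  gp <- derive_growth_params(rec)
  expect_equal(gp$fledge_mass, gp$peak_mass)
  expect_equal(gp$mass_recession, 0)
  expect_true(is.na(gp$sgr2))  # peak is the last record: no span to fledge
})

test_that("growth parameters ignore input row order and warn on no d14-16", {
  rec <- data.frame(day_of_life = c(14, 17, 20, 23),
                    mass_g = c(100, 120, 118, 110))
  shuf <- rec[c(3, 1, 4, 2), ]
  expect_equal(derive_growth_params(rec), derive_growth_params(shuf))

  late <- data.frame(day_of_life = c(17, 20), mass_g = c(120, 118))
  expect_warning(gp <- derive_growth_params(late), "14-16")
  expect_true(is.na(gp$mass_d14_16))
  expect_true(is.na(gp$sgr1))
})

test_that("PCA variance proportions are a valid spectrum", {
  set.seed(19)
  n <- 20
  base <- rnorm(n)
  params <- data.frame(
    pair_id = sprintf("p%02d", 1:n),
    mass_d14_16 = 100 + 5 * base + rnorm(n),
    peak_mass = 150 + 8 * base + rnorm(n),
    fledge_mass = 135 + 7 * base + rnorm(n),
    mass_recession = 15 + rnorm(n),
    peak_day = 20 + rnorm(n),
    fledge_day = 26 + rnorm(n),
    sgr1 = 0.001 + 0.0001 * base + 0.0001 * rnorm(n),
    sgr2 = -0.0005 + 0.0001 * rnorm(n))
  pca <- growth_pca(params)
  ve <- pca$variance_explained
  expect_equal(sum(ve), 1)
  expect_true(all(diff(ve) <= 1e-12))
  expect_true(all(ve >= 0 & ve <= 1))
  expect_equal(nrow(pca$scores), n)
})

test_that("two perfectly correlated variables load on a single component", {
  x <- rnorm(10)
  params <- data.frame(pair_id = letters[1:10], a = x, b = 2 * x + 3)
  pca <- growth_pca(params)
  expect_equal(pca$variance_explained[1], 1, tolerance = 1e-12)
})

test_that("zero-variance variables are dropped with a warning", {
  set.seed(4)
  params <- data.frame(pair_id = letters[1:8], a = rnorm(8), b = rnorm(8),
                       c = 5)
  expect_warning(pca <- growth_pca(params), "zero-variance")
  expect_equal(ncol(pca$loadings), 2L)
})

test_that("SGR convention choice does not change the PCA", {
  co <- simulate_corpus(sim_params(n_pairs = 10, seed = 55))
  p1 <- growth_params_table(co$masses, co$nest_checks,
                            sgr_convention = "paper_literal")
  p2 <- growth_params_table(co$masses, co$nest_checks,
                            sgr_convention = "percent_per_day")
  expect_equal(p2$sgr1 / p1$sgr1, rep(1e4, nrow(p1)))
  v1 <- growth_pca(p1)$variance_explained
  v2 <- growth_pca(p2)$variance_explained
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("a noiseless generator round-trips peak mass and day exactly", {
  set.seed(12)
  params <- sim_params(n_pairs = 1, mass_noise_sd = 0)
  g <- simulate_chick_growth(params, "pX", cv_mean = 0.5)
  gp <- derive_growth_params(g$masses, g$nest_checks)
  expect_equal(gp$peak_mass, g$truth$true_peak_mass, tolerance = 1e-12)
  expect_equal(gp$peak_day, g$truth$true_peak_day)
  expect_equal(gp$fledge_mass, g$truth$true_fledge_mass, tolerance = 1e-12)
  # nest checks every 3 days: interval-censored fledge day within 1.5 days
  expect_lte(abs(gp$fledge_day - g$truth$true_fledge_day), 1.5)
})

test_that("mixed models recover a built-in coordination-CV slope", {
  set.seed(33)
  n_pairs <- 20
  tbl <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    k <- 3
    coord <- rnorm(k, 0.5, 0.4)
    data.frame(pair_id = sprintf("p%02d", i),
               coordination = coord,
               cv_index = -0.5 * coord + rnorm(k, 0, 0.1) + rnorm(1, 0, 0.05),
               chick_age = sample(5:29, k),
               n_feedings = rpois(k, 16),
               PC1 = rnorm(k), PC2 = rnorm(k))
  }))
  fit <- fit_coordination_models(tbl)
  row <- fit$table[fit$table$model == "cv" &
                     fit$table$term == "coordination", ]
  expect_lt(row$estimate, 0)
  expect_lt(row$p, 0.05)
})

test_that("a constant response yields a zero slope", {
  set.seed(34)
  tbl <- data.frame(pair_id = rep(letters[1:8], each = 3),
                    coordination = rnorm(24),
                    cv_index = 1,
                    chick_age = rep(10, 24),
                    n_feedings = rpois(24, 16),
                    PC1 = rnorm(24), PC2 = rnorm(24))
  fit <- suppressWarnings(fit_coordination_models(tbl))
  row <- fit$table[fit$table$model == "cv" &
                     fit$table$term == "coordination", ]
  expect_equal(row$estimate, 0, tolerance = 1e-8)
})
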