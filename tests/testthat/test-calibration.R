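make_meas <- function(n = 6) {
  data.frame(observable = rep(c("cDCW", "Glc"), each = n / 2),
             time_h = rep(seq_len(n / 2), 2),
             value = c(10, 20, 30, 5, 3, 1), sd = NA_real_,
             stringsAsFactors = FALSE)
}

test_that("perturbation is centered, seed-deterministic and exact at zero noise", {
  d <- measurement_dataset(make_meas(),
                           initial = c(init.cDCW = 2),
                           setpoints = c(pH = 5),
                           split = c(Xpri = 0.6, Xs = 0.4))
  n0 <- noise_spec(0, 0, 0, 0)
  expect_equal(perturb_dataset(d, n0, seed = 3), d)
  d0 <- d; d0$measurements$sd <- 0  # per-point sd of zero: degenerate normal
  expect_equal(perturb_dataset(d0, noise_spec(0.05, 0, 0, 0), seed = 3)$
                 measurements$value, d0$measurements$value)
  n1 <- noise_spec()
  p1 <- perturb_dataset(d, n1, seed = 11)
  p2 <- perturb_dataset(d, n1, seed = 11)
  expect_identical(p1, p2)
  expect_false(identical(p1$measurements$value, d$measurements$value))
  expect_equal(sum(p1$split), 1, tolerance = 1e-12)
})

test_that("5% relative noise reproduces a 5% empirical spread", {
  n <- 1e5
  meas <- data.frame(observable = "Glc", time_h = seq_len(n),
                     value = rep(40, n), sd = NA_real_)
  d <- measurement_dataset(meas)
  p <- perturb_dataset(d, noise_spec(measurement_rel = 0.05), seed = 5)
  rel <- stats::sd(p$measurements$value) / mean(p$measurements$value)
  expect_lt(abs(rel - 0.05), 0.002)
  expect_true(all(p$measurements$value >= 0))
})

test_that("weighted RMSD matches hand-computed cases", {
  meas <- data.frame(observable = rep("Glc", 4), time_h = 1:4,
                     value = c(1, 2, 3, 4), sd = 0)
  expect_equal(rmsd(c(1, 2, 3, 4), meas), 0)
  # four residuals of one, unnormalized: sqrt(4/4) = 1
  expect_equal(rmsd(c(2, 3, 4, 5), meas, normalize = FALSE), 1)
  # the high-cell-density rule halves the weight of a cDCW point > 100 g/l
  m2 <- data.frame(observable = "cDCW", time_h = c(1, 2),
                   value = c(120, 120), sd = 0)
  expect_equal(rmsd(c(122, 122), m2, normalize = FALSE),
               sqrt((4 * 0.5 + 4 * 0.5) / 2), tolerance = 1e-12)
  m3 <- data.frame(observable = "cDCW", time_h = c(1, 2),
                   value = c(120, 50), sd = 0)
  expect_equal(rmsd(c(122, 50), m3, normalize = FALSE),
               sqrt(4 * 0.5 / 2), tolerance = 1e-12)
  expect_error(rmsd(numeric(0), meas[0, ]), "empty")
})

test_that("RMSD equals a brute-force recomputation on random instances", {
  for (s in 1:100) {
    meas <- random_meas(n = 3 + s %% 12, seed = s)
    y <- meas$value + stats::rnorm(nrow(meas))
    expect_equal(rmsd(y, meas), oracle_rmsd(y, meas), tolerance = 1e-12)
    expect_equal(rmsd(y, meas, normalize = FALSE),
                 oracle_rmsd(y, meas, normalize = FALSE), tolerance = 1e-12)
  }
})

test_that("R2 anchors at 1, 0 and goes negative when the mean is closer", {
  y <- c(2, 4, 6, 8)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  expect_lt(r_squared(c(8, 6, 4, 2), y), 0)
  expect_true(is.na(r_squared(c(1, 1), c(3, 3))))
  for (s in 1:30) {
    set.seed(s)
    ym <- stats::rnorm(10); ys <- ym + stats::rnorm(10, 0, 0.3)
    expect_equal(r_squared(ys, ym), oracle_r_squared(ys, ym),
                 tolerance = 1e-12)
    # affine invariance under joint rescaling
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1)
    expect_equal(r_squared(a * ys + b, a * ym + b), r_squared(ys, ym),
                 tolerance = 1e-9)
  }
})

test_that("R-7 quantile interpolates the order statistics", {
  expect_equal(quantile_r7(1:10, 0.1), 1.9)
  expect_equal(quantile_r7(1:10, 0), 1)
  expect_equal(quantile_r7(1:10, 1), 10)
  set.seed(99)
  for (i in 1:50) {
    x <- stats::rnorm(sample(2:40, 1))
    p <- stats::runif(1)
    expect_equal(quantile_r7(x, p), oracle_quantile_r7(x, p),
                 tolerance = 1e-12)
  }
  expect_error(quantile_r7(numeric(0), 0.5), "empty")
})

test_that("fitting recovers known parameters from noise-free data", {
  sc <- scenario_toy(F = 0.3, unimodal = FALSE)
  st <- generate_synthetic_study("toy", truth = c(k = 3.1),
                                 noise = noise_spec(0, 0, 0, 0), seed = 1,
                                 scenario = sc)
  cfg <- calibration_config(free = "k", n_fits = 1, n_starts = 2,
                            maxit = 200, seed = 4)
  fit <- fit_parameters(st$scenario, st$dataset$measurements, cfg, seed = 4)
  expect_equal(unname(fit$free[["k"]]), 3.1, tolerance = 0.01)
  expect_lt(fit$rmsd, 1e-3)
})

test_that("a zero-iteration budget returns the start point", {
  sc <- scenario_toy(F = 0.3)
  st <- generate_synthetic_study("toy", seed = 2, scenario = sc)
  cfg <- calibration_config(free = "k", n_fits = 1, n_starts = 1,
                            maxit = 0, seed = 1)
  fit <- fit_parameters(sc, st$dataset$measurements, cfg, seed = 1)
  expect_equal(unname(fit$free[["k"]]),
               default_params(sc$model)[["k"]], tolerance = 1e-6)
})

test_that("fitted parameters respect their box bounds", {
  sc <- scenario_toy(F = 0.3, unimodal = FALSE)
  # truth above the upper bound of k (10): fit must stay at or inside it
  st <- generate_synthetic_study("toy", truth = c(k = 9.99),
                                 noise = noise_spec(0, 0, 0, 0), seed = 3,
                                 scenario = sc)
  cfg <- calibration_config(free = "k", n_fits = 1, n_starts = 1,
                            maxit = 150, seed = 2)
  fit <- fit_parameters(st$scenario, st$dataset$measurements, cfg, seed = 2)
  expect_lte(fit$free[["k"]], 10)
  expect_gte(fit$free[["k"]], 0)
})

test_that("ensembles are seed-deterministic with ordered, bounded quantiles", {
  st <- generate_synthetic_study("toy", seed = 7)
  cfg <- calibration_config(free = c("k", "b"), n_fits = 6, n_starts = 1,
                            maxit = 40, seed = 21)
  e1 <- build_ensemble(st$scenario, st$dataset, cfg)
  e2 <- build_ensemble(st$scenario, st$dataset, cfg)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$members, e2$members)
  expect_equal(nrow(e1$members), 6)
  s <- e1$summary
  expect_true(all(s$q10 <= s$median & s$median <= s$q90))
  b <- e1$bounds
  expect_true(all(e1$members >= matrix(b$lower, 6, 2, byrow = TRUE) &
                    e1$members <= matrix(b$upper, 6, 2, byrow = TRUE)))
})

test_that("zero noise collapses the ensemble to identical members", {
  st <- generate_synthetic_study("toy", noise = noise_spec(0, 0, 0, 0),
                                 seed = 9)
  cfg <- calibration_config(free = "k", n_fits = 4, n_starts = 1,
                            maxit = 40, seed = 5)
  ens <- build_ensemble(st$scenario, st$dataset, cfg, noise_spec(0, 0, 0, 0))
  expect_equal(ens$summary$q10, ens$summary$q90, tolerance = 1e-10)
})
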