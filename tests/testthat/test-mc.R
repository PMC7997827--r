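# a small handmade ensemble with known quantile box
fake_ensemble <- function(members) {
  free <- colnames(members)
  structure(list(
    members = members,
    rmsd = rep(0.1, nrow(members)), converged = rep(TRUE, nrow(members)),
    summary = data.frame(name = free,
                         median = apply(members, 2, quantile_r7, p = 0.5),
                         q10 = apply(members, 2, quantile_r7, p = 0.1),
                         q90 = apply(members, 2, quantile_r7, p = 0.9),
                         stringsAsFactors = FALSE),
    free = free, bounds = NULL, n_fits = nrow(members), n_ok = nrow(members)),
    class = "mdoe_ensemble")
}

test_that("LHS places exactly one draw per stratum of the 10-90% box", {
  memb <- cbind(k = seq(1, 3, length.out = 21), b = seq(-1, 1, length.out = 21))
  ens <- fake_ensemble(memb)
  n <- 12
  dr <- lhs_sample(ens, n, seed = 3)
  for (j in 1:2) {
    q10 <- ens$summary$q10[j]; q90 <- ens$summary$q90[j]
    expect_true(all(dr[, j] >= q10 & dr[, j] <= q90))
    stratum <- floor((dr[, j] - q10) / (q90 - q10) * n)
    stratum[stratum == n] <- n - 1
    expect_equal(sort(stratum), 0:(n - 1))
  }
  expect_identical(dr, lhs_sample(ens, n, seed = 3))
})

test_that("a degenerate ensemble yields constant draws at the median", {
  memb <- cbind(k = rep(2.5, 10))
  ens <- fake_ensemble(memb)
  dr <- lhs_sample(ens, 7, seed = 1)
  expect_equal(unname(dr[, "k"]), rep(2.5, 7))
})

test_that("LHS draws are uniform on the quantile box", {
  memb <- cbind(k = seq(0, 10, length.out = 101))
  ens <- fake_ensemble(memb)
  n <- 1000
  dr <- lhs_sample(ens, n, seed = 8)
  q10 <- ens$summary$q10; q90 <- ens$summary$q90
  u <- (dr[, 1] - q10) / (q90 - q10)
  ks <- max(abs(seq_len(n) / n - sort(u)))
  expect_lt(ks, 0.02)
})

test_that("member resampling keeps joint parameter combinations", {
  memb <- cbind(k = c(1, 2, 3, 4), b = c(10, 20, 30, 40))  # b = 10 k
  ens <- fake_ensemble(memb)
  dr <- lhs_sample(ens, 50, seed = 2, mode = "members")
  expect_true(all(dr[, "b"] == 10 * dr[, "k"]))
})

test_that("identical draws give zero response variability", {
  sc <- scenario_toy(F = 0.3)
  space <- design_space(data.frame(name = "F", lower = 0, upper = 1.2,
                                   maps_to = "feed.f1.F"))
  draws <- matrix(rep(c(2, 0.1), each = 10), 10, 2,
                  dimnames = list(NULL, c("k", "b")))
  rsp <- response_spec("P", "value_at_time", at = 24)
  s <- simulate_design_point(c(F = 0.5), draws, sc, space, rsp)
  expect_equal(s$nu, 0, tolerance = 1e-10)
  expect_equal(s$n_ok, 10)
  expect_false(s$flagged)
})

test_that("nu equals a brute-force sort-and-interpolate quantile difference", {
  sc <- scenario_toy(F = 0.3)
  space <- design_space(data.frame(name = "F", lower = 0, upper = 1.2,
                                   maps_to = "feed.f1.F"))
  set.seed(31)
  draws <- cbind(k = stats::runif(15, 1, 3), b = stats::runif(15, -0.5, 0.5))
  rsp <- response_spec("P", "value_at_time", at = 24)
  s <- simulate_design_point(c(F = 0.7), draws, sc, space, rsp)
  r <- s$responses[!is.na(s$responses)]
  expect_equal(s$nu, oracle_quantile_r7(r, 0.9) - oracle_quantile_r7(r, 0.1),
               tolerance = 1e-12)
  expect_equal(s$r_mean, mean(r), tolerance = 1e-12)
  expect_gte(s$r_mean, min(r)); expect_lte(s$r_mean, max(r))
})

test_that("a monotone feed effect produces monotone mean responses", {
  sc <- scenario_toy(F = 0.3, unimodal = FALSE)   # F0 large: response rises in F
  space <- design_space(data.frame(name = "F", lower = 0.05, upper = 1,
                                   maps_to = "feed.f1.F"))
  draws <- matrix(rep(c(2, 0), each = 5), 5, 2,
                  dimnames = list(NULL, c("k", "b")))
  rsp <- response_spec("P", "value_at_time", at = 24)
  Fs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  r <- vapply(Fs, function(Fv)
    simulate_design_point(c(F = Fv), draws, sc, space, rsp)$r_mean,
    numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("mean responses are stable when the simulation count grows tenfold", {
  st <- generate_synthetic_study("toy", seed = 4)
  cfg <- calibration_config(free = c("k", "b"), n_fits = 8, n_starts = 1,
                            maxit = 40, seed = 13)
  ens <- build_ensemble(st$scenario, st$dataset, cfg)
  space <- design_space(data.frame(name = "F", lower = 0, upper = 1.2,
                                   maps_to = "feed.f1.F"))
  rsp <- response_spec("P", "value_at_time", at = 24)
  s30 <- simulate_design_point(c(F = 0.6), lhs_sample(ens, 30, seed = 1),
                               st$scenario, space, rsp)
  s300 <- simulate_design_point(c(F = 0.6), lhs_sample(ens, 300, seed = 2),
                                st$scenario, space, rsp)
  se30 <- stats::sd(s30$responses, na.rm = TRUE) / sqrt(s30$n_ok)
  expect_lt(abs(s30$r_mean - s300$r_mean), 3 * se30)
})

test_that("evaluate_design summarizes every point with per-point seeds", {
  st <- generate_synthetic_study("toy", seed = 6)
  cfg <- calibration_config(free = c("k", "b"), n_fits = 6, n_starts = 1,
                            maxit = 30, seed = 2)
  ens <- build_ensemble(st$scenario, st$dataset, cfg)
  space <- design_space(data.frame(name = "F", lower = 0, upper = 1.2,
                                   maps_to = "feed.f1.F"))
  des <- plan_design(space, k = 5, n_random = 2000, seed = 3)
  rsp <- response_spec("P", "value_at_time", at = 24)
  rs <- evaluate_design(des, ens, st$scenario, rsp, n_sims = 8, seed = 9)
  expect_equal(nrow(rs), 5)
  expect_true(all(rs$n_ok == 8))
  expect_true(all(rs$nu >= 0))
  rs2 <- evaluate_design(des, ens, st$scenario, rsp, n_sims = 8, seed = 9)
  expect_identical(as.data.frame(rs), as.data.frame(rs2))
})
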