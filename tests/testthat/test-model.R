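# parameters with every kinetic and transfer rate switched off
zero_rate_params <- function(model) {
  pv <- default_params(model)
  pv[c("rGlc_ox_max", "rGlc_ferm_max", "rEtOH_max", "rEAA_max",
       "k_act", "k_xp", "k_inact", "k_d")] <- 0
  pv
}

static_state <- function(model) {
  y0 <- stats::setNames(numeric(length(model$states)), model$states)
  y0[c("Glc", "EtOH", "N", "Xpri", "Xs")] <- c(10, 5, 0.4, 3, 1)
  y0[["V"]] <- 1
  y0
}

test_that("with all rates zero and no feeds the system is static", {
  m <- yeast_model("S1")
  d <- rhs(m, 5, static_state(m), zero_rate_params(m))
  expect_equal(unname(d), rep(0, length(m$states)))
})

test_that("feed input and dilution terms match the mass balance read-off", {
  m <- yeast_model("S1")
  y0 <- static_state(m)
  # water feed (no composition): pure dilution, dc = -c F/V
  fw <- list(feed_schedule("w", "constant", F = 2, t_start = 0, t_end = 24))
  d <- rhs(m, 5, y0, zero_rate_params(m), feeds = fw)
  Flh <- 2 * 0.06
  expect_equal(d[["Glc"]], -10 * Flh / 1, tolerance = 1e-12)
  expect_equal(d[["Xpri"]], -3 * Flh / 1, tolerance = 1e-12)
  expect_equal(d[["V"]], Flh, tolerance = 1e-12)
  # substrate feed: input term c_feed F/V on top of dilution
  fs <- list(feed_schedule("g", "constant", F = 2, t_start = 0, t_end = 24,
                           composition = c(Glc = 400)))
  d2 <- rhs(m, 5, y0, zero_rate_params(m), feeds = fs)
  expect_equal(d2[["Glc"]], (400 - 10) * Flh / 1, tolerance = 1e-10)
})

test_that("pure dilution matches the closed form c0 V0 / V(t) to 1e-6 relative", {
  m <- yeast_model("S1")
  y0 <- static_state(m)
  feeds <- list(feed_schedule("w", "constant", F = 2, t_start = 0, t_end = 24))
  tr <- simulate_process(m, zero_rate_params(m), y0, feeds,
                         process_environment(), seq(0, 24, 2))
  d <- tr$data
  for (nm in c("Glc", "EtOH", "Xpri")) {
    expect_equal(d[[nm]], y0[[nm]] * 1 / d$V, tolerance = 1e-6)
  }
  # volume balance against the analytic feed integral
  expect_equal(d$V[nrow(d)], 1 + 2 * 0.06 * 24, tolerance = 1e-6)
  expect_lt(tr$volume_residual_l, 1e-6 * 1)
})

test_that("zero-rate zero-feed trajectory is constant", {
  m <- yeast_model("S1")
  y0 <- static_state(m)
  tr <- simulate_process(m, zero_rate_params(m), y0, list(),
                         process_environment(), seq(0, 10, 1))
  for (nm in m$states)
    expect_equal(tr$data[[nm]], rep(y0[[nm]], 11), tolerance = 1e-9)
})

test_that("reference growth run conserves carbon and volume and grows monotonically", {
  sc <- scenario_s1()
  tr <- simulate_scenario(sc)
  d <- tr$data
  expect_lt(tr$volume_residual_l, 1e-6 * sc$V0)
  cb <- carbon_balance(tr, sc$model)
  expect_lt(max(abs(cb$residual_g)) / max(cb$carbon_in_g), 1e-5)
  # biomass accumulates while ethanol stays below the inhibition midpoint
  pre <- d$EtOH < default_params(sc$model)[["etoh_inh_X50"]]
  expect_true(all(diff(d$cDCW[pre]) > -1e-9))
  expect_true(all(d$cDCW == d$Xpri + d$Xp + d$Xi + d$Xs + d$Xsi + d$Xd))
  # concentrations never meaningfully negative
  for (nm in sc$model$conc_states) expect_true(all(d[[nm]] >= 0))
})

test_that("pulse feeds add volume and dilute/concentrate states consistently", {
  m <- yeast_model("S1")
  y0 <- static_state(m)
  pf <- list(feed_schedule("pulse", "pulses",
                           pulses = data.frame(time = 5, volume = 0.25),
                           composition = c(Glc = 100)))
  tr <- simulate_process(m, zero_rate_params(m), y0, pf,
                         process_environment(), seq(0, 10, 1))
  d <- tr$data
  expect_equal(d$V[d$time_h == 4], 1)
  expect_equal(d$V[d$time_h == 6], 1.25, tolerance = 1e-9)
  # mass balance over the pulse: c_new = (c V + c_feed vol)/(V + vol)
  expect_equal(d$Glc[d$time_h == 6], (10 * 1 + 100 * 0.25) / 1.25,
               tolerance = 1e-9)
  expect_equal(d$Xpri[d$time_h == 6], 3 / 1.25, tolerance = 1e-9)
})

test_that("respiratory quotient is the mol ratio of the gas increments", {
  fake <- structure(list(data = data.frame(
    time_h = 0:4, O2 = c(0, 1, 2, 2, 2), CO2 = c(0, 1, 2.2, 2.2, 2.2))),
    class = "mdoe_trajectory")
  rq <- respiratory_quotient(fake)
  expect_true(is.na(rq[1]))
  expect_equal(rq[2], 1.0)                 # equal moles
  expect_equal(rq[3], 1.2, tolerance = 1e-12)
  expect_true(is.na(rq[4]))                # no O2 consumed: undefined marker
  rqc <- respiratory_quotient(fake, mode = "cumulative")
  expect_equal(rqc[5], 2.2 / 2, tolerance = 1e-12)
})

test_that("oxidative reference metabolism runs near RQ 1", {
  sc <- scenario_s1(F_Glc_end = 0.25, F_N_end = 0.15)
  tr <- simulate_scenario(sc)
  rq <- respiratory_quotient(tr, mode = "cumulative")
  expect_lt(abs(rq[length(rq)] - 1), 0.25)
})

test_that("parameter bounds are enforced", {
  m <- yeast_model("S1")
  pv <- default_params(m)
  pv["Ks_Glc"] <- 99
  expect_error(mdoebox:::check_params(m, pv), "out of bounds")
  expect_error(simulate_process(m, default_params(m), static_state(m),
                                list(), process_environment(), c(0, 1, 1)),
               "strictly increasing")
})
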