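test_that("desirability anchors the best at 1 and the worst at 0", {
  rbar <- c(10, 30, 20)
  d <- desirability_mean(rbar)
  expect_equal(d, c(0, 1, 0.5))
  nu <- c(4, 1, 2.5)
  dv <- desirability_var(nu)
  expect_equal(dv, c(0, 1, 0.5))
  expect_warning(dall <- desirability_mean(c(2, 2, 2)), "equal")
  expect_equal(dall, c(1, 1, 1))
  expect_error(desirability_mean(5), ">= 2")
})

test_that("combined desirability is the stated convex combination", {
  cfg <- desirability_config(w1 = 0.8, w2 = 0.2)
  expect_equal(combined_desirability(0.5, 1.0, cfg), 0.6)
  expect_equal(combined_desirability(1, 1, cfg), 1)
  cfg1 <- desirability_config(w1 = 1, w2 = 0, n_select = 1)
  dr <- c(0.2, 0.9, 0.4)
  expect_equal(combined_desirability(dr, c(1, 0, 0.5), cfg1), dr)
  expect_error(desirability_config(w1 = 0.8, w2 = 0.3), "equal 1")
  expect_error(desirability_config(w1 = 1.2, w2 = -0.2), "\\[0, 1\\]")
})

test_that("affine rescaling of the responses leaves desirabilities unchanged", {
  set.seed(12)
  for (i in 1:25) {
    r <- stats::rnorm(10)
    a <- stats::runif(1, 0.1, 9); b <- stats::rnorm(1, 0, 10)
    expect_equal(desirability_mean(a * r + b), desirability_mean(r),
                 tolerance = 1e-9)
  }
})

test_that("D is monotone in the responses on randomized vectors", {
  set.seed(77)
  cfg <- desirability_config()
  for (i in 1:50) {
    n <- sample(5:20, 1)
    rbar <- stats::runif(n, 10, 50)
    nu <- stats::runif(n, 0.5, 8)
    d0 <- combined_desirability(desirability_mean(rbar),
                                desirability_var(nu), cfg)
    # raise one interior response without touching the anchors
    j <- which(rbar < max(rbar) & rbar > min(rbar))[1]
    if (is.na(j)) next
    r2 <- rbar; r2[j] <- min(max(rbar), r2[j] + 0.5 * (max(rbar) - r2[j]))
    d1 <- combined_desirability(desirability_mean(r2),
                                desirability_var(nu), cfg)
    expect_gte(d1[j] - d0[j], -1e-12)
    # increase one interior variability: D must not increase
    jv <- which(nu < max(nu) & nu > min(nu))[1]
    if (is.na(jv)) next
    n2 <- nu; n2[jv] <- min(max(nu), n2[jv] + 0.5 * (max(nu) - n2[jv]))
    d2 <- combined_desirability(desirability_mean(rbar),
                                desirability_var(n2), cfg)
    expect_lte(d2[jv] - d0[jv], 1e-12)
  }
})

test_that("ranking selects the top block with exp_id tie-breaks", {
  resp <- data.frame(exp_id = 1:6, r_mean = c(5, 9, 9, 2, 7, 9),
                     nu = c(1, 2, 2, 3, 2, 2))
  rk <- rank_and_select(resp, desirability_config(n_select = 4))
  expect_equal(sum(rk$selected), 4)
  expect_true(all(rk$D >= 0 & rk$D <= 1))
  expect_equal(max(rk$d_r), 1); expect_equal(min(rk$d_r), 0)
  # experiments 2, 3 and 6 are identical: ranked in exp_id order
  ties <- rk$exp_id[rk$rank %in% 1:3]
  expect_equal(ties, c(2, 3, 6))
  # all-equal D: pure exp_id order
  same <- data.frame(exp_id = 1:5, r_mean = rep(3, 5), nu = rep(1, 5))
  rk2 <- suppressWarnings(rank_and_select(same, desirability_config(n_select = 2)))
  expect_equal(rk2$exp_id[rk2$selected], c(1, 2))
  # a dominant point ranks first
  dom <- data.frame(exp_id = 1:3, r_mean = c(1, 50, 2), nu = c(5, 0.1, 5))
  rk3 <- rank_and_select(dom, desirability_config(n_select = 1))
  expect_equal(rk3$exp_id[rk3$rank == 1], 2)
})

test_that("quadratic response surfaces are recovered exactly from exact data", {
  sp <- design_space(data.frame(name = c("x", "y"), lower = 0, upper = 1))
  des <- plan_design(sp, k = 12, n_random = 3000, seed = 2)
  pts <- des$points
  truth <- function(x, y) 0.3 + 0.5 * x - 0.2 * y + 0.4 * x * y -
    0.6 * x^2 + 0.1 * y^2
  D <- truth(pts$x, pts$y)
  rs <- fit_response_surface(des, D)
  co <- rs$coefficients
  expect_equal(unname(co["(Intercept)"]), 0.3, tolerance = 1e-8)
  expect_equal(unname(co["x"]), 0.5, tolerance = 1e-8)
  expect_equal(unname(co["y"]), -0.2, tolerance = 1e-8)
  expect_equal(unname(co["x:y"]), 0.4, tolerance = 1e-8)
  expect_equal(unname(co["I(x^2)"]), -0.6, tolerance = 1e-8)
  expect_equal(unname(co["I(y^2)"]), 0.1, tolerance = 1e-8)
  expect_equal(rs$r2, 1, tolerance = 1e-9)
  # grid export spans the requested slice
  g <- rs_grid(rs, sp, "x", "y", n = 11)
  expect_equal(nrow(g), 121)
  expect_equal(g$D_fit, truth(g$x, g$y), tolerance = 1e-7)
})

test_that("degenerate surfaces behave: constant D and pure linear D", {
  sp <- design_space(data.frame(name = c("x", "y"), lower = 0, upper = 1))
  des <- plan_design(sp, k = 10, n_random = 2000, seed = 3)
  rs0 <- fit_response_surface(des, rep(0.4, 10))
  co <- rs0$coefficients
  expect_equal(unname(co["(Intercept)"]), 0.4, tolerance = 1e-10)
  expect_true(all(abs(co[names(co) != "(Intercept)"]) < 1e-10))
  rs1 <- fit_response_surface(des, 0.1 + 0.7 * des$points$x)
  expect_equal(unname(rs1$coefficients["x"]), 0.7, tolerance = 1e-8)
  expect_lt(abs(rs1$coefficients[["I(x^2)"]]), 1e-8)
  # too few points for the coefficient count
  sp1 <- design_space(data.frame(name = c("x", "y"), lower = 0, upper = 1))
  des4 <- plan_design(sp1, k = 4, n_random = 500, seed = 4)
  expect_error(fit_response_surface(des4, rep(1, 4)), "at least")
})
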