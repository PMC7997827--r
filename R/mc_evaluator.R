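#' Response specification
#'
#' Defines how one simulated trajectory is reduced to the scalar response
#' that the study maximizes: either the maximum of an observable over time
#' or its value at a fixed time.  Optional constraints (observable, upper
#' bound) are evaluated per simulation and reported as violation
#' fractions.
#'
#' @param observable column of the observed trajectory (e.g. "cDCW",
#'   "E3HB").
#' @param reduction "value_at_time" or "max_over_time".
#' @param at time (h) for value_at_time.
#' @param constraints optional list of \code{list(observable =, max =)}.
#' @return object of class \code{mdoe_response_spec}.
#' @export
response_spec <- function(observable,
                          reduction = c("value_at_time", "max_over_time"),
                          at = NULL, constraints = list()) {
  reduction <- match.arg(reduction)
  if (reduction == "value_at_time" && is.null(at))
    stop("response_spec: value_at_time needs 'at'")
  structure(list(observable = observable, reduction = reduction, at = at,
                 constraints = constraints),
            class = "mdoe_response_spec")
}

reduce_response <- function(traj, rspec) {
  d <- traj$data
  y <- d[[rspec$observable]]
  if (is.null(y)) stop("reduce_response: observable '", rspec$observable,
                       "' not in trajectory")
  if (rspec$reduction == "max_over_time") return(max(y))
  i <- which.min(abs(d$time_h - rspec$at))
  y[i]
}

#' Latin-Hypercube sample from a parameter ensemble
#'
#' Draws n parameter vectors by Latin Hypercube Sampling from the
#' per-parameter 10-90\% quantile box of the ensemble: each free parameter
#' gets exactly one draw in each of n equal-width strata of [q10, q90]
#' (R-7 quantiles), with the strata randomly permuted across parameters.
#' Parameters are sampled independently per dimension; the alternative
#' mode "members" resamples whole ensemble members instead, preserving
#' correlations.
#'
#' @param ensemble an \code{mdoe_ensemble}.
#' @param n number of draws.
#' @param seed integer seed.
#' @param mode "lhs" (default) or "members".
#' @return matrix n x n_free with parameter names as columns.
#' @export
lhs_sample <- function(ensemble, n, seed = 1L, mode = c("lhs", "members")) {
  mode <- match.arg(mode)
  if (n < 1L) stop("lhs_sample: n must be >= 1")
  free <- ensemble$free
  set.seed(seed)
  if (mode == "members") {
    idx <- sample.int(nrow(ensemble$members), n, replace = TRUE)
    return(ensemble$members[idx, , drop = FALSE])
  }
  L <- lhs::randomLHS(n, length(free))
  q10 <- ensemble$summary$q10
  q90 <- ensemble$summary$q90
  out <- sweep(sweep(L, 2, q90 - q10, "*"), 2, q10, "+")
  colnames(out) <- free
  out
}

#' Turn a design point into a scenario
#'
#' Applies a factor vector onto a scenario template using the factors'
#' \code{maps_to} setpoint paths.
#'
#' @param point named numeric factor vector (or one-row data.frame).
#' @param scenario the scenario template.
#' @param space the \code{mdoe_design_space} declaring the mapping.
#' @return the configured scenario.
#' @export
point_scenario <- function(point, scenario, space) {
  f <- space$factors
  if (is.data.frame(point))
    point <- stats::setNames(vapply(f$name, function(nm)
      as.numeric(point[[nm]][1]), numeric(1)), f$name)
  if (is.null(names(point)) && length(point) == nrow(f))
    names(point) <- f$name
  vals <- stats::setNames(as.numeric(point[f$name]), f$maps_to)
  apply_setpoints(scenario, vals)
}

#' Monte-Carlo simulation of one planned experiment
#'
#' Simulates the scenario of one design point once per parameter draw
#' (default 30 draws), reduces each trajectory to the scalar response, and
#' summarizes the response distribution by its mean and its 10-90\%
#' quantile width.  Failed simulations are excluded from the summary but
#' counted; the point is flagged when more than 20\% fail.
#'
#' @param point named factor vector.
#' @param draws matrix of parameter draws (rows = simulations), e.g. from
#'   \code{\link{lhs_sample}}.
#' @param scenario scenario template.
#' @param space design space (for the factor mapping).
#' @param rspec an \code{mdoe_response_spec}.
#' @param max_fail_frac failure tolerance (default 0.2).
#' @return list with r_mean, nu (q90 - q10), n_ok, n_fail, flagged,
#'   responses, constraint_violation (named fractions).
#' @export
simulate_design_point <- function(point, draws, scenario, space, rspec,
                                  max_fail_frac = 0.2) {
  sc <- point_scenario(point, scenario, space)
  pv <- default_params(sc$model)
  n <- nrow(draws)
  responses <- rep(NA_real_, n)
  viol <- matrix(FALSE, n, length(rspec$constraints))
  for (j in seq_len(n)) {
    pv[colnames(draws)] <- draws[j, ]
    traj <- tryCatch(simulate_scenario(sc, pv), error = function(e) NULL)
    if (is.null(traj)) next
    responses[j] <- reduce_response(traj, rspec)
    for (ci in seq_along(rspec$constraints)) {
      con <- rspec$constraints[[ci]]
      viol[j, ci] <- max(traj$data[[con$observable]]) > con$max
    }
  }
  ok <- !is.na(responses)
  n_ok <- sum(ok); n_fail <- n - n_ok
  if (n_ok == 0L)
    stop("simulate_design_point: all simulations failed")
  r_ok <- responses[ok]
  cv <- if (length(rspec$constraints) > 0L)
    stats::setNames(colMeans(viol[ok, , drop = FALSE]),
                    vapply(rspec$constraints, `[[`, character(1), "observable"))
  else numeric(0)
  list(r_mean = mean(r_ok),
       nu = quantile_r7(r_ok, 0.9) - quantile_r7(r_ok, 0.1),
       n_ok = n_ok, n_fail = n_fail,
       flagged = n_fail > max_fail_frac * n,
       responses = responses,
       constraint_violation = cv)
}

#' Simulate every planned experiment
#'
#' Runs \code{\link{simulate_design_point}} for each row of a design, each
#' with its own deterministic LHS draw from the ensemble.
#'
#' @param design an \code{mdoe_design}.
#' @param ensemble an \code{mdoe_ensemble}.
#' @param scenario scenario template.
#' @param rspec an \code{mdoe_response_spec}.
#' @param n_sims Monte-Carlo simulations per point (default 30).
#' @param seed master seed; per-point seeds are derived from it.
#' @param mode draw mode, see \code{\link{lhs_sample}}.
#' @return object of class \code{mdoe_responses}: data.frame with exp_id,
#'   factors, r_mean, nu, n_ok, n_fail, flagged (plus per-point responses
#'   in \code{attr(, "responses")}).
#' @export
evaluate_design <- function(design, ensemble, scenario, rspec,
                            n_sims = 30L, seed = 1L,
                            mode = c("lhs", "members")) {
  mode <- match.arg(mode)
  pts <- design$points
  seeds <- derive_seeds(seed, nrow(pts), stream = "mc")
  rows <- vector("list", nrow(pts))
  resp <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    draws <- lhs_sample(ensemble, n_sims, seed = seeds[i], mode = mode)
    s <- simulate_design_point(pts[i, ], draws, scenario, design$space, rspec)
    rows[[i]] <- data.frame(exp_id = pts$exp_id[i],
                            r_mean = s$r_mean, nu = s$nu,
                            n_ok = s$n_ok, n_fail = s$n_fail,
                            flagged = s$flagged)
    resp[[i]] <- s$responses
  }
  out <- cbind(pts["exp_id"],
               pts[, setdiff(names(pts), "exp_id"), drop = FALSE],
               do.call(rbind, rows)[, -1])
  attr(out, "responses") <- resp
  class(out) <- c("mdoe_responses", "data.frame")
  out
}
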