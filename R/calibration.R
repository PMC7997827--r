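#' Measurement datasets
#'
#' A measurement dataset holds the time series used for parameter
#' adaptation together with everything that carries experimental
#' uncertainty: per-point standard deviations, initial values, setpoints
#' (pH, feed rates, feed concentrations) and the unobserved split of the
#' initial biomass over the model compartments.
#'
#' @param measurements data.frame with columns observable, time_h, value,
#'   sd (sd may be NA: the relative default of the noise spec then
#'   applies).
#' @param initial named numeric vector of initial values keyed by setpoint
#'   path (e.g. \code{init.cDCW}, \code{init.Glc}).
#' @param setpoints named numeric vector keyed by setpoint path (e.g.
#'   \code{pH}, \code{feed.glc.F_end}).
#' @param split named fractions of the initial biomass over compartments.
#' @return object of class \code{mdoe_dataset}.
#' @export
measurement_dataset <- function(measurements, initial = numeric(0),
                                setpoints = numeric(0), split = numeric(0)) {
  req <- c("observable", "time_h", "value")
  if (!all(req %in% names(measurements)))
    stop("measurement_dataset: measurements need columns ",
         paste(req, collapse = ", "))
  if (is.null(measurements$sd)) measurements$sd <- NA_real_
  if (any(measurements$sd < 0, na.rm = TRUE))
    stop("measurement_dataset: negative sd")
  tab <- table(measurements$observable)
  if (any(tab < 2L))
    stop("measurement_dataset: need at least 2 points per observable (",
         paste(names(tab)[tab < 2L], collapse = ", "), ")")
  structure(list(measurements = measurements, initial = initial,
                 setpoints = setpoints, split = split),
            class = "mdoe_dataset")
}

#' Noise specification
#'
#' Relative standard deviations of the independent normal noise model:
#' measured values default to their per-point sd (falling back to
#' \code{measurement_rel}), initial values 5\%, the unobserved biomass
#' compartment split 10\%, and setpoints (pH, temperature, DO, feed rates
#' and feed concentrations) 5\%.
#'
#' @param measurement_rel fallback relative sd for measurements.
#' @param initial_rel relative sd of initial values.
#' @param compartment_rel relative sd of the initial compartment split.
#' @param setpoint_rel relative sd of setpoints.
#' @return object of class \code{mdoe_noise}.
#' @export
noise_spec <- function(measurement_rel = 0.05, initial_rel = 0.05,
                       compartment_rel = 0.10, setpoint_rel = 0.05) {
  v <- c(measurement_rel, initial_rel, compartment_rel, setpoint_rel)
  if (any(v < 0)) stop("noise_spec: relative sds must be >= 0")
  structure(list(measurement_rel = measurement_rel,
                 initial_rel = initial_rel,
                 compartment_rel = compartment_rel,
                 setpoint_rel = setpoint_rel),
            class = "mdoe_noise")
}

#' Perturb a dataset according to the noise model
#'
#' Every uncertain quantity is replaced by an independent normal draw
#' centered on its nominal value.  Draws for non-negative quantities that
#' come out negative are redrawn (truncated normal) rather than clipped,
#' so no probability mass piles up at zero.  The perturbed compartment
#' split is renormalized to sum to one.  Deterministic under \code{seed}.
#'
#' @param d an \code{mdoe_dataset}.
#' @param n an \code{mdoe_noise}.
#' @param seed integer seed.
#' @return a perturbed \code{mdoe_dataset}.
#' @export
perturb_dataset <- function(d, n = noise_spec(), seed = 1L) {
  stopifnot(inherits(d, "mdoe_dataset"), inherits(n, "mdoe_noise"))
  set.seed(seed)
  m <- d$measurements
  sd_eff <- ifelse(is.na(m$sd), n$measurement_rel * abs(m$value), m$sd)
  m$value <- rnorm_pos(nrow(m), m$value, sd_eff)
  ini <- d$initial
  if (length(ini) > 0L)
    ini[] <- rnorm_pos(length(ini), ini, n$initial_rel * abs(ini))
  sp <- d$setpoints
  if (length(sp) > 0L)
    sp[] <- rnorm_pos(length(sp), sp, n$setpoint_rel * abs(sp))
  spl <- d$split
  if (length(spl) > 0L) {
    spl[] <- rnorm_pos(length(spl), spl, n$compartment_rel * abs(spl))
    spl <- spl / sum(spl)
  }
  measurement_dataset(m, ini, sp, spl)
}

#' Weighted root-mean-square deviation
#'
#' RMSD = sqrt( sum_i k_i (y_s,i - y_m,i)^2 / n ) pooled over all
#' measurement rows.  Points of dry cell weight above 100 g/l receive
#' weight 0.5 (high-density points would otherwise dominate the residual
#' sum); all other points weight 1.  Because observables carry different
#' units, residuals are by default normalized by each observable's mean
#' absolute measured value before pooling (switchable off).
#'
#' @param y_sim numeric vector of simulated values aligned with the rows
#'   of \code{meas}.
#' @param meas data.frame with columns observable, time_h, value.
#' @param normalize normalize residuals per observable (default TRUE).
#' @param cdcw_rule apply the 0.5 weight to cDCW > 100 g/l (default TRUE).
#' @return scalar RMSD.
#' @export
rmsd <- function(y_sim, meas, normalize = TRUE, cdcw_rule = TRUE) {
  if (nrow(meas) == 0L) stop("rmsd: empty dataset")
  if (length(y_sim) != nrow(meas))
    stop("rmsd: y_sim must align with measurement rows")
  res <- y_sim - meas$value
  if (normalize) {
    for (obs in unique(meas$observable)) {
      i <- meas$observable == obs
      s <- mean(abs(meas$value[i]))
      if (s > 0) res[i] <- res[i] / s
    }
  }
  k <- rep(1, nrow(meas))
  if (cdcw_rule)
    k[meas$observable == "cDCW" & meas$value > 100] <- 0.5
  sqrt(sum(res^2 * k) / nrow(meas))
}

#' Coefficient of determination
#'
#' R2 = 1 - sum (y - y_s)^2 / sum (y - mean(y))^2.  Equals 1 for a perfect
#' fit, 0 when the model does no better than the mean of the data, and is
#' negative when the mean is closer to the data than the model.
#'
#' @param y_sim simulated values.
#' @param y_meas measured values (>= 2, with nonzero variance).
#' @return scalar R2, or NA (undefined marker) if the measurements have
#'   zero variance.
#' @export
r_squared <- function(y_sim, y_meas) {
  if (length(y_meas) < 2L) stop("r_squared: need at least 2 measurements")
  ss_tot <- sum((y_meas - mean(y_meas))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y_meas - y_sim)^2) / ss_tot
}

# simulate a scenario and read off the observables at the measurement rows
predict_measurements <- function(scenario, params, meas) {
  times <- sort(unique(c(0, meas$time_h)))
  traj <- simulate_scenario(scenario, params, t_grid = times)
  d <- traj$data
  out <- numeric(nrow(meas))
  for (obs in unique(meas$observable)) {
    i <- meas$observable == obs
    if (is.null(d[[obs]]))
      stop("predict_measurements: observable '", obs, "' not in trajectory")
    out[i] <- d[[obs]][match(meas$time_h[i], d$time_h)]
  }
  out
}

# apply a dataset's (possibly perturbed) conditions onto a scenario
apply_dataset_conditions <- function(scenario, dataset) {
  if (length(dataset$setpoints) > 0L)
    scenario <- apply_setpoints(scenario, dataset$setpoints)
  if (length(dataset$initial) > 0L)
    scenario <- apply_setpoints(scenario, dataset$initial)
  if (length(dataset$split) > 0L)
    scenario$split <- dataset$split / sum(dataset$split)
  scenario
}

#' Calibration configuration
#'
#' @param free character vector of free parameter names.
#' @param n_fits number of Monte-Carlo perturb-and-fit cycles.
#' @param n_starts multi-starts per fit (start points jittered around the
#'   nominal values).
#' @param maxit iteration budget of the simplex search per start.
#' @param jitter relative jitter of the additional start points.
#' @param normalize normalize residuals per observable in the RMSD.
#' @param seed base seed; per-fit seeds are derived from it.
#' @return object of class \code{mdoe_calib_config}.
#' @export
calibration_config <- function(free, n_fits = 30L, n_starts = 3L,
                               maxit = 150L, jitter = 0.10,
                               normalize = TRUE, seed = 1L) {
  if (n_fits < 1L) stop("calibration_config: n_fits must be >= 1")
  structure(list(free = free, n_fits = as.integer(n_fits),
                 n_starts = as.integer(n_starts), maxit = as.integer(maxit),
                 jitter = jitter, normalize = normalize,
                 seed = as.integer(seed)),
            class = "mdoe_calib_config")
}

# box-constrained parameters via a logistic transform; the simplex search
# runs unconstrained in z-space
to_z <- function(x, lo, hi) {
  u <- pmin(pmax((x - lo) / (hi - lo), 1e-8), 1 - 1e-8)
  log(u / (1 - u))
}
from_z <- function(z, lo, hi) lo + (hi - lo) / (1 + exp(-z))

#' Fit model parameters to a dataset
#'
#' Minimizes the weighted RMSD between simulated and measured observables
#' over the free-parameter subset with a bounded derivative-free simplex
#' search (Nelder-Mead on logistic-transformed coordinates), taking the
#' best of several jittered multi-starts.
#'
#' @param scenario an \code{mdoe_scenario} (conditions already set, e.g.
#'   via \code{apply_dataset_conditions}).
#' @param meas measurement data.frame (observable, time_h, value, sd).
#' @param cfg an \code{mdoe_calib_config}.
#' @param start optional named start vector for the free parameters
#'   (defaults to the model's defaults).
#' @param seed seed for the start-point jitter.
#' @return list with \code{params} (full named vector), \code{free}
#'   (fitted free values), \code{rmsd}, \code{converged},
#'   \code{n_evals}.
#' @export
fit_parameters <- function(scenario, meas, cfg, start = NULL, seed = 1L) {
  model <- scenario$model
  pv <- default_params(model)
  free <- cfg$free
  if (!all(free %in% names(pv)))
    stop("fit_parameters: unknown free parameters: ",
         paste(setdiff(free, names(pv)), collapse = ", "))
  lo <- stats::setNames(model$params$lower, model$params$name)[free]
  hi <- stats::setNames(model$params$upper, model$params$name)[free]
  x0 <- if (is.null(start)) pv[free] else start[free]

  objective <- function(z) {
    pv[free] <- from_z(z, lo, hi)
    y <- tryCatch(predict_measurements(scenario, pv, meas),
                  error = function(e) NULL)
    if (is.null(y) || any(!is.finite(y))) return(1e6)
    rmsd(y, meas, normalize = cfg$normalize)
  }

  set.seed(seed)
  starts <- list(x0)
  if (cfg$n_starts > 1L)
    for (j in seq_len(cfg$n_starts - 1L)) {
      xj <- x0 * (1 + stats::rnorm(length(x0), 0, cfg$jitter))
      starts[[j + 1L]] <- pmin(pmax(xj, lo), hi)
    }

  best <- NULL
  n_evals <- 0L
  for (x in starts) {
    z0 <- to_z(x, lo, hi)
    if (cfg$maxit <= 0L) {
      fit <- list(par = z0, value = objective(z0), convergence = 0L,
                  counts = c(1L, NA))
    } else {
      # suppressWarnings: optim warns on 1-D Nelder-Mead, which is still
      # adequate here (short, bounded-via-transform searches)
      fit <- tryCatch(
        suppressWarnings(
          stats::optim(z0, objective, method = "Nelder-Mead",
                       control = list(maxit = cfg$maxit, reltol = 1e-6))),
        error = function(e) NULL)
    }
    if (is.null(fit)) next
    n_evals <- n_evals + fit$counts[1]
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e6)
    stop("fit_parameters: all starts failed to produce a valid fit")
  pv[free] <- from_z(best$par, lo, hi)
  list(params = pv, free = pv[free], rmsd = best$value,
       converged = identical(best$convergence, 0L), n_evals = n_evals)
}

#' Monte-Carlo parameter-uncertainty ensemble
#'
#' Performs \code{cfg$n_fits} independent perturb-then-fit cycles: each
#' cycle perturbs the dataset (measurements, initial values, setpoints and
#' compartment split) according to the noise model, pushes the perturbed
#' conditions into the scenario, and re-fits the free parameters.  The
#' resulting ensemble is summarized by the per-parameter median and the
#' 10\%/90\% R-7 quantiles.
#'
#' @param scenario an \code{mdoe_scenario}.
#' @param dataset an \code{mdoe_dataset}.
#' @param cfg an \code{mdoe_calib_config}.
#' @param noise an \code{mdoe_noise}.
#' @return object of class \code{mdoe_ensemble}: \code{members} (n_fits x
#'   n_free matrix), \code{rmsd}, \code{converged}, \code{summary}
#'   (data.frame name, median, q10, q90), \code{free}, \code{bounds}.
#' @export
build_ensemble <- function(scenario, dataset, cfg, noise = noise_spec()) {
  seeds <- derive_seeds(cfg$seed, 2L * cfg$n_fits, stream = "calibration")
  members <- matrix(NA_real_, cfg$n_fits, length(cfg$free),
                    dimnames = list(NULL, cfg$free))
  rmsds <- rep(NA_real_, cfg$n_fits)
  conv <- rep(FALSE, cfg$n_fits)
  for (i in seq_len(cfg$n_fits)) {
    di <- perturb_dataset(dataset, noise, seed = seeds[2L * i - 1L])
    sci <- apply_dataset_conditions(scenario, di)
    fit <- tryCatch(
      fit_parameters(sci, di$measurements, cfg, seed = seeds[2L * i]),
      error = function(e) NULL)
    if (is.null(fit)) next
    members[i, ] <- fit$free
    rmsds[i] <- fit$rmsd
    conv[i] <- fit$converged
  }
  ok <- !is.na(rmsds)
  if (sum(ok) < cfg$n_fits / 2)
    stop("build_ensemble: more than half of the fits failed (",
         sum(!ok), "/", cfg$n_fits, ")")
  members <- members[ok, , drop = FALSE]
  summ <- data.frame(
    name = cfg$free,
    median = apply(members, 2, quantile_r7, p = 0.5),
    q10 = apply(members, 2, quantile_r7, p = 0.1),
    q90 = apply(members, 2, quantile_r7, p = 0.9),
    row.names = NULL, stringsAsFactors = FALSE)
  model <- scenario$model
  bounds <- data.frame(
    name = cfg$free,
    lower = stats::setNames(model$params$lower, model$params$name)[cfg$free],
    upper = stats::setNames(model$params$upper, model$params$name)[cfg$free],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(members = members, rmsd = rmsds[ok], converged = conv[ok],
                 summary = summ, free = cfg$free, bounds = bounds,
                 n_fits = cfg$n_fits, n_ok = sum(ok)),
            class = "mdoe_ensemble")
}

#' @export
print.mdoe_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d/%d fits, median RMSD %.4g\n",
              x$n_ok, x$n_fits, stats::median(x$rmsd)))
  print(x$summary, digits = 4)
  invisible(x)
}
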