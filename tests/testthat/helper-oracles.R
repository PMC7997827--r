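# Independent oracles used across tests.  These deliberately re-derive
# quantities by the most literal route available (explicit loops, manual
# interpolation) so they never share code with the implementation.

# R-7 quantile by manual interpolation on the order statistics
oracle_quantile_r7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(xs[n])
  xs[lo] + (h - lo) * (xs[lo + 1] - xs[lo])
}

# Eq.-8-style weighted RMSD recomputed from raw residual lists
oracle_rmsd <- function(y_sim, meas, normalize = TRUE) {
  total <- 0
  n <- nrow(meas)
  for (i in seq_len(n)) {
    r <- y_sim[i] - meas$value[i]
    if (normalize) {
      obs_vals <- meas$value[meas$observable == meas$observable[i]]
      m <- mean(abs(obs_vals))
      if (m > 0) r <- r / m
    }
    k <- if (meas$observable[i] == "cDCW" && meas$value[i] > 100) 0.5 else 1
    total <- total + r^2 * k
  }
  sqrt(total / n)
}

oracle_r_squared <- function(y_sim, y_meas) {
  num <- 0; den <- 0
  yb <- sum(y_meas) / length(y_meas)
  for (i in seq_along(y_meas)) {
    num <- num + (y_meas[i] - y_sim[i])^2
    den <- den + (y_meas[i] - yb)^2
  }
  1 - num / den
}

# elemental closure of a balanced pathway, recomputed from raw formulas
oracle_closure <- function(p) {
  res <- c(C = 0, H = 0, O = 0, N = 0)
  res <- res + p$substrate$formula
  for (sp in p$species) {
    s <- if (sp$side == "reactant") 1 else -1
    res <- res + s * sp$nu * sp$species$formula
  }
  res
}

# small random measurement table for oracle-equivalence checks
random_meas <- function(n, seed) {
  set.seed(seed)
  obs <- sample(c("cDCW", "Glc", "EtOH"), n, replace = TRUE)
  data.frame(observable = obs,
             time_h = seq_len(n),
             value = stats::runif(n, 0, 150),
             sd = stats::runif(n, 0, 5),
             stringsAsFactors = FALSE)
}

# fast max-over-cloud of distance to the nearest design point
maxmin_dist <- function(centers, cloud) {
  d2min <- rep(Inf, nrow(cloud))
  for (j in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(cloud, 2, centers[j, ], "-")^2)
    d2min <- pmin(d2min, d2)
  }
  sqrt(max(d2min))
}

toy_pipeline_config <- function() {
  list(
    scenario = scenario_toy(F = 0.3),
    synthetic = list(kind = "toy"),
    calibration = list(free = c("k", "b"), n_fits = 8, n_starts = 1,
                       maxit = 60),
    design = list(factors = list(list(name = "F", lower = 0, upper = 1.2,
                                      maps_to = "feed.f1.F")),
                  k = 15, n_random = 5000),
    mc = list(n_sims = 15),
    response = list(observable = "P", reduction = "value_at_time", at = 24),
    desirability = list(n_select = 3))
}
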