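#' Design space of experimental factors
#'
#' @param factors data.frame with columns name, lower, upper and optional
#'   units and maps_to (setpoint path used when a design point is turned
#'   into a scenario, e.g. \code{feed.glc.F_end}).
#' @param feasible optional predicate \code{function(x)} on a named factor
#'   vector returning TRUE for admissible combinations (e.g. a total feed
#'   budget); NULL accepts everything in the box.
#' @return object of class \code{mdoe_design_space}.
#' @export
design_space <- function(factors, feasible = NULL) {
  req <- c("name", "lower", "upper")
  if (!all(req %in% names(factors)))
    stop("design_space: factors need columns ", paste(req, collapse = ", "))
  if (nrow(factors) < 1L) stop("design_space: need at least one factor")
  if (any(factors$lower >= factors$upper))
    stop("design_space: lower must be < upper for every factor")
  if (is.null(factors$units)) factors$units <- ""
  if (is.null(factors$maps_to)) factors$maps_to <- factors$name
  structure(list(factors = factors, feasible = feasible),
            class = "mdoe_design_space")
}

#' Uniform random sample of the design space
#'
#' Draws i.i.d. uniform points inside the factor box; if a feasibility
#' predicate is present, infeasible points are rejected and redrawn until
#' the requested count is reached.
#'
#' @param space an \code{mdoe_design_space}.
#' @param n_random number of points (default 1e6, matching the large cloud
#'   the k-means planner is meant to summarize).
#' @param seed integer seed.
#' @return matrix n_random x n_factors with factor names as columns.
#' @export
sample_space <- function(space, n_random = 1e6, seed = 1L) {
  f <- space$factors
  set.seed(seed)
  draw <- function(n) {
    m <- vapply(seq_len(nrow(f)),
                function(j) stats::runif(n, f$lower[j], f$upper[j]),
                numeric(n))
    matrix(m, nrow = n, dimnames = list(NULL, f$name))
  }
  pts <- draw(n_random)
  if (!is.null(space$feasible)) {
    keep <- apply(pts, 1, space$feasible)
    frac <- mean(keep)
    if (frac < 1e-3)
      stop("sample_space: feasible fraction ", format(frac),
           " < 1e-3; revise the factor bounds")
    pts <- pts[keep, , drop = FALSE]
    while (nrow(pts) < n_random) {
      extra <- draw(ceiling((n_random - nrow(pts)) / frac) + 16L)
      extra <- extra[apply(extra, 1, space$feasible), , drop = FALSE]
      pts <- rbind(pts, extra)
    }
    pts <- pts[seq_len(n_random), , drop = FALSE]
  }
  pts
}

#' Plan a space-filling design by k-means clustering
#'
#' Clusters a large uniform sample of the (min-max scaled) factor space
#' with k-means; the k cluster centers, mapped back to factor units, are
#' the planned factor combinations.  Scaling to [0, 1] before clustering
#' keeps factors with large numeric ranges from dominating the distance.
#'
#' @param space an \code{mdoe_design_space}.
#' @param k number of planned experiments (default 29).
#' @param n_random size of the random cloud.
#' @param seed integer seed (controls both the cloud and the clustering).
#' @return object of class \code{mdoe_design}: \code{points} (data.frame
#'   exp_id + one column per factor), \code{space}, \code{meta}.
#' @export
plan_design <- function(space, k = 29L, n_random = 1e6, seed = 1L) {
  if (k < 1L) stop("plan_design: k must be >= 1")
  if (n_random < k) stop("plan_design: n_random must be >= k")
  f <- space$factors
  pts <- sample_space(space, n_random, seed = derive_seeds(seed, 1L, "cloud"))
  scaled <- sweep(sweep(pts, 2, f$lower, "-"), 2, f$upper - f$lower, "/")
  set.seed(derive_seeds(seed, 1L, "kmeans"))
  km <- if (k == nrow(scaled)) {
    list(centers = scaled)
  } else {
    # MacQueen avoids the Quick-TRANSfer pathology of Hartigan-Wong on
    # large uniform clouds; non-convergence at iter.max still returns the
    # best running centers, which is all a space-filling design needs
    suppressWarnings(
      stats::kmeans(scaled, centers = k, nstart = 10L, iter.max = 200L,
                    algorithm = "MacQueen"))
  }
  centers <- sweep(sweep(km$centers, 2, f$upper - f$lower, "*"),
                   2, f$lower, "+")
  centers <- matrix(centers, ncol = nrow(f), dimnames = list(NULL, f$name))
  points <- data.frame(exp_id = seq_len(nrow(centers)), centers)
  names(points) <- c("exp_id", f$name)
  structure(list(points = points, space = space,
                 meta = list(k = k, n_random = n_random, seed = seed,
                             scaling = "minmax")),
            class = "mdoe_design")
}

#' @export
print.mdoe_design <- function(x, ...) {
  cat(sprintf("<design> %d points over %d factors (n_random = %g, seed = %d)\n",
              nrow(x$points), nrow(x$space$factors),
              x$meta$n_random, x$meta$seed))
  print(utils::head(x$points, 8), digits = 4)
  if (nrow(x$points) > 8) cat("  ...\n")
  invisible(x)
}
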