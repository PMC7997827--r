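#' Desirability configuration
#'
#' Weights for combining the mean-response desirability and the
#' variability desirability into one score per planned experiment.  The
#' weights must sum to one; the weight on the variability term sets the
#' percentage at which the simulated spread is taken into account
#' (defaults 0.8/0.2).
#'
#' @param w1 weight on d(r_mean).
#' @param w2 weight on d(nu).
#' @param n_select number of experiments to recommend (2-4 typical).
#' @return object of class \code{mdoe_desirability_config}.
#' @export
desirability_config <- function(w1 = 0.8, w2 = 0.2, n_select = 4L) {
  if (abs(w1 + w2 - 1) > 1e-12)
    stop("desirability_config: w1 + w2 must equal 1")
  if (w1 < 0 || w1 > 1 || w2 < 0 || w2 > 1)
    stop("desirability_config: weights must lie in [0, 1]")
  if (n_select < 1L) stop("desirability_config: n_select must be >= 1")
  structure(list(w1 = w1, w2 = w2, n_select = as.integer(n_select)),
            class = "mdoe_desirability_config")
}

#' Desirability of the mean response (maximization)
#'
#' Linear min-max rescaling: d = (r - L)/(U - L) with L, U the minimum and
#' maximum over all planned experiments.  If all values coincide the
#' desirabilities are set to 1 with a warning (degenerate anchors).
#'
#' @param rbar vector of mean responses (>= 2 points).
#' @return vector of desirabilities in [0, 1].
#' @export
desirability_mean <- function(rbar) {
  if (length(rbar) < 2L) stop("desirability_mean: need >= 2 points")
  L <- min(rbar); U <- max(rbar)
  if (U == L) {
    warning("desirability_mean: all responses equal; desirability set to 1")
    return(rep(1, length(rbar)))
  }
  (rbar - L) / (U - L)
}

#' Desirability of the response variability (minimization)
#'
#' Inverse rescaling: d = (nu - U)/(L - U); the least variable experiment
#' scores 1, the most variable 0.
#'
#' @param nu vector of variability measures (q90 - q10; >= 2 points).
#' @return vector of desirabilities in [0, 1].
#' @export
desirability_var <- function(nu) {
  if (length(nu) < 2L) stop("desirability_var: need >= 2 points")
  L <- min(nu); U <- max(nu)
  if (U == L) {
    warning("desirability_var: all variabilities equal; desirability set to 1")
    return(rep(1, length(nu)))
  }
  (nu - U) / (L - U)
}

#' Combined desirability
#'
#' D = w1 * d_r + w2 * d_v, a convex combination of the mean-response and
#' variability desirabilities.
#'
#' @param d_r,d_v desirability vectors.
#' @param cfg an \code{mdoe_desirability_config}.
#' @return vector D in [0, 1].
#' @export
combined_desirability <- function(d_r, d_v, cfg = desirability_config()) {
  stopifnot(inherits(cfg, "mdoe_desirability_config"))
  if (length(d_r) != length(d_v))
    stop("combined_desirability: length mismatch")
  cfg$w1 * d_r + cfg$w2 * d_v
}

#' Rank planned experiments and select the recommended subset
#'
#' Computes d(r_mean), d(nu) and D for every planned experiment, ranks by
#' descending D (ties broken by lower exp_id for reproducibility) and
#' selects the top n_select experiments to actually perform.
#'
#' @param responses an \code{mdoe_responses} (or data.frame with exp_id,
#'   r_mean, nu).
#' @param cfg an \code{mdoe_desirability_config}.
#' @return object of class \code{mdoe_ranking}: the responses data.frame
#'   extended with d_r, d_v, D, rank, selected; plus anchors L/U in
#'   \code{attr(, "anchors")}.
#' @export
rank_and_select <- function(responses, cfg = desirability_config()) {
  r <- as.data.frame(responses)
  if (nrow(r) < cfg$n_select)
    stop("rank_and_select: fewer points than n_select")
  r$d_r <- desirability_mean(r$r_mean)
  r$d_v <- desirability_var(r$nu)
  r$D <- combined_desirability(r$d_r, r$d_v, cfg)
  ord <- order(-r$D, r$exp_id)
  r$rank <- NA_integer_
  r$rank[ord] <- seq_len(nrow(r))
  r$selected <- r$rank <= cfg$n_select
  r <- r[order(r$rank), ]
  rownames(r) <- NULL
  attr(r, "anchors") <- c(L_r = min(r$r_mean), U_r = max(r$r_mean),
                          L_nu = min(r$nu), U_nu = max(r$nu))
  class(r) <- c("mdoe_ranking", "data.frame")
  r
}

#' Quadratic response surface of the desirability
#'
#' Ordinary least-squares fit of D over the factors with intercept, linear,
#' two-way interaction and quadratic terms; used for visualization of the
#' desirability landscape (selection itself uses the raw D values).
#'
#' @param design an \code{mdoe_design}.
#' @param D desirability vector aligned with the design points (by
#'   exp_id).
#' @return object of class \code{mdoe_rs}: \code{fit} (lm), \code{r2},
#'   \code{coefficients}, \code{factors}.
#' @export
fit_response_surface <- function(design, D) {
  f <- design$space$factors$name
  df <- design$points[order(design$points$exp_id), f, drop = FALSE]
  if (length(D) != nrow(df))
    stop("fit_response_surface: D must align with the design points")
  n_coef <- 1 + length(f) + choose(length(f), 2) + length(f)
  if (nrow(df) < n_coef)
    stop("fit_response_surface: need at least ", n_coef, " points")
  df$D <- D
  rhs_terms <- c(f,
                 if (length(f) > 1) utils::combn(f, 2, paste, collapse = ":"),
                 paste0("I(", f, "^2)"))
  form <- stats::as.formula(paste("D ~", paste(rhs_terms, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  co <- stats::coef(fit)
  if (any(is.na(co)))
    stop("fit_response_surface: rank-deficient design; confounded terms: ",
         paste(names(co)[is.na(co)], collapse = ", "))
  # suppressWarnings: lm warns on numerically perfect fits, which occur
  # legitimately when D is an exact quadratic
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(fit = fit, coefficients = co, r2 = r2, factors = f),
            class = "mdoe_rs")
}

#' Response-surface contour grid
#'
#' Evaluates the fitted quadratic surface on a regular grid over two
#' factors, other factors fixed at given slice values; intended for
#' contour plotting (levels every 0.05).
#'
#' @param rs an \code{mdoe_rs}.
#' @param space the design space.
#' @param fx,fy names of the two grid factors.
#' @param slice named values of the remaining factors.
#' @param n grid resolution per axis.
#' @return data.frame with columns fx, fy, D_fit.
#' @export
rs_grid <- function(rs, space, fx, fy, slice = numeric(0), n = 41L) {
  f <- space$factors
  gx <- seq(f$lower[f$name == fx], f$upper[f$name == fx], length.out = n)
  gy <- seq(f$lower[f$name == fy], f$upper[f$name == fy], length.out = n)
  grid <- expand.grid(gx, gy)
  names(grid) <- c(fx, fy)
  for (nm in setdiff(f$name, c(fx, fy))) {
    if (!nm %in% names(slice))
      stop("rs_grid: missing slice value for factor '", nm, "'")
    grid[[nm]] <- slice[[nm]]
  }
  grid$D_fit <- stats::predict(rs$fit, newdata = grid)
  grid[, c(fx, fy, "D_fit")]
}
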