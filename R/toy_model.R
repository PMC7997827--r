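#' Minimal single-feed toy model
#'
#' A deliberately small plug-in model used in examples and smoke tests of
#' the full workflow.  A product P accumulates at a rate set by the feed
#' rate F (ml/min) of a single feed: dP/dt = k * F * exp(-F / F0) +
#' b * (F - F0)^2, dV/dt = F.  With b = 0 the expected response is
#' unimodal in F with its optimum at F = F0; an ensemble spread in b
#' inflates the response variability quadratically away from F0, which
#' makes the toy a sharp end-to-end probe of the ranking logic: the best
#' design point must sit near F0 both on mean response and on variability.
#'
#' @param unimodal logical; FALSE sets F0 large so that the response is
#'   effectively monotone increasing in F over small feed ranges (used by
#'   monotonicity checks).
#' @return an \code{mdoe_model} with states P, V and parameters k, b, F0.
#' @export
toy_model <- function(unimodal = TRUE) {
  p <- data.frame(
    name = c("k", "b", "F0"),
    value = c(2, 0, if (unimodal) 0.55 else 50),
    lower = c(0, -5, 0.05),
    upper = c(10, 5, 100),
    units = c("g/(l h)/(ml/min)", "g/(l h)/(ml/min)^2", "ml/min"),
    stringsAsFactors = FALSE)
  states <- c("P", "V")

  make_rhs <- function(params, feeds, env) {
    k <- params[["k"]]; b <- params[["b"]]; F0 <- params[["F0"]]
    function(t, y, parms = NULL) {
      Fml <- 0
      for (fd in feeds) Fml <- Fml + feed_rate(fd, t)
      dP <- k * Fml * exp(-Fml / F0) + b * (Fml - F0)^2
      list(c(dP, Fml * ML_MIN_TO_L_H))
    }
  }

  structure(list(name = "toy_single_feed", states = states,
                 conc_states = character(0),
                 params = p, make_rhs = make_rhs,
                 observe = function(traj) traj,
                 carbon = c(P = 0)),
            class = "mdoe_model")
}

#' Toy scenario around the toy model
#'
#' One constant feed "f1" whose rate is the single design factor.
#'
#' @param F feed rate, ml/min.
#' @param t_end horizon, h.
#' @param dt grid spacing, h.
#' @param unimodal passed to \code{\link{toy_model}}.
#' @return an \code{mdoe_scenario}.
#' @export
scenario_toy <- function(F = 0.3, t_end = 24, dt = 2, unimodal = TRUE) {
  feeds <- list(feed_schedule("f1", "constant", F = F,
                              t_start = 0, t_end = t_end))
  structure(list(model = toy_model(unimodal), init_conc = c(P = 0),
                 cDCW0 = 0, split = c(P = 1), V0 = 1,
                 feeds = feeds, env = process_environment(),
                 t_end = t_end, dt = dt, observables = "P"),
            class = "mdoe_scenario")
}
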