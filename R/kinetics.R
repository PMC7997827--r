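#' Double-sigmoid modifier parameters
#'
#' The double sigmoidal function is the product of two logistic transitions
#' and describes how a state variable (ethanol, glucose, EAA, pH, ...)
#' modulates a rate: it takes the value \code{Y_l} at low x, \code{Y_mid}
#' between the two transition midpoints \code{X_50l} and \code{X_50h}, and
#' \code{Y_h} at high x.  \code{K_sl} sets the steepness of the transitions;
#' an optional \code{K_sl_h} gives the upper flank its own slope.
#'
#' @param Y_l,Y_mid,Y_h plateau values (dimensionless); Y_mid must be nonzero.
#' @param K_sl slope, 1/(unit of x).
#' @param X_50l,X_50h transition midpoints (unit of x), X_50l <= X_50h.
#' @param K_sl_h optional separate slope for the upper transition
#'   (defaults to K_sl, the shared-slope form).
#' @return object of class \code{mdoe_sigmoid}.
#' @export
sigmoid_params <- function(Y_l, Y_mid, Y_h, K_sl, X_50l, X_50h, K_sl_h = K_sl) {
  if (Y_mid == 0) stop("sigmoid_params: Y_mid must be nonzero")
  if (!is.finite(K_sl) || !is.finite(K_sl_h))
    stop("sigmoid_params: slopes must be finite")
  if (X_50l > X_50h) stop("sigmoid_params: X_50l must be <= X_50h")
  structure(list(Y_l = Y_l, Y_mid = Y_mid, Y_h = Y_h, K_sl = K_sl,
                 X_50l = X_50l, X_50h = X_50h, K_sl_h = K_sl_h),
            class = "mdoe_sigmoid")
}

#' Evaluate a double-sigmoid modifier
#'
#' @param x state-variable value(s).
#' @param p an \code{mdoe_sigmoid} (or a plain list with the same fields).
#' @return dimensionless factor(s), same length as x.
#' @examples
#' p <- sigmoid_params(Y_l = 1, Y_mid = 1, Y_h = 0.05,
#'                     K_sl = 0.3, X_50l = 25, X_50h = 40)
#' dsig(0, p)    # ~1: no ethanol stress
#' dsig(100, p)  # ~0.05: strong inhibition
#' @export
dsig <- function(x, p) {
  if (p$Y_mid == 0) stop("dsig: Y_mid must be nonzero")
  ksl_h <- p$K_sl_h %||% p$K_sl
  low <- p$Y_l + (p$Y_mid - p$Y_l) / (1 + exp(-p$K_sl * (x - p$X_50l)))
  high <- 1 + (p$Y_h / p$Y_mid - 1) / (1 + exp(-ksl_h * (x - p$X_50h)))
  low * high
}

# compile a sigmoid into a scalar-arithmetic closure (hot path of the ODE
# right-hand side; avoids repeated list access)
dsig_compile <- function(p) {
  yl <- p$Y_l; ym <- p$Y_mid; yh <- p$Y_h
  k1 <- p$K_sl; k2 <- p$K_sl_h %||% p$K_sl
  x1 <- p$X_50l; x2 <- p$X_50h
  a <- ym - yl; b <- yh / ym - 1
  function(x)
    (yl + a / (1 + exp(-k1 * (x - x1)))) *
    (1 + b / (1 + exp(-k2 * (x - x2))))
}

# compile a feed schedule into a scalar rate function, l/h
feed_rate_compile <- function(fd) {
  t1 <- fd$t_start; t2 <- fd$t_end
  if (fd$kind == "constant") {
    Fc <- fd$F * ML_MIN_TO_L_H
    function(t) if (t >= t1 && t <= t2) Fc else 0
  } else if (fd$kind == "linear_ramp") {
    slope <- (if (fd$ramp_convention == "as_printed") fd$F_end / fd$t_end
              else fd$F_end / (fd$t_end - fd$t_start)) * ML_MIN_TO_L_H
    function(t) if (t >= t1 && t <= t2) slope * (t - t1) else 0
  } else {
    function(t) 0
  }
}

#' Substrate uptake kinetics
#'
#' Uptake follows Monod saturation in the substrate multiplied by the
#' product of double-sigmoid modifiers of other state variables (substrate
#' or product inhibition, pH, ...).
#'
#' @param rS_max maximum specific uptake rate, g substrate/(g biomass h).
#' @param K_s half-saturation constant, g/l (> 0).
#' @param modifiers list of entries \code{list(var = <state name>, params =
#'   <mdoe_sigmoid>)}.
#' @return object of class \code{mdoe_uptake}.
#' @export
uptake_kinetics <- function(rS_max, K_s, modifiers = list()) {
  if (rS_max < 0) stop("uptake_kinetics: rS_max must be >= 0")
  if (K_s <= 0) stop("uptake_kinetics: K_s must be > 0")
  structure(list(rS_max = rS_max, K_s = K_s, modifiers = modifiers),
            class = "mdoe_uptake")
}

#' Evaluate an uptake rate
#'
#' @param S substrate concentration, g/l (>= 0; negative values from solver
#'   round-off are clamped to 0).
#' @param k an \code{mdoe_uptake}.
#' @param state named numeric vector supplying the modifier variables
#'   (concentrations, pH, ...).
#' @return specific rate, g/(g h).
#' @export
uptake_rate <- function(S, k, state = numeric(0)) {
  S <- max(S, 0)
  r <- k$rS_max * S / (k$K_s + S)
  for (m in k$modifiers) {
    if (!m$var %in% names(state))
      stop("uptake_rate: modifier variable '", m$var, "' not found in state")
    x <- state[[m$var]]
    r <- r * dsig(x, m$params)
  }
  r
}
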