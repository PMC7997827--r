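#' Process-model plug-in contract
#'
#' A process model is a list with class \code{mdoe_model} carrying:
#' \itemize{
#'   \item \code{name}: identifier.
#'   \item \code{states}: character vector of state names; must include "V"
#'     (reactor volume, l).
#'   \item \code{conc_states}: subset of states that are concentrations
#'     (g/l) and are therefore diluted by feeding; extensive states
#'     (cumulative off-gas moles) are excluded.
#'   \item \code{params}: data.frame with columns name, value, lower, upper,
#'     units describing the flat parameter vector and its box bounds.
#'   \item \code{make_rhs(params, feeds, env)}: returns the derivative
#'     function \code{function(t, y, ...)} used by the integrator.
#'   \item \code{observe(traj)}: adds derived observables (e.g. cDCW) to a
#'     trajectory data.frame.
#'   \item \code{carbon}: named vector, g carbon per g of each concentration
#'     state (used by the carbon-accounting check); plus entries
#'     \code{CO2_mol} for gas states in mol.
#' }
#' Any structure satisfying this contract can be driven through
#' calibration, design simulation and desirability ranking.
#'
#' @param x object to test.
#' @return logical.
#' @export
is_mdoe_model <- function(x) inherits(x, "mdoe_model")

#' Default parameter vector of a model
#'
#' @param model an \code{mdoe_model}.
#' @return named numeric vector of default parameter values.
#' @export
default_params <- function(model) {
  stats::setNames(model$params$value, model$params$name)
}

# validate a parameter vector against the model's bounds
check_params <- function(model, params) {
  miss <- setdiff(model$params$name, names(params))
  if (length(miss) > 0L)
    stop("missing model parameters: ", paste(miss, collapse = ", "))
  lo <- stats::setNames(model$params$lower, model$params$name)
  hi <- stats::setNames(model$params$upper, model$params$name)
  v <- params[model$params$name]
  out <- v < lo - 1e-12 | v > hi + 1e-12
  if (any(out))
    stop("parameters out of bounds: ",
         paste(model$params$name[out], collapse = ", "))
  invisible(TRUE)
}

#' Structured six-compartment yeast model
#'
#' Reference mechanistic model of aerobic fed-batch growth and whole-cell
#' biocatalysis in \emph{S. cerevisiae}.  Biomass is segregated into six
#' compartments: autocatalytically active (Xpri), product-forming (Xp),
#' biocatalytically inactive (Xi), structurally active (Xs) and inactive
#' (Xsi), and dead (Xd).  Four elementally balanced pathways are modeled:
#' oxidative growth on glucose, overflow fermentation of glucose to ethanol
#' (Crabtree effect), oxidative growth on ethanol, and the biocatalytic
#' reduction of ethyl acetoacetate (EAA) to (S)-ethyl-3-hydroxybutyrate
#' (E3HB) with glucose as co-substrate.  Uptake rates are Monod terms
#' multiplied by double-sigmoid modifiers for glucose overflow, ethanol
#' inhibition, EAA inhibition and pH.  Compartment transfer (activation,
#' inactivation, maturation, mortality) is first order with stress-dependent
#' double-sigmoid factors.
#'
#' The nitrogen source is the lumped yeast-extract/peptone pool expressed
#' as assimilable ammonia equivalents (formula H3N).
#'
#' @param variant "S1" (growth study: biocatalysis off by default) or "S2"
#'   (biocatalysis study).
#' @return an \code{mdoe_model}.
#' @export
yeast_model <- function(variant = c("S1", "S2")) {
  variant <- match.arg(variant)
  p <- data.frame(
    name = c("rGlc_ox_max", "rGlc_ferm_max", "rEtOH_max", "rEAA_max",
             "Ks_Glc", "Ks_EtOH", "Ks_EAA", "Ks_N",
             "Y_XS_ox", "Y_XS_et", "nu_glc_bc",
             "k_act", "k_xp", "k_inact", "k_d",
             "crab_X50l", "etoh_inh_X50", "etoh_stress_X50",
             "pH_X50l", "pH_X50h"),
    value = c(0.55, 1.0, 0.20, if (variant == "S2") 0.05 else 0,
              0.15, 0.5, 0.05, 0.05,
              0.45, 0.60, 0.25,
              0.2, 0.05, 0.03, 0.008,
              0.6, 25, 38,
              3.8, 6.6),
    lower = c(0.1, 0.2, 0.02, 0,
              0.01, 0.05, 0.005, 0.005,
              0.30, 0.40, 0.10,
              0, 0, 0, 0,
              0.1, 10, 20,
              3.0, 5.5),
    upper = c(1.5, 2.5, 0.6, 0.2,
              1.0, 3.0, 0.5, 0.5,
              0.55, 0.72, 1.0,
              1.0, 0.5, 0.3, 0.1,
              5, 60, 80,
              5.0, 8.0),
    units = c("g/(g h)", "g/(g h)", "g/(g h)", "g/(g h)",
              "g/l", "g/l", "g/l", "g/l",
              "g/g", "g/g", "mol/mol",
              "1/h", "1/h", "1/h", "1/h",
              "g/l", "g/l", "g/l",
              "-", "-"),
    stringsAsFactors = FALSE)

  states <- c("Glc", "EtOH", "N", "EAA", "E3HB",
              "Xpri", "Xp", "Xi", "Xs", "Xsi", "Xd",
              "V", "O2", "CO2")
  conc_states <- setdiff(states, c("V", "O2", "CO2"))

  sp_glc <- species_glucose(); sp_et <- species_ethanol()
  sp_x <- species_biomass(); sp_n <- species_nsource()
  sp_o2 <- species_o2(); sp_co2 <- species_co2(); sp_h2o <- species_h2o()
  sp_eaa <- species_eaa(); sp_e3hb <- species_e3hb()

  build_pathways <- function(pv) {
    ox <- balance_pathway(pathway("glc_oxidative_growth", sp_glc, list(
      list(species = sp_o2, role = "O2", side = "reactant", nu = NA),
      list(species = sp_n, role = "N-source", side = "reactant", nu = NA),
      list(species = sp_x, role = "biomass", side = "product",
           nu = pv[["Y_XS_ox"]] * sp_glc$mw / sp_x$mw),
      list(species = sp_co2, role = "CO2", side = "product", nu = NA),
      list(species = sp_h2o, role = "H2O", side = "product", nu = NA))))
    ferm <- balance_pathway(pathway("glc_fermentation", sp_glc, list(
      list(species = sp_et, role = "product", side = "product", nu = NA),
      list(species = sp_co2, role = "CO2", side = "product", nu = NA),
      list(species = sp_h2o, role = "H2O", side = "product", nu = NA))))
    et_ox <- balance_pathway(pathway("etoh_oxidative_growth", sp_et, list(
      list(species = sp_o2, role = "O2", side = "reactant", nu = NA),
      list(species = sp_n, role = "N-source", side = "reactant", nu = NA),
      list(species = sp_x, role = "biomass", side = "product",
           nu = pv[["Y_XS_et"]] * sp_et$mw / sp_x$mw),
      list(species = sp_co2, role = "CO2", side = "product", nu = NA),
      list(species = sp_h2o, role = "H2O", side = "product", nu = NA))))
    bc <- balance_pathway(pathway("eaa_reduction", sp_eaa, list(
      list(species = sp_glc, role = "cosubstrate", side = "reactant",
           nu = pv[["nu_glc_bc"]]),
      list(species = sp_o2, role = "O2", side = "reactant", nu = NA),
      list(species = sp_e3hb, role = "product", side = "product", nu = 1),
      list(species = sp_co2, role = "CO2", side = "product", nu = NA),
      list(species = sp_h2o, role = "H2O", side = "product", nu = NA))))
    list(ox = ox, ferm = ferm, et_ox = et_ox, bc = bc)
  }

  make_rhs <- function(params, feeds, env) {
    pv <- params
    pw <- build_pathways(pv)
    y_ox <- pw$ox$yields; y_ferm <- pw$ferm$yields
    y_et <- pw$et_ox$yields; y_bc <- pw$bc$yields
    # double-sigmoid modifiers; midpoints exposed as flat parameters,
    # compiled to scalar closures for the solver hot path
    f_oxcap <- dsig_compile(sigmoid_params(1, 1, 0.4, 0.8, 2, 15))
    f_crab <- dsig_compile(sigmoid_params(0.05, 0.3, 1, 1.5, pv[["crab_X50l"]],
                                          pv[["crab_X50l"]] + 5))
    f_etinh <- dsig_compile(sigmoid_params(1, 1, 0.05, 0.25, pv[["etoh_inh_X50"]],
                                           pv[["etoh_inh_X50"]] + 15))
    f_glcrep <- dsig_compile(sigmoid_params(1, 0.5, 0.05, 8, 0.1, 1))
    f_stress <- dsig_compile(sigmoid_params(0.1, 0.2, 4, 0.25, 18,
                                            pv[["etoh_stress_X50"]]))
    f_eaainh <- dsig_compile(sigmoid_params(1, 1, 0.08, 4, 0.5, 2.5))
    f_eaastr <- dsig_compile(sigmoid_params(1, 1, 6, 2.5, 0.8, 3))
    f_act <- dsig_compile(sigmoid_params(0.05, 1, 1, 20, 0.02, 1000))
    ds_ph <- sigmoid_params(0.15, 1, 0.45, 2.5, pv[["pH_X50l"]], pv[["pH_X50h"]])
    ph_fac <- dsig(env$pH, ds_ph)  # pH is an exogenous constant setpoint
    mw_o2 <- sp_o2$mw; mw_co2 <- sp_co2$mw

    r_ox_max <- pv[["rGlc_ox_max"]]; r_ferm_max <- pv[["rGlc_ferm_max"]]
    r_et_max <- pv[["rEtOH_max"]]; r_bc_max <- pv[["rEAA_max"]]
    ks_glc <- pv[["Ks_Glc"]]; ks_et <- pv[["Ks_EtOH"]]
    ks_eaa <- pv[["Ks_EAA"]]; ks_n <- pv[["Ks_N"]]
    k_act <- pv[["k_act"]]; k_xp <- pv[["k_xp"]]
    k_inact <- pv[["k_inact"]]; k_d0 <- pv[["k_d"]]
    yox_n <- y_ox[["N-source"]]; yox_x <- y_ox[["biomass"]]
    yox_o2 <- y_ox[["O2"]]; yox_co2 <- y_ox[["CO2"]]
    yfe_et <- y_ferm[["ethanol"]]; yfe_co2 <- y_ferm[["CO2"]]
    yet_n <- y_et[["N-source"]]; yet_x <- y_et[["biomass"]]
    yet_o2 <- y_et[["O2"]]; yet_co2 <- y_et[["CO2"]]
    ybc_glc <- y_bc[["glucose"]]; ybc_p <- y_bc[["E3HB"]]
    ybc_o2 <- y_bc[["O2"]]; ybc_co2 <- y_bc[["CO2"]]

    rate_fns <- lapply(feeds, feed_rate_compile)
    # per-feed input vectors over the 11 concentration states, g/l
    comp_vecs <- lapply(feeds, function(fd) {
      v <- numeric(11)
      idx <- match(names(fd$composition), states[1:11])
      v[idx[!is.na(idx)]] <- fd$composition[!is.na(idx)]
      v
    })
    n_feeds <- length(feeds)

    function(t, y, parms = NULL) {
      Glc <- max(y[1], 0); EtOH <- max(y[2], 0); N <- max(y[3], 0)
      EAA <- max(y[4], 0)
      Xpri <- max(y[6], 0); Xp <- max(y[7], 0); Xi <- max(y[8], 0)
      Xs <- max(y[9], 0); Xsi <- max(y[10], 0)
      V <- y[12]

      mon_glc <- Glc / (ks_glc + Glc)
      mon_n <- N / (ks_n + N)
      et_fac <- f_etinh(EtOH)
      eaa_fac <- f_eaainh(EAA)

      # specific uptake rates, g substrate /(g catalyst h)
      q_ox <- r_ox_max * mon_glc * mon_n * f_oxcap(Glc) * et_fac * ph_fac * eaa_fac
      q_ferm <- r_ferm_max * mon_glc * f_crab(Glc) * et_fac * ph_fac
      q_et <- r_et_max * EtOH / (ks_et + EtOH) * mon_n *
        f_glcrep(Glc) * et_fac * ph_fac
      q_bc <- r_bc_max * EAA / (ks_eaa + EAA) * mon_glc * eaa_fac * et_fac

      R_ox <- q_ox * Xpri; R_ferm <- q_ferm * Xpri
      R_et <- q_et * Xpri; R_bc <- q_bc * Xp   # g substrate/(l h)

      # compartment transfer rates, g/(l h)
      stress <- f_stress(EtOH) * f_eaastr(EAA)
      r_act <- k_act * f_act(Glc) * Xs
      r_in <- k_inact * stress
      r_mat <- k_xp * Xpri
      kd <- k_d0 * stress

      growth <- yox_x * R_ox + yet_x * R_et
      dy <- c(-R_ox - R_ferm - ybc_glc * R_bc,          # Glc
              yfe_et * R_ferm - R_et,                   # EtOH
              -yox_n * R_ox - yet_n * R_et,             # N
              -R_bc,                                    # EAA
              ybc_p * R_bc,                             # E3HB
              growth + r_act - r_in * Xpri - r_mat - kd * Xpri,  # Xpri
              r_mat - kd * Xp,                          # Xp
              r_in * Xpri - kd * Xi,                    # Xi
              -r_act - r_in * Xs - kd * Xs,             # Xs
              r_in * Xs - kd * Xsi,                     # Xsi
              kd * (Xpri + Xp + Xi + Xs + Xsi))         # Xd

      # off-gas, mol/h (extensive)
      dO2 <- (yox_o2 * R_ox + yet_o2 * R_et + ybc_o2 * R_bc) * V / mw_o2
      dCO2 <- (yox_co2 * R_ox + yfe_co2 * R_ferm + yet_co2 * R_et +
                 ybc_co2 * R_bc) * V / mw_co2

      # feed input and dilution terms
      F_tot <- 0
      for (k in seq_len(n_feeds)) {
        Fk <- rate_fns[[k]](t)
        if (Fk > 0) {
          F_tot <- F_tot + Fk
          dy <- dy + comp_vecs[[k]] * (Fk / V)
        }
      }
      dy <- dy - y[1:11] * (F_tot / V)          # dilution of all g/l states
      out <- c(dy, F_tot, dO2, dCO2)
      if (any(!is.finite(out)))
        stop("yeast_model rhs: non-finite derivative for ",
             paste(states[!is.finite(out)], collapse = ", "), " at t = ", t)
      list(out)
    }
  }

  observe <- function(traj) {
    traj$cDCW <- traj$Xpri + traj$Xp + traj$Xi + traj$Xs + traj$Xsi + traj$Xd
    traj
  }

  carbon <- c(
    Glc = 6 * ATOMIC_MASS[["C"]] / sp_glc$mw,
    EtOH = 2 * ATOMIC_MASS[["C"]] / sp_et$mw,
    N = 0,
    EAA = 6 * ATOMIC_MASS[["C"]] / sp_eaa$mw,
    E3HB = 6 * ATOMIC_MASS[["C"]] / sp_e3hb$mw,
    Xpri = ATOMIC_MASS[["C"]] / sp_x$mw, Xp = ATOMIC_MASS[["C"]] / sp_x$mw,
    Xi = ATOMIC_MASS[["C"]] / sp_x$mw, Xs = ATOMIC_MASS[["C"]] / sp_x$mw,
    Xsi = ATOMIC_MASS[["C"]] / sp_x$mw, Xd = ATOMIC_MASS[["C"]] / sp_x$mw)

  structure(list(name = paste0("yeast_six_compartment_", variant),
                 variant = variant,
                 states = states, conc_states = conc_states,
                 params = p, make_rhs = make_rhs,
                 build_pathways = build_pathways,
                 observe = observe, carbon = carbon),
            class = "mdoe_model")
}

#' Evaluate the model right-hand side at one point
#'
#' Convenience wrapper around the compiled derivative function; mainly for
#' testing and for inspecting individual mass-balance terms.
#'
#' @param model an \code{mdoe_model}.
#' @param t time, h.
#' @param state named state vector.
#' @param params named parameter vector.
#' @param feeds list of \code{mdoe_feed}.
#' @param env environment list (pH, temperature, DO).
#' @return named vector of time derivatives.
#' @export
rhs <- function(model, t, state, params = default_params(model),
                feeds = list(), env = process_environment()) {
  f <- model$make_rhs(params, feeds, env)
  d <- f(t, state[model$states])[[1]]
  stats::setNames(d, model$states)
}

#' Exogenous environment setpoints
#'
#' pH, temperature and dissolved oxygen are controlled at constant
#' setpoints in the experiments the model describes; they enter the
#' kinetics only through double-sigmoid modifiers.
#'
#' @param pH medium pH (0-14).
#' @param temperature degrees C.
#' @param DO dissolved oxygen, % saturation.
#' @return list with class \code{mdoe_env}.
#' @export
process_environment <- function(pH = 5, temperature = 30, DO = 30) {
  if (pH <= 0 || pH >= 14) stop("process_environment: pH out of range")
  if (DO < 0 || DO > 100) stop("process_environment: DO out of range")
  structure(list(pH = pH, temperature = temperature, DO = DO),
            class = "mdoe_env")
}
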