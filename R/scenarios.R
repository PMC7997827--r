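#' Cultivation scenarios
#'
#' A scenario bundles everything needed to simulate one cultivation: the
#' model, initial concentrations, the initial biomass and its split over
#' the six compartments, reactor volume, feed schedules, environment
#' setpoints and the output time grid.  Scenario fields are addressable by
#' setpoint paths (e.g. \code{feed.glc.F_end}, \code{pH},
#' \code{init.cDCW}), the common currency of measurement-uncertainty
#' perturbation and of design-factor mapping.
#'
#' @name scenarios
NULL

new_scenario <- function(model, init_conc, cDCW0, split, V0, feeds, env,
                         t_end, dt, observables) {
  split <- split / sum(split)
  structure(list(model = model, init_conc = init_conc, cDCW0 = cDCW0,
                 split = split, V0 = V0, feeds = feeds, env = env,
                 t_end = t_end, dt = dt, observables = observables),
            class = "mdoe_scenario")
}

default_split <- function()
  c(Xpri = 0.55, Xp = 0.15, Xs = 0.20, Xi = 0.05, Xsi = 0.03, Xd = 0.02)

#' Growth-study scenario (pH + linearly rising glucose/nitrogen feeds)
#'
#' Fed-batch growth scenario: 0.70 l initial volume, 2 g/l initial dry
#' cell weight, 15 g/l initial glucose, complex nitrogen source, glucose
#' (400 g/l) and nitrogen feeds as linear ramps active from 1 h to 48 h.
#' The lumped yeast-extract/peptone nitrogen pool is expressed as
#' assimilable-ammonia equivalents with a configurable fraction per gram.
#'
#' @param F_Glc_end,F_N_end ramp endpoint feed rates, ml/min.
#' @param pH controlled pH setpoint.
#' @param t_end horizon, h.
#' @param dt output grid spacing, h.
#' @param n_fraction assimilable-N equivalents per g of YE+peptone (g/g).
#' @param model optionally a pre-built model (variant "S1").
#' @return an \code{mdoe_scenario}.
#' @export
scenario_s1 <- function(F_Glc_end = 0.42, F_N_end = 0.20, pH = 5.0,
                        t_end = 48, dt = 2, n_fraction = 0.12,
                        model = yeast_model("S1")) {
  feeds <- list(
    feed_schedule("glc", "linear_ramp", F_end = F_Glc_end,
                  t_start = 1, t_end = t_end,
                  composition = c(Glc = 400)),
    feed_schedule("n", "linear_ramp", F_end = F_N_end,
                  t_start = 1, t_end = t_end,
                  composition = c(N = n_fraction * (130 + 270))))
  new_scenario(model,
               init_conc = c(Glc = 15, EtOH = 0,
                             N = n_fraction * (1.4 + 2.3), EAA = 0, E3HB = 0),
               cDCW0 = 2.0, split = default_split(), V0 = 0.70,
               feeds = feeds, env = process_environment(pH = pH),
               t_end = t_end, dt = dt,
               observables = c("cDCW", "Glc", "EtOH"))
}

#' Biocatalysis scenario (constant EAA/glucose/nitrogen feeds)
#'
#' Whole-cell biocatalysis scenario: 0.64 l initial volume, 30 g/l
#' directly inoculated dry cell weight, constant feeds of pure ethyl
#' acetoacetate (1021 g/l), glucose (400 g/l) and nitrogen source.
#'
#' @param F_EAA,F_Glc,F_N constant feed rates, ml/min.
#' @param pH controlled pH setpoint.
#' @param t_end horizon, h.
#' @param dt output grid spacing, h.
#' @param n_fraction assimilable-N equivalents per g of YE+peptone (g/g).
#' @param model optionally a pre-built model (variant "S2").
#' @return an \code{mdoe_scenario}.
#' @export
scenario_s2 <- function(F_EAA = 0.02, F_Glc = 0.11, F_N = 0.01, pH = 5.0,
                        t_end = 48, dt = 2, n_fraction = 0.12,
                        model = yeast_model("S2")) {
  feeds <- list(
    feed_schedule("eaa", "constant", F = F_EAA, t_start = 0, t_end = t_end,
                  composition = c(EAA = 1021)),
    feed_schedule("glc", "constant", F = F_Glc, t_start = 0, t_end = t_end,
                  composition = c(Glc = 400)),
    feed_schedule("n", "constant", F = F_N, t_start = 0, t_end = t_end,
                  composition = c(N = n_fraction * (130 + 270))))
  new_scenario(model,
               init_conc = c(Glc = 2.0, EtOH = 0,
                             N = n_fraction * (1.6 + 2.4), EAA = 0, E3HB = 0),
               cDCW0 = 30, split = default_split(), V0 = 0.64,
               feeds = feeds, env = process_environment(pH = pH),
               t_end = t_end, dt = dt,
               observables = c("cDCW", "Glc", "EtOH", "EAA", "E3HB"))
}

#' Initial state vector of a scenario
#'
#' Expands initial concentrations plus the compartment split of the
#' initial biomass into the model's full state vector.
#'
#' @param scenario an \code{mdoe_scenario}.
#' @return named numeric vector over the model states.
#' @export
scenario_initial_state <- function(scenario) {
  model <- scenario$model
  y0 <- stats::setNames(numeric(length(model$states)), model$states)
  for (nm in names(scenario$init_conc))
    if (nm %in% model$states) y0[[nm]] <- scenario$init_conc[[nm]]
  split <- scenario$split / sum(scenario$split)
  for (nm in names(split))
    if (nm %in% model$states) y0[[nm]] <- scenario$cDCW0 * split[[nm]]
  y0[["V"]] <- scenario$V0
  y0
}

#' Simulate a scenario
#'
#' @param scenario an \code{mdoe_scenario}.
#' @param params named parameter vector (defaults to model defaults).
#' @param t_grid optional output grid (defaults to seq(0, t_end, dt)).
#' @param ... passed to \code{\link{simulate_process}}.
#' @return an \code{mdoe_trajectory}.
#' @export
simulate_scenario <- function(scenario, params = default_params(scenario$model),
                              t_grid = NULL, ...) {
  if (is.null(t_grid)) t_grid <- seq(0, scenario$t_end, by = scenario$dt)
  simulate_process(scenario$model, params, scenario_initial_state(scenario),
                   scenario$feeds, scenario$env, t_grid, ...)
}

#' Current setpoint values of a scenario
#'
#' Returns the scenario fields that are experimental setpoints (pH, feed
#' rates, feed concentrations) as a named vector keyed by setpoint path.
#'
#' @param scenario an \code{mdoe_scenario}.
#' @return named numeric vector.
#' @export
scenario_setpoints <- function(scenario) {
  out <- c(pH = scenario$env$pH)
  for (fd in scenario$feeds) {
    if (fd$kind == "constant")
      out[paste0("feed.", fd$id, ".F")] <- fd$F
    if (fd$kind == "linear_ramp")
      out[paste0("feed.", fd$id, ".F_end")] <- fd$F_end
    for (nm in names(fd$composition))
      out[paste0("feedconc.", fd$id, ".", nm)] <- fd$composition[[nm]]
  }
  out
}

#' Apply setpoint values to a scenario
#'
#' Writes named values back into a scenario.  Recognized path forms:
#' \code{pH}; \code{feed.<id>.F}; \code{feed.<id>.F_end};
#' \code{feedconc.<id>.<component>}; \code{init.cDCW};
#' \code{init.<component>}; \code{split.<compartment>}.
#'
#' @param scenario an \code{mdoe_scenario}.
#' @param values named numeric vector of setpoint paths.
#' @return the modified scenario.
#' @export
apply_setpoints <- function(scenario, values) {
  feed_ids <- vapply(scenario$feeds, `[[`, character(1), "id")
  for (key in names(values)) {
    v <- unname(values[[key]])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (key == "pH") {
      scenario$env$pH <- v
    } else if (parts[1] == "feed" && length(parts) == 3L) {
      i <- match(parts[2], feed_ids)
      if (is.na(i)) stop("apply_setpoints: unknown feed '", parts[2], "'")
      scenario$feeds[[i]][[parts[3]]] <- v
    } else if (parts[1] == "feedconc" && length(parts) == 3L) {
      i <- match(parts[2], feed_ids)
      if (is.na(i)) stop("apply_setpoints: unknown feed '", parts[2], "'")
      scenario$feeds[[i]]$composition[[parts[3]]] <- v
    } else if (parts[1] == "init" && length(parts) == 2L) {
      if (parts[2] == "cDCW") scenario$cDCW0 <- v
      else scenario$init_conc[[parts[2]]] <- v
    } else if (parts[1] == "split" && length(parts) == 2L) {
      scenario$split[[parts[2]]] <- v
    } else {
      stop("apply_setpoints: unrecognized setpoint path '", key, "'")
    }
  }
  scenario
}
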