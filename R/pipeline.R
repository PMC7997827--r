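#' Resolve a study configuration into concrete objects
#'
#' Accepts either programmatic objects (an \code{mdoe_scenario},
#' \code{mdoe_dataset}, \code{mdoe_design_space} placed directly in the
#' list) or declarative sections as read from YAML/JSON, and returns the
#' fully constructed inputs of the pipeline stages.  Per-stage seeds are
#' derived deterministically from the master seed so the whole run is a
#' pure function of (config, seed).
#'
#' @param cfg configuration list or path to a YAML/JSON file.
#' @param seed master seed (overrides \code{cfg$seed}).
#' @param out_dir output directory (overrides \code{cfg$out_dir}).
#' @return list with scenario, dataset, noise, calib_cfg, space, design
#'   settings, rspec, des_cfg, mc settings, seeds, out_dir.
#' @export
resolve_study_config <- function(cfg, seed = NULL, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  out_dir <- out_dir %||% cfg$out_dir %||% file.path(tempdir(), "mdoe_run")
  seeds <- stats::setNames(derive_seeds(seed, 4L, "pipeline"),
                           c("synthetic", "calibration", "design", "mc"))

  scenario <- cfg$scenario
  if (!inherits(scenario, "mdoe_scenario")) {
    kind <- cfg$scenario$kind %||% "S1"
    args <- cfg$scenario$args %||% list()
    scenario <- switch(kind,
                       S1 = do.call(scenario_s1, args),
                       S2 = do.call(scenario_s2, args),
                       toy = do.call(scenario_toy, args),
                       stop("resolve_study_config: unknown scenario kind '",
                            kind, "'"))
  }

  noise <- if (inherits(cfg$noise, "mdoe_noise")) cfg$noise
  else do.call(noise_spec, as.list(cfg$noise %||% list()))

  dataset <- cfg$dataset
  synth <- NULL
  if (!inherits(dataset, "mdoe_dataset")) {
    if (!is.null(cfg$synthetic)) {
      synth <- generate_synthetic_study(
        kind = cfg$synthetic$kind %||% cfg$scenario$kind %||% "S1",
        truth = unlist(cfg$synthetic$truth %||% numeric(0)),
        noise = noise,
        seed = as.integer(cfg$synthetic$seed %||% seeds[["synthetic"]]),
        sample_every = cfg$synthetic$sample_every %||% 4,
        scenario = scenario)
      dataset <- synth$dataset
    } else if (!is.null(cfg$dataset$path)) {
      if (!file.exists(cfg$dataset$path))
        stop("resolve_study_config: dataset file does not exist: ",
             cfg$dataset$path)
      dataset <- read_dataset_csv(cfg$dataset$path,
                                  initial = unlist(cfg$dataset$initial %||% numeric(0)),
                                  setpoints = unlist(cfg$dataset$setpoints %||% numeric(0)),
                                  split = unlist(cfg$dataset$split %||% numeric(0)))
    } else {
      stop("resolve_study_config: no dataset (provide dataset$path, a ",
           "measurement_dataset, or a synthetic section)")
    }
  }

  cal <- cfg$calibration %||% list()
  if (is.null(cal$free))
    stop("resolve_study_config: calibration$free must name the free parameters")
  calib_cfg <- calibration_config(
    free = unlist(cal$free), n_fits = cal$n_fits %||% 30L,
    n_starts = cal$n_starts %||% 3L, maxit = cal$maxit %||% 150L,
    jitter = cal$jitter %||% 0.10, normalize = cal$normalize %||% TRUE,
    seed = cal$seed %||% seeds[["calibration"]])

  space <- cfg$design$space %||% cfg$space
  if (!inherits(space, "mdoe_design_space")) {
    fl <- cfg$design$factors
    if (is.null(fl)) stop("resolve_study_config: design$factors missing")
    fdf <- if (is.data.frame(fl)) fl else
      do.call(rbind, lapply(fl, function(x)
        data.frame(name = x$name, lower = x$lower, upper = x$upper,
                   units = x$units %||% "", maps_to = x$maps_to %||% x$name,
                   stringsAsFactors = FALSE)))
    space <- design_space(fdf)
  }

  resp <- cfg$response %||% list()
  rspec <- if (inherits(resp, "mdoe_response_spec")) resp
  else response_spec(
    observable = resp$observable %||%
      scenario$observables[length(scenario$observables)],
    reduction = resp$reduction %||% "value_at_time",
    at = resp$at %||% scenario$t_end,
    constraints = resp$constraints %||% list())

  des <- cfg$desirability %||% list()
  des_cfg <- if (inherits(des, "mdoe_desirability_config")) des
  else desirability_config(w1 = des$w1 %||% 0.8, w2 = des$w2 %||% 0.2,
                           n_select = des$n_select %||% 4L)

  list(scenario = scenario, dataset = dataset, synth = synth, noise = noise,
       calib_cfg = calib_cfg, space = space,
       k = as.integer(cfg$design$k %||% 29L),
       n_random = cfg$design$n_random %||% 1e6,
       design_seed = as.integer(cfg$design$seed %||% seeds[["design"]]),
       rspec = rspec, des_cfg = des_cfg,
       n_sims = as.integer(cfg$mc$n_sims %||% 30L),
       mc_seed = as.integer(cfg$mc$seed %||% seeds[["mc"]]),
       mc_mode = cfg$mc$mode %||% "lhs",
       seed = seed, out_dir = out_dir)
}

#' Run the full model-assisted DoE pipeline
#'
#' Executes the four computational stages in order -- Monte-Carlo
#' parameter-uncertainty quantification, k-means design planning,
#' Latin-Hypercube Monte-Carlo simulation of every planned experiment, and
#' desirability-based ranking -- and writes all artifacts (ensemble,
#' design, per-point response summaries, ranking, response-surface grids,
#' run log) as CSV/text into the output directory.  A stage failure aborts
#' with the stage name; artifacts of completed stages are preserved.
#'
#' @param cfg configuration (list or YAML/JSON path), see
#'   \code{\link{resolve_study_config}}.
#' @param seed master seed (overrides the config).
#' @param out_dir output directory (overrides the config).
#' @return invisibly, a list with ensemble, design, responses, ranking,
#'   rs, paths and the resolved configuration.
#' @export
run_pipeline <- function(cfg, seed = NULL, out_dir = NULL) {
  rc <- resolve_study_config(cfg, seed = seed, out_dir = out_dir)
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  t_begin <- proc.time()[["elapsed"]]
  log <- list(seed = rc$seed, model = rc$scenario$model$name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("run_pipeline [stage ", name, "]: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(rc$synth)) {
    paths$dataset <- file.path(rc$out_dir, "dataset.csv")
    write_dataset_csv(rc$dataset, paths$dataset)
  }

  ensemble <- stage("calibrate",
    build_ensemble(rc$scenario, rc$dataset, rc$calib_cfg, rc$noise))
  paths$ensemble <- file.path(rc$out_dir, "ensemble.csv")
  write_ensemble_csv(ensemble, paths$ensemble)
  log$n_fits <- ensemble$n_fits; log$n_fits_ok <- ensemble$n_ok

  design <- stage("plan",
    plan_design(rc$space, k = rc$k, n_random = rc$n_random,
                seed = rc$design_seed))
  paths$design <- file.path(rc$out_dir, "design.csv")
  write_design_csv(design, paths$design)
  log$k <- rc$k; log$n_random <- rc$n_random

  responses <- stage("simulate-design",
    evaluate_design(design, ensemble, rc$scenario, rc$rspec,
                    n_sims = rc$n_sims, seed = rc$mc_seed,
                    mode = rc$mc_mode))
  paths$responses <- file.path(rc$out_dir, "responses.csv")
  write_responses_csv(responses, paths$responses)
  log$n_sims <- rc$n_sims
  log$n_sim_failures <- sum(responses$n_fail)

  ranking <- stage("evaluate",
    rank_and_select(responses, rc$des_cfg))
  paths$ranking <- file.path(rc$out_dir, "ranking.csv")
  write_ranking_csv(ranking, paths$ranking)

  rs <- NULL
  fnames <- rc$space$factors$name
  n_coef <- 1 + 2 * length(fnames) + choose(length(fnames), 2)
  if (nrow(design$points) >= n_coef) {
    rs <- stage("evaluate", {
      Dord <- ranking$D[order(ranking$exp_id)]
      fit_response_surface(design, Dord)
    })
    if (length(fnames) >= 2) {
      best <- ranking[1, ]
      prs <- utils::combn(fnames, 2, simplify = FALSE)
      for (pr in prs) {
        slice <- unlist(best[setdiff(fnames, pr)])
        g <- rs_grid(rs, rc$space, pr[1], pr[2], slice = slice)
        p <- file.path(rc$out_dir, paste0("rs_", pr[1], "_", pr[2], ".csv"))
        write_csv0(g, p)
        paths[[paste0("rs_", pr[1], "_", pr[2])]] <- p
      }
    }
    log$rs_r2 <- round(rs$r2, 4)
  }

  log$selected <- paste(ranking$exp_id[ranking$selected], collapse = ",")
  log$elapsed_s <- round(proc.time()[["elapsed"]] - t_begin, 2)
  paths$log <- file.path(rc$out_dir, "run_log.txt")
  write_run_log(paths$log, log)

  invisible(list(ensemble = ensemble, design = design,
                 responses = responses, ranking = ranking, rs = rs,
                 paths = paths, config = rc))
}
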