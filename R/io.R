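#' CSV and configuration I/O
#'
#' All tables are written as UTF-8 comma-separated files with a header row
#' and '.' decimal separator; every writer has a paired reader that
#' round-trips values losslessly (values are printed with 15 significant
#' digits).
#'
#' @name mdoe_io
NULL

write_csv0 <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]])) df2[[j]] <- format(df2[[j]], digits = 15,
                                                 trim = TRUE, scientific = FALSE)
  utils::write.csv(df2, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a trajectory table
#'
#' Columns: time_h, every state variable, derived observables, per-feed
#' flow in ml/min, and the interval respiratory quotient.
#'
#' @param traj an \code{mdoe_trajectory}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  write_csv0(trajectory_table(traj), path)
}

#' Read / write a measurement dataset
#'
#' @param d an \code{mdoe_dataset}.
#' @param path CSV file with columns observable, time_h, value, sd.
#' @return \code{write_dataset_csv}: the path; \code{read_dataset_csv}: an
#'   \code{mdoe_dataset}.
#' @export
write_dataset_csv <- function(d, path) {
  write_csv0(d$measurements, path)
}

#' @param initial,setpoints,split condition vectors attached to the read
#'   dataset (they are configuration, not part of the time-series CSV).
#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, initial = numeric(0),
                             setpoints = numeric(0), split = numeric(0)) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  measurement_dataset(m, initial, setpoints, split)
}

#' Write pipeline artifacts
#'
#' @param x object to write (ensemble, design, responses, ranking).
#' @param path output file.
#' @return the path, invisibly.
#' @name write_artifacts
NULL

#' @rdname write_artifacts
#' @export
write_ensemble_csv <- function(x, path) {
  df <- data.frame(fit = seq_len(nrow(x$members)), x$members,
                   rmsd = x$rmsd, converged = x$converged)
  write_csv0(df, path)
}

#' @param free free-parameter names (columns of the members matrix).
#' @param bounds data.frame name, lower, upper.
#' @rdname write_artifacts
#' @export
read_ensemble_csv <- function(path, free = NULL, bounds = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (is.null(free))
    free <- setdiff(names(df), c("fit", "rmsd", "converged"))
  members <- as.matrix(df[, free, drop = FALSE])
  summ <- data.frame(name = free,
                     median = apply(members, 2, quantile_r7, p = 0.5),
                     q10 = apply(members, 2, quantile_r7, p = 0.1),
                     q90 = apply(members, 2, quantile_r7, p = 0.9),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(members = members, rmsd = df$rmsd, converged = df$converged,
                 summary = summ, free = free, bounds = bounds,
                 n_fits = nrow(members), n_ok = nrow(members)),
            class = "mdoe_ensemble")
}

#' @rdname write_artifacts
#' @export
write_design_csv <- function(x, path) {
  write_csv0(x$points, path)
}

#' @param space design space used to rebuild the design object.
#' @rdname write_artifacts
#' @export
read_design_csv <- function(path, space) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  structure(list(points = pts, space = space,
                 meta = list(k = nrow(pts), n_random = NA, seed = NA,
                             scaling = "minmax")),
            class = "mdoe_design")
}

#' @rdname write_artifacts
#' @export
write_responses_csv <- function(x, path) {
  write_csv0(as.data.frame(x), path)
}

#' @rdname write_artifacts
#' @export
read_responses_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  class(out) <- c("mdoe_responses", "data.frame")
  out
}

#' @rdname write_artifacts
#' @export
write_ranking_csv <- function(x, path) {
  write_csv0(as.data.frame(x), path)
}

#' Read a study configuration
#'
#' YAML (or JSON) configuration with sections scenario, dataset (or
#' synthetic), calibration, noise, design, mc, response, desirability,
#' seed.  Referenced files are checked for existence before any
#' computation starts.
#'
#' @param path configuration file (.yml/.yaml/.json).
#' @return the configuration list (class \code{mdoe_config}).
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("read_study_config: no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
  if (!is.null(cfg$dataset$path) && !file.exists(cfg$dataset$path))
    stop("read_study_config: dataset file does not exist: ", cfg$dataset$path)
  class(cfg) <- c("mdoe_config", class(cfg))
  cfg
}

write_run_log <- function(path, entries) {
  lines <- vapply(names(entries), function(k)
    paste0(k, ": ", paste(format(entries[[k]]), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
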