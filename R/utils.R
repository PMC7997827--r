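#' R-7 sample quantile
#'
#' Linear-interpolation quantile with plotting position h = (n - 1) p + 1,
#' i.e. the default (type 7) definition in R.  All ensemble and response
#' summaries in the package use this definition so that interval bounds are
#' consistent across modules.
#'
#' @param x numeric vector, non-empty.
#' @param p probability (or vector of probabilities) in [0, 1].
#' @return numeric vector of quantiles, unnamed.
#' @examples
#' quantile_r7(1:10, 0.1)  # 1.9
#' @export
quantile_r7 <- function(x, p) {
  if (length(x) == 0L) stop("quantile_r7: empty sample")
  if (any(!is.finite(x))) stop("quantile_r7: non-finite values in sample")
  if (any(p < 0 | p > 1)) stop("quantile_r7: p must lie in [0, 1]")
  stats::quantile(x, probs = p, type = 7, names = FALSE)
}

#' Derive per-stage random seeds from a master seed
#'
#' The pipeline is a pure function of (config, seed).  Each stage (and each
#' fit / design point within a stage) receives its own seed derived
#' deterministically from the master seed, so that stages are reproducible
#' individually and changing e.g. the number of fits does not perturb the
#' design stage.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @param stream optional character tag separating independent uses.
#' @return integer vector of length n, each in [1, 2^31 - 2].
#' @export
derive_seeds <- function(seed, n, stream = "default") {
  # simple splitmix-style integer hash, kept in 31-bit range
  h <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(stream)) h <- (h * 69069 + ch) %% 2147483647
  out <- integer(n)
  for (i in seq_len(n)) {
    h <- (h * 48271) %% 2147483647
    out[i] <- as.integer(h %% 2147483645 + 1)
  }
  out
}

# draw from normal(mean, sd) truncated at zero by redrawing; used for
# perturbing non-negative quantities so that no probability mass piles at 0
rnorm_pos <- function(n, mean, sd, max_tries = 1000L) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < 0)
  tries <- 0L
  while (length(bad) > 0L && tries < max_tries) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x < 0)
    tries <- tries + 1L
  }
  if (length(bad) > 0L) x[bad] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ml/min -> l/h
ML_MIN_TO_L_H <- 0.06
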