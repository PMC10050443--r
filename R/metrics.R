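#' Behavioral flexibility: state agreement between prediction and observation
#'
#' Both trajectories are classified into discrete states (HOME/LEFT/RIGHT)
#' per step by nearest-center classification; the score is the percentage of
#' steps on which the labels agree.
#'
#' @param pred `T x 2` predicted trajectory.
#' @param obs `T x 2` observed trajectory (or `trajectory_sequence`).
#' @param cfg an [env_config()] supplying the state centers.
#' @return percentage in `[0, 100]`.
#' @export
behavioral_flexibility <- function(pred, obs, cfg) {
  if (inherits(obs, "trajectory_sequence")) obs <- obs$x
  if (nrow(pred) != nrow(obs)) stop("pred and obs lengths differ")
  100 * mean(classify_state(pred, cfg) == classify_state(obs, cfg))
}

# Pearson correlation with the zero-variance convention r = 0.
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(0)
  cor(a, b)
}

#' Cognitive flexibility: latent tracking of the hidden transition bias
#'
#' Correlates each highest-layer posterior-mean latent trace with the true
#' piecewise-constant transition-bias signal of a context-switching test
#' sequence; the score is the maximum absolute Pearson correlation over
#' those units (constant traces score 0 by convention).
#'
#' @param trace a posterior latent trace with element `mu_q`
#'   (`T x nz_total`), e.g. from [error_regression()].
#' @param truth ground-truth data.frame with a `bias` column, or a
#'   `trajectory_sequence`.
#' @param arch the [pvrnn_arch()] of the network.
#' @return list with `score` (in `[0, 1]`) and `per_unit` (named vector of
#'   signed correlations for each highest-layer mean unit).
#' @export
cognitive_flexibility <- function(trace, truth, arch) {
  if (inherits(truth, "trajectory_sequence")) truth <- truth$truth
  bias <- truth$bias
  L <- arch$L
  idx <- arch$oz[L] + seq_len(arch$n_z[L])
  mu <- trace$mu_q[, idx, drop = FALSE]
  if (nrow(mu) != length(bias)) stop("trace does not cover the test sequence")
  r <- apply(mu, 2, safe_cor, b = bias)
  names(r) <- paste0("unit", arch$oz[L] + seq_len(arch$n_z[L]) - 1L)
  list(score = max(abs(r)), per_unit = r)
}
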