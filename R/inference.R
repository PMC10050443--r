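#' Error-regression configuration
#'
#' Test-phase inference: with synaptic weights frozen, the adaptive
#' variables inside a sliding window are optimized against the windowed free
#' energy (reconstruction on the observed steps plus `w_test`-weighted KL),
#' yielding online posterior inference and one-step-ahead prediction.
#'
#' The test-phase meta-prior sets the strength of the prior on the inferred
#' posterior: too strong and the agent perseveres on its learned
#' expectations (poor behavioral flexibility); too weak and the latent
#' state stops tracking the hidden context (poor cognitive flexibility).
#' By default it is the learning-phase meta-prior of the condition scaled
#' by `w_test_scale = 0.1`, which balances the two while preserving the
#' relative ordering of conditions.
#'
#' The default window of 32 steps spans slightly more than one full reach
#' cycle, so the inference always sees at least one complete movement when
#' identifying the current goal.
#'
#' @param window sliding-window length in steps (a growing window is used at
#'   the start of the sequence).
#' @param iters Adam iterations per time step.
#' @param learning_rate Adam learning rate for the adaptive variables.
#' @param w_test per-layer test-phase meta-prior; default `NULL` means
#'   `w_test_scale` times the fit's learning-phase meta-prior.
#' @param w_test_scale scaling applied to the learning-phase meta-prior
#'   when `w_test` is not given.
#' @param warm_start initialize each newly entered step's adaptive variables
#'   from the previous step's solution.
#' @return list of class `regression_config`.
#' @export
regression_config <- function(window = 32L, iters = 30L, learning_rate = 0.05,
                              w_test = NULL, w_test_scale = 0.1,
                              warm_start = TRUE) {
  stopifnot(window >= 1, iters >= 1, learning_rate > 0, w_test_scale >= 0)
  structure(list(window = as.integer(window), iters = as.integer(iters),
                 learning_rate = learning_rate, w_test = w_test,
                 w_test_scale = w_test_scale,
                 warm_start = isTRUE(warm_start)),
            class = "regression_config")
}

#' Online posterior inference by error regression
#'
#' For each time step t the adaptive variables of the last `window` observed
#' steps are optimized for `iters` Adam iterations against the windowed free
#' energy, with all synaptic weights frozen; the network is then rolled one
#' step beyond the window on the prior mean to emit the prediction of the
#' next observation.  Adaptive variables that have slid out of the window
#' are frozen at their last optimized values.  Reparameterization noise is
#' drawn once per step position at the start, so the whole procedure is
#' deterministic given `seed`.
#'
#' @param fit a `pvrnn_fit` (weights are taken from it and never modified).
#' @param test a `trajectory_sequence` to infer on.
#' @param cfg a [regression_config()].
#' @param seed optional integer seed.
#' @return list with:
#'   * `pred`: `T x 2` matrix; row t is the one-step-ahead prediction of
#'     `x_t` made after observing steps `1..t-1` (row 1 is the prior-mean
#'     prediction from the initial state),
#'   * `trace`: full-sequence posterior latent trace under the final
#'     adaptive variables,
#'   * `a_mu`, `a_sig`: the inferred adaptive variables,
#'   * `iter_loss`: per-step, per-iteration windowed losses (for
#'     convergence audits).
#' @export
error_regression <- function(fit, test, cfg = regression_config(), seed = NULL) {
  arch <- fit$arch
  params <- fit$params
  w_test <- if (is.null(cfg$w_test)) cfg$w_test_scale * fit$cfg$meta_prior$w
            else cfg$w_test
  stopifnot(length(w_test) == arch$L)
  x <- if (inherits(test, "trajectory_sequence")) test$x else test
  T_ <- nrow(x); nz <- arch$nz_total
  if (!is.null(seed)) set.seed(seed)
  eps <- matrix(rnorm(T_ * nz), T_, nz)

  a_mu <- matrix(0, T_, nz); a_sig <- matrix(0, T_, nz)
  pred <- matrix(NA_real_, T_, arch$n_x)
  iter_loss <- matrix(NA_real_, T_, cfg$iters)

  # committed state: internal state after the steps that precede the window
  h0 <- numeric(arch$nd_total); d0 <- numeric(arch$nd_total)
  s0 <- 0L  # number of committed steps

  # prediction of x_1 from the untouched initial state
  g <- pvrnn_generate_cpp(params, arch$n_d, arch$n_z, arch$tau,
                          1L, arch$n_x, matrix(0, 1, nz), h0, d0,
                          -1L, -1L, 0L, 0)
  pred[1, ] <- g$xhat[1, ]

  for (t in seq_len(T_)) {
    s <- max(1L, t - cfg$window + 1L)
    while (s0 < s - 1L) {
      # slide: commit step s0+1 under its frozen adaptive variables
      i <- s0 + 1L
      r <- pvrnn_forward_cpp(params, arch$n_d, arch$n_z, arch$tau,
                             x[i, , drop = FALSE],
                             a_mu[i, , drop = FALSE], a_sig[i, , drop = FALSE],
                             eps[i, , drop = FALSE], w_test, h0, d0,
                             FALSE, FALSE, FALSE)
      h0 <- r$h_final; d0 <- r$d_final
      s0 <- i
    }
    win <- s:t
    ad <- adam_init(2L * length(win) * nz)
    for (it in seq_len(cfg$iters)) {
      r <- pvrnn_forward_cpp(params, arch$n_d, arch$n_z, arch$tau,
                             x[win, , drop = FALSE],
                             a_mu[win, , drop = FALSE], a_sig[win, , drop = FALSE],
                             eps[win, , drop = FALSE], w_test, h0, d0,
                             FALSE, TRUE, FALSE)
      iter_loss[t, it] <- r$loss
      theta <- c(as.numeric(a_mu[win, ]), as.numeric(a_sig[win, ]))
      grad <- c(as.numeric(r$grad_a_mu), as.numeric(r$grad_a_sig))
      st <- adam_step(ad, theta, grad, cfg$learning_rate, 0.9, 0.999, 1e-8)
      theta <- st$theta; ad <- st$state
      nw <- length(win) * nz
      a_mu[win, ] <- matrix(theta[seq_len(nw)], length(win), nz)
      a_sig[win, ] <- matrix(theta[nw + seq_len(nw)], length(win), nz)
    }
    if (t < T_) {
      # roll through the window posterior, then one prior-mean step ahead
      r <- pvrnn_forward_cpp(params, arch$n_d, arch$n_z, arch$tau,
                             x[win, , drop = FALSE],
                             a_mu[win, , drop = FALSE], a_sig[win, , drop = FALSE],
                             eps[win, , drop = FALSE], w_test, h0, d0,
                             FALSE, FALSE, FALSE)
      g <- pvrnn_generate_cpp(params, arch$n_d, arch$n_z, arch$tau,
                              1L, arch$n_x, matrix(0, 1, nz),
                              r$h_final, r$d_final, -1L, -1L, 0L, 0)
      pred[t + 1L, ] <- g$xhat[1, ]
      if (cfg$warm_start) {
        a_mu[t + 1L, ] <- a_mu[t, ]
        a_sig[t + 1L, ] <- a_sig[t, ]
      }
    }
  }

  full <- forward_pass(params, arch, x, a_mu, a_sig, eps = eps, w = w_test,
                       keep_trace = TRUE)
  list(pred = pred, trace = full$trace, a_mu = a_mu, a_sig = a_sig,
       iter_loss = iter_loss)
}
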