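#' Prior parameters from the previous deterministic state
#'
#' The layer-l prior over z_t is a diagonal Gaussian whose mean and s.d. are
#' read out from the layer's own deterministic units at t-1:
#' `mu_p = tanh(W_pm d + b_pm)`, `sigma_p = exp(W_ps d + b_ps)`.
#'
#' @param d_prev numeric vector, the layer's d units at the previous step.
#' @param W_mu,b_mu,W_sig,b_sig readout weights and biases.
#' @return list with `mu` and `sigma` (all `sigma > 0`).
#' @export
prior_params <- function(d_prev, W_mu, b_mu, W_sig, b_sig) {
  stopifnot(all(is.finite(d_prev)))
  W_mu <- as.matrix(W_mu); W_sig <- as.matrix(W_sig)
  list(mu = as.numeric(tanh(W_mu %*% d_prev + b_mu)),
       sigma = as.numeric(exp(W_sig %*% d_prev + b_sig)))
}

#' Posterior parameters from the adaptive variables
#'
#' The approximate posterior is parameterized directly by the per-step
#' adaptive variables: `mu_q = tanh(a_mu)`, `sigma_q = exp(a_sig)`.  The
#' conditioning on d_{t-1} enters only through the KL against the
#' d-dependent prior.
#'
#' @param a_mu,a_sig numeric vectors of adaptive variables.
#' @return list with `mu` and `sigma`.
#' @export
posterior_params <- function(a_mu, a_sig) {
  stopifnot(all(is.finite(a_mu)), all(is.finite(a_sig)))
  list(mu = tanh(a_mu), sigma = exp(a_sig))
}

#' Reparameterized Gaussian sample
#'
#' @param mu,sigma Gaussian parameters (`sigma >= 0`; 0 only in
#'   deterministic-generation mode).
#' @param eps a standard-normal draw of the same length.
#' @return `mu + sigma * eps`.
#' @export
reparameterize <- function(mu, sigma, eps) {
  stopifnot(all(sigma >= 0), length(mu) == length(eps))
  mu + sigma * eps
}

#' One multiple-timescale recurrent step
#'
#' Per layer l with time constant tau_l:
#' `h_t = (1 - 1/tau) h_{t-1} + (1/tau) (sum_m W[m->l] d^m_{t-1} + W_z z_t + b)`
#' and `d_t = tanh(h_t)`.  Layer l receives d input from itself and its
#' immediate neighbours only (l-1, l, l+1 where they exist).
#'
#' @param h_prev,d_prev lists over layers of numeric vectors at t-1.
#' @param z_t list over layers of latent samples at t.
#' @param W_dd nested list: `W_dd[[l]][[as.character(m)]]` maps d^m to layer l.
#' @param W_zd,b_d lists over layers.
#' @param tau numeric vector of time constants.
#' @return list with `h` and `d`, lists over layers.
#' @export
mtrnn_step <- function(h_prev, d_prev, z_t, W_dd, W_zd, b_d, tau) {
  L <- length(tau)
  h <- vector("list", L); d <- vector("list", L)
  for (l in seq_len(L)) {
    nbrs <- intersect((l - 1L):(l + 1L), seq_len(L))
    inp <- b_d[[l]]
    for (m in nbrs) inp <- inp + as.matrix(W_dd[[l]][[as.character(m)]]) %*% d_prev[[m]]
    inp <- inp + as.matrix(W_zd[[l]]) %*% z_t[[l]]
    h[[l]] <- as.numeric((1 - 1 / tau[l]) * h_prev[[l]] + (1 / tau[l]) * inp)
    d[[l]] <- tanh(h[[l]])
  }
  list(h = h, d = d)
}

#' Output mapping from the lowest layer
#'
#' @param d1_t lowest-layer d vector.
#' @param W_out,b_out output weights.
#' @return the predicted observation, componentwise in (-1, 1).
#' @export
output_map <- function(d1_t, W_out, b_out) {
  as.numeric(tanh(as.matrix(W_out) %*% d1_t + b_out))
}

#' KL divergence between diagonal Gaussians
#'
#' `KL(q || p)` summed over dimensions:
#' `sum_i log(sp_i/sq_i) + (sq_i^2 + (mq_i - mp_i)^2) / (2 sp_i^2) - 1/2`.
#'
#' @param mu_q,sigma_q posterior parameters.
#' @param mu_p,sigma_p prior parameters.
#' @return nonnegative scalar; 0 iff the distributions coincide.
#' @export
kl_gaussians <- function(mu_q, sigma_q, mu_p, sigma_p) {
  if (any(sigma_q <= 0) || any(sigma_p <= 0)) stop("sigma must be positive")
  sum(log(sigma_p / sigma_q) +
        (sigma_q^2 + (mu_q - mu_p)^2) / (2 * sigma_p^2) - 0.5)
}

#' Meta-prior-weighted variational free energy of a latent trace
#'
#' Reconstruction term (Gaussian likelihood with fixed unit output variance,
#' additive constants dropped) plus per-layer KL terms weighted by the
#' meta-prior:
#' `loss = sum_t ||x_t - xhat_t||^2 / 2 + sum_t sum_l w_l KL_l,t`.
#'
#' @param x `T x 2` observed sequence (matrix or `trajectory_sequence`).
#' @param trace a latent trace as returned by [forward_pass()]: list with
#'   `xhat` (`T x 2`) and per-step per-layer Gaussian parameters `mu_q`,
#'   `sig_q`, `mu_p`, `sig_p` (`T x nz_total` matrices) plus the layer
#'   offsets of the architecture.
#' @param w per-layer meta-prior weights.
#' @param arch the [pvrnn_arch()] that produced the trace.
#' @return list with `loss`, `recon`, and `kl` (per-layer totals).
#' @export
free_energy <- function(x, trace, w, arch) {
  if (inherits(x, "trajectory_sequence")) x <- x$x
  if (nrow(x) != nrow(trace$xhat)) stop("sequence and trace lengths differ")
  stopifnot(length(w) == arch$L)
  recon <- 0.5 * sum((x - trace$xhat)^2)
  kl <- numeric(arch$L)
  for (l in seq_len(arch$L)) {
    idx <- arch$oz[l] + seq_len(arch$n_z[l])
    kl[l] <- kl_gaussians(trace$mu_q[, idx], trace$sig_q[, idx],
                          trace$mu_p[, idx], trace$sig_p[, idx])
  }
  list(loss = recon + sum(w * kl), recon = recon, kl = kl)
}

#' Posterior-driven forward pass with free energy and gradients
#'
#' Runs the compiled core over one observed sequence: the posterior is read
#' from the adaptive variables, z is sampled by reparameterization with the
#' supplied noise `eps`, the multiple-timescale dynamics are unrolled, and
#' the meta-prior-weighted free energy and (optionally) its analytic
#' backpropagation-through-time gradients are returned.
#'
#' @param params flat parameter vector (see [param_layout()]).
#' @param arch a [pvrnn_arch()].
#' @param x `T x 2` observation matrix or `trajectory_sequence`.
#' @param a_mu,a_sig `T x nz_total` adaptive-variable matrices.
#' @param eps `T x nz_total` standard-normal draws (zeros give the posterior
#'   mean path).
#' @param w per-layer meta-prior weights.
#' @param h0,d0 initial internal state (defaults: zeros).
#' @param grad_params,grad_a compute gradients w.r.t. weights / adaptive
#'   variables.
#' @param keep_trace return the full latent trace.
#' @return list with `loss`, `recon`, `kl` (per layer), `xhat`, final state,
#'   and any requested gradients / trace.
#' @export
forward_pass <- function(params, arch, x, a_mu, a_sig,
                         eps = NULL, w = rep(1, arch$L),
                         h0 = NULL, d0 = NULL,
                         grad_params = FALSE, grad_a = FALSE,
                         keep_trace = FALSE) {
  if (inherits(x, "trajectory_sequence")) x <- x$x
  T_ <- nrow(x)
  if (is.null(eps)) eps <- matrix(0, T_, arch$nz_total)
  if (is.null(h0)) h0 <- numeric(arch$nd_total)
  if (is.null(d0)) d0 <- numeric(arch$nd_total)
  res <- pvrnn_forward_cpp(params, arch$n_d, arch$n_z, arch$tau,
                           x, a_mu, a_sig, eps, w, h0, d0,
                           grad_params, grad_a, keep_trace)
  if (keep_trace) {
    res$trace$xhat <- res$xhat
    res$trace$mu_q <- res$trace$mu_q
  }
  res
}

#' Closed-loop generation from the prior
#'
#' Rolls the network forward for `T` steps with z drawn from the learned
#' prior (`mode = "prior_sample"`) or set to the prior mean
#' (`mode = "prior_mean"`, deterministic).  Optionally one latent unit is
#' clamped at every step: for the mean channel the sampled z entry is
#' replaced by `clamp$value`; for the variance channel sigma is replaced by
#' `exp(clamp$value)` before sampling.
#'
#' @param params flat parameter vector.
#' @param arch a [pvrnn_arch()].
#' @param T number of steps to generate.
#' @param mode `"prior_sample"` or `"prior_mean"`.
#' @param clamp optional list with `layer` (1-based), `unit` (1-based within
#'   layer), `channel` (`"mean"` or `"variance"`) and `value`.
#' @param seed optional integer seed for the prior samples.
#' @param h0,d0 optional initial internal state.
#' @return list with `xhat` (`T x 2`), `trace` (d, z, mu_p, sig_p) and the
#'   final internal state.
#' @export
generate <- function(params, arch, T, mode = c("prior_sample", "prior_mean"),
                     clamp = NULL, seed = NULL, h0 = NULL, d0 = NULL) {
  mode <- match.arg(mode)
  stopifnot(T >= 1)
  if (!is.null(seed)) set.seed(seed)
  eps <- if (mode == "prior_sample")
    matrix(rnorm(T * arch$nz_total), T, arch$nz_total)
  else matrix(0, T, arch$nz_total)
  if (is.null(h0)) h0 <- numeric(arch$nd_total)
  if (is.null(d0)) d0 <- numeric(arch$nd_total)
  cl <- c(-1L, -1L, 0L)
  cv <- 0
  if (!is.null(clamp)) {
    ch <- match.arg(clamp$channel, c("mean", "variance"))
    if (clamp$layer < 1 || clamp$layer > arch$L) stop("clamp layer out of range")
    if (clamp$unit < 1 || clamp$unit > arch$n_z[clamp$layer]) stop("clamp unit out of range")
    cl <- c(clamp$layer - 1L, clamp$unit - 1L, if (ch == "mean") 0L else 1L)
    cv <- clamp$value
  }
  pvrnn_generate_cpp(params, arch$n_d, arch$n_z, arch$tau,
                     as.integer(T), arch$n_x, eps, h0, d0,
                     cl[1], cl[2], cl[3], cv)
}
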