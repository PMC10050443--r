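#' Training configuration
#'
#' @param epochs number of optimization epochs (one batch-gradient Adam step
#'   per epoch, gradients summed over all sequences).
#' @param learning_rate shared Adam learning rate for weights and adaptive
#'   variables.
#' @param beta1,beta2,adam_eps Adam moment decays and stabilizer.
#' @param meta_prior a [meta_prior()] configuration (or preset name).
#' @param step `"batch"` (sum gradients over all sequences, one Adam step
#'   per epoch) or `"per_sequence"` (one Adam step per sequence per epoch;
#'   more updates per epoch, usually fewer epochs to the plateau).
#' @param seed integer seed.
#' @param n_networks networks per condition for [train_condition()].
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 2000L, learning_rate = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         meta_prior = "normal", step = c("batch", "per_sequence"),
                         seed = 1L, n_networks = 20L) {
  if (is.character(meta_prior)) meta_prior <- meta_prior(meta_prior)
  step <- match.arg(step)
  stopifnot(epochs >= 1, learning_rate > 0, n_networks >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 meta_prior = meta_prior, step = step, seed = as.integer(seed),
                 n_networks = as.integer(n_networks)),
            class = "train_config")
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Developmental learning: train one network on a corpus
#'
#' Jointly optimizes the synaptic weights and the per-sequence adaptive
#' variables by full-sequence backpropagation through time, minimizing the
#' meta-prior-weighted free energy summed over the corpus, with one Adam
#' step per epoch.  Reparameterization noise is redrawn every epoch from the
#' R RNG, so a run is fully reproducible given `cfg$seed`.
#'
#' @param corpus list of `trajectory_sequence` objects of equal length.
#' @param arch a [pvrnn_arch()].
#' @param cfg a [train_config()].
#' @param params_init optional flat parameter vector to start from.
#' @return list of class `pvrnn_fit`: `params`, `a_mu`/`a_sig` (lists of
#'   `T x nz_total` matrices, one per sequence), `history` (data.frame with
#'   per-epoch loss, recon and per-layer KL), `arch`, `cfg`.
#' @export
train_network <- function(corpus, arch, cfg, params_init = NULL) {
  stopifnot(length(corpus) >= 1)
  Ts <- vapply(corpus, function(s) nrow(s$x), 1L)
  if (length(unique(Ts)) != 1L) stop("all corpus sequences must have equal length")
  T_ <- Ts[1]
  set.seed(cfg$seed)
  params <- if (is.null(params_init)) init_params(arch) else params_init
  ns <- length(corpus)
  nz <- arch$nz_total
  a_mu <- replicate(ns, matrix(0, T_, nz), simplify = FALSE)
  a_sig <- replicate(ns, matrix(0, T_, nz), simplify = FALSE)
  w <- cfg$meta_prior$w
  np <- length(params)
  na <- T_ * nz

  # one flat optimization vector: [weights, a_mu & a_sig per sequence]
  theta <- c(params, unlist(a_mu), unlist(a_sig))
  hist <- matrix(NA_real_, cfg$epochs, 2L + arch$L)
  colnames(hist) <- c("loss", "recon", paste0("kl", seq_len(arch$L)))

  a_off <- function(i) np + (i - 1L) * na          # a_mu block of sequence i
  s_off <- function(i) np + ns * na + (i - 1L) * na # a_sig block
  per_seq <- identical(cfg$step, "per_sequence")

  if (per_seq) {
    ad_p <- adam_init(np)
    ad_a <- lapply(seq_len(ns), function(i) adam_init(2L * na))
  } else {
    ad <- adam_init(length(theta))
  }

  for (ep in seq_len(cfg$epochs)) {
    grad <- if (per_seq) NULL else numeric(length(theta))
    loss <- 0; recon <- 0; kl <- numeric(arch$L)
    for (i in seq_len(ns)) {
      am <- matrix(theta[a_off(i) + seq_len(na)], T_, nz)
      as_ <- matrix(theta[s_off(i) + seq_len(na)], T_, nz)
      eps <- matrix(rnorm(na), T_, nz)
      r <- pvrnn_forward_cpp(theta[seq_len(np)], arch$n_d, arch$n_z, arch$tau,
                             corpus[[i]]$x, am, as_, eps, w,
                             numeric(arch$nd_total), numeric(arch$nd_total),
                             TRUE, TRUE, FALSE)
      if (!is.finite(r$loss))
        stop(sprintf("non-finite loss at epoch %d, sequence %d (recon=%g)",
                     ep, i, r$recon))
      loss <- loss + r$loss; recon <- recon + r$recon; kl <- kl + r$kl
      if (per_seq) {
        sp <- adam_step(ad_p, theta[seq_len(np)], r$grad_params,
                        cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$adam_eps)
        theta[seq_len(np)] <- sp$theta; ad_p <- sp$state
        ai <- c(a_off(i) + seq_len(na), s_off(i) + seq_len(na))
        sa <- adam_step(ad_a[[i]], theta[ai],
                        c(as.numeric(r$grad_a_mu), as.numeric(r$grad_a_sig)),
                        cfg$learning_rate, cfg$beta1, cfg$beta2, cfg$adam_eps)
        theta[ai] <- sa$theta; ad_a[[i]] <- sa$state
      } else {
        grad[seq_len(np)] <- grad[seq_len(np)] + r$grad_params
        grad[a_off(i) + seq_len(na)] <- as.numeric(r$grad_a_mu)
        grad[s_off(i) + seq_len(na)] <- as.numeric(r$grad_a_sig)
      }
    }
    hist[ep, ] <- c(loss, recon, kl)
    if (!per_seq) {
      st <- adam_step(ad, theta, grad, cfg$learning_rate,
                      cfg$beta1, cfg$beta2, cfg$adam_eps)
      theta <- st$theta; ad <- st$state
    }
  }

  for (i in seq_len(ns)) {
    a_mu[[i]] <- matrix(theta[a_off(i) + seq_len(na)], T_, nz)
    a_sig[[i]] <- matrix(theta[s_off(i) + seq_len(na)], T_, nz)
  }
  structure(list(params = theta[seq_len(np)], a_mu = a_mu, a_sig = a_sig,
                 history = as.data.frame(hist), arch = arch, cfg = cfg),
            class = "pvrnn_fit")
}

#' @export
print.pvrnn_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("pvrnn_fit: %d epochs, final loss %.4f (recon %.4f)\n",
              n, x$history$loss[n], x$history$recon[n]))
  invisible(x)
}

#' Average per-step KL of a trained network on its corpus
#'
#' Evaluated on the posterior-mean path (no reparameterization noise).
#'
#' @param fit a [train_network()] result.
#' @param corpus the training corpus.
#' @return numeric vector, mean KL per step for each layer.
#' @export
layer_kl_per_step <- function(fit, corpus) {
  arch <- fit$arch
  kl <- numeric(arch$L); nT <- 0L
  for (i in seq_along(corpus)) {
    r <- forward_pass(fit$params, arch, corpus[[i]]$x,
                      fit$a_mu[[i]], fit$a_sig[[i]], w = fit$cfg$meta_prior$w)
    kl <- kl + r$kl
    nT <- nT + nrow(corpus[[i]]$x)
  }
  kl / nT
}

#' Train several independent networks in one condition
#'
#' Network i uses seed `cfg$seed + i - 1` for both weight initialization and
#' reparameterization noise.
#'
#' @param corpus_builder either a fixed corpus (list of sequences) or a
#'   function `function(seed)` returning a corpus.
#' @param arch a [pvrnn_arch()].
#' @param cfg a [train_config()]; `cfg$n_networks` networks are trained.
#' @param label optional condition label recorded on each fit.
#' @return list of `pvrnn_fit` objects.
#' @export
train_condition <- function(corpus_builder, arch, cfg, label = NULL) {
  fits <- vector("list", cfg$n_networks)
  for (i in seq_len(cfg$n_networks)) {
    ci <- cfg; ci$seed <- cfg$seed + i - 1L
    corpus <- if (is.function(corpus_builder)) corpus_builder(ci$seed) else corpus_builder
    fits[[i]] <- train_network(corpus, arch, ci)
    fits[[i]]$condition <- label
  }
  fits
}
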