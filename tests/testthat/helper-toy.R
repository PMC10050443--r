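# Small architectures and deterministic parameter sets used across tests.

toy_arch <- function() pvrnn_arch(n_d = c(3L, 2L), n_z = c(1L, 1L),
                                  tau = c(2, 4), n_x = 2L)

toy_params <- function(arch = toy_arch(), seed = 11) init_params(arch, seed = seed)

# A tiny environment whose sequences are quick to generate.
tiny_env <- function(seq_len = 128L, ...) {
  env_config(seq_len = seq_len,
             biases = c(0.76, 0.24),
             n_sets = 1L, ...)
}

# Noise-free variant: produced by switching off the signal noise after
# construction (the public constructor requires sigma > 0).
noise_free_env <- function(seq_len = 128L) {
  cfg <- tiny_env(seq_len)
  cfg$sigma_stable <- 0
  cfg
}

# One small trained network, built once per test run and memoised, so the
# inference/metrics tests can share it.
.fixture_cache <- new.env(parent = emptyenv())

fixture_fit <- function() {
  if (is.null(.fixture_cache$fit)) {
    cfg <- env_config(seq_len = 192L, biases = c(0.9, 0.76, 0.24, 0.1),
                      n_sets = 1L)
    corpus <- build_training_set(cfg, "stable", seed = 301)
    tc <- train_config(epochs = 1200L, learning_rate = 3e-3,
                       meta_prior = "normal", seed = 302, n_networks = 1L)
    .fixture_cache$env <- cfg
    .fixture_cache$fit <- train_network(corpus, pvrnn_arch(), tc)
    .fixture_cache$corpus <- corpus
  }
  list(fit = .fixture_cache$fit, env = .fixture_cache$env,
       corpus = .fixture_cache$corpus)
}
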