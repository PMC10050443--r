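test_that("prior readout squashes mean and exponentiates sigma", {
  p <- prior_params(c(0, 0), matrix(0, 2, 2), c(0, 0), matrix(0, 2, 2), c(0, 0))
  expect_equal(p$mu, c(0, 0))
  expect_equal(p$sigma, c(1, 1))   # unit Gaussian at the t = 1 boundary
  # scalar hand evaluation
  p <- prior_params(0.5, matrix(1), 0, matrix(-2), 0.1)
  expect_equal(p$mu, tanh(0.5))
  expect_equal(p$sigma, exp(-2 * 0.5 + 0.1))
  # tanh range
  for (d in list(c(10, -10), rnorm(2, 0, 5)))
    expect_true(all(abs(prior_params(d, matrix(rnorm(4), 2), rnorm(2),
                                     matrix(rnorm(4), 2), rnorm(2))$mu) < 1))
})

test_that("posterior is parameterized directly by the adaptive variables", {
  p <- posterior_params(c(0, 0), c(0, 0))
  expect_equal(p$mu, c(0, 0)); expect_equal(p$sigma, c(1, 1))
  p <- posterior_params(0.3, -1)
  expect_equal(p$mu, tanh(0.3)); expect_equal(p$sigma, exp(-1))
  expect_equal(posterior_params(50, 0)$mu, 1, tolerance = 1e-12)  # saturation
})

test_that("reparameterized samples have the requested moments", {
  expect_equal(reparameterize(c(0.3, -0.2), c(1, 2), c(0, 0)), c(0.3, -0.2))
  expect_equal(reparameterize(0.5, 0, 3), 0.5)   # deterministic mode
  set.seed(4)
  n <- 1e5
  z <- reparameterize(rep(0.7, n), rep(0.3, n), rnorm(n))
  expect_lt(abs(mean(z) - 0.7), 4 * 0.3 / sqrt(n))
})

test_that("multiple-timescale step matches pencil-and-paper arithmetic", {
  # tau = 1 removes the leak entirely
  st <- mtrnn_step(h_prev = list(5), d_prev = list(0.5), z_t = list(0.2),
                   W_dd = list(list("1" = matrix(2))), W_zd = list(matrix(3)),
                   b_d = list(0.1), tau = 1)
  expect_equal(st$h[[1]], 2 * 0.5 + 3 * 0.2 + 0.1)
  # zero input: pure leak h_t = (1 - 1/tau) h0
  st <- mtrnn_step(list(2), list(0), list(0), list(list("1" = matrix(0))),
                   list(matrix(0)), list(0), tau = 4)
  expect_equal(st$h[[1]], 2 * 0.75)
  # two-layer toy with hand-set scalars (tau = 2 and 4)
  st <- mtrnn_step(h_prev = list(0.1, -0.2), d_prev = list(0.3, 0.4),
                   z_t = list(0.5, -0.6),
                   W_dd = list(list("1" = matrix(1.5), "2" = matrix(-0.7)),
                               list("1" = matrix(0.8), "2" = matrix(0.9))),
                   W_zd = list(matrix(0.2), matrix(-0.3)),
                   b_d = list(0.05, -0.05), tau = c(2, 4))
  h1 <- 0.5 * 0.1 + 0.5 * (1.5 * 0.3 - 0.7 * 0.4 + 0.2 * 0.5 + 0.05)
  h2 <- 0.75 * (-0.2) + 0.25 * (0.8 * 0.3 + 0.9 * 0.4 - 0.3 * (-0.6) - 0.05)
  expect_equal(st$h[[1]], h1, tolerance = 1e-15)
  expect_equal(st$h[[2]], h2, tolerance = 1e-15)
  expect_equal(st$d[[1]], tanh(h1), tolerance = 1e-15)
})

test_that("output mapping is a squashed affine readout of the lowest layer", {
  expect_equal(output_map(c(1, 1), matrix(0, 2, 2), c(0.3, -0.4)),
               tanh(c(0.3, -0.4)))
  expect_equal(output_map(0.5, matrix(c(2, -1), 2, 1), c(0, 0)),
               tanh(c(1, -0.5)))
  set.seed(8)
  x <- output_map(rnorm(3, 0, 5), matrix(rnorm(6), 2, 3), rnorm(2))
  expect_true(all(abs(x) < 1))
})

test_that("Gaussian KL matches closed form and a Monte-Carlo oracle", {
  expect_equal(kl_gaussians(0.3, 0.7, 0.3, 0.7), 0)
  expect_equal(kl_gaussians(1, 1, 0, 1), 0.5)
  expect_error(kl_gaussians(0, -1, 0, 1), "positive")
  set.seed(13)
  mu_q <- rnorm(2); sig_q <- exp(rnorm(2, 0, 0.3))
  mu_p <- rnorm(2); sig_p <- exp(rnorm(2, 0, 0.3))
  n <- 1e6
  z1 <- rnorm(n, mu_q[1], sig_q[1]); z2 <- rnorm(n, mu_q[2], sig_q[2])
  lr <- dnorm(z1, mu_q[1], sig_q[1], log = TRUE) - dnorm(z1, mu_p[1], sig_p[1], log = TRUE) +
        dnorm(z2, mu_q[2], sig_q[2], log = TRUE) - dnorm(z2, mu_p[2], sig_p[2], log = TRUE)
  mc <- mean(lr); se <- sd(lr) / sqrt(n)
  expect_lt(abs(kl_gaussians(mu_q, sig_q, mu_p, sig_p) - mc), 3 * se)
})

test_that("free energy decomposes into reconstruction and weighted KL", {
  arch <- toy_arch()
  params <- toy_params(arch)
  set.seed(3)
  T_ <- 4
  x <- matrix(runif(T_ * 2, -1, 1), T_, 2)
  a_mu <- matrix(rnorm(T_ * 2, 0, 0.3), T_, 2)
  a_sig <- matrix(rnorm(T_ * 2, 0, 0.3), T_, 2)
  r <- forward_pass(params, arch, x, a_mu, a_sig, w = c(0.7, 1.3),
                    keep_trace = TRUE)
  fe <- free_energy(x, r$trace, c(0.7, 1.3), arch)
  expect_equal(fe$loss, r$loss, tolerance = 1e-12)
  # w = 0 leaves the reconstruction term only
  fe0 <- free_energy(x, r$trace, c(0, 0), arch)
  expect_equal(fe0$loss, fe0$recon)
  expect_equal(fe0$recon, 0.5 * sum((x - r$xhat)^2), tolerance = 1e-12)
})

test_that("two-step single-layer free energy matches a hand-summed value", {
  arch <- pvrnn_arch(n_d = 1L, n_z = 1L, tau = 2, n_x = 1L)
  p <- numeric(n_params(arch))
  p <- set_param_block(p, arch, "W_dd_1_1", 0.5)
  p <- set_param_block(p, arch, "W_zd_1", 1.0)
  p <- set_param_block(p, arch, "b_d_1", 0.1)
  p <- set_param_block(p, arch, "W_pm_1", 0.4)
  p <- set_param_block(p, arch, "W_ps_1", -0.2)
  p <- set_param_block(p, arch, "W_out", 2.0)
  x <- matrix(c(0.3, -0.1), 2, 1)
  a_mu <- matrix(c(0.2, -0.3), 2, 1)
  a_sig <- matrix(c(-0.5, 0.1), 2, 1)
  eps <- matrix(c(0.7, -1.1), 2, 1)
  w <- 1.7
  # hand computation, step by step
  kl_sc <- function(mq, sq, mp, sp)
    log(sp / sq) + (sq^2 + (mq - mp)^2) / (2 * sp^2) - 0.5
  d0 <- 0; h0 <- 0
  mu_p1 <- tanh(0.4 * d0); sig_p1 <- exp(-0.2 * d0)
  mu_q1 <- tanh(0.2); sig_q1 <- exp(-0.5)
  z1 <- mu_q1 + sig_q1 * 0.7
  h1 <- 0.5 * h0 + 0.5 * (0.5 * d0 + 1.0 * z1 + 0.1); d1 <- tanh(h1)
  xh1 <- tanh(2 * d1)
  mu_p2 <- tanh(0.4 * d1); sig_p2 <- exp(-0.2 * d1)
  mu_q2 <- tanh(-0.3); sig_q2 <- exp(0.1)
  z2 <- mu_q2 + sig_q2 * (-1.1)
  h2 <- 0.5 * h1 + 0.5 * (0.5 * d1 + 1.0 * z2 + 0.1); d2 <- tanh(h2)
  xh2 <- tanh(2 * d2)
  hand <- 0.5 * ((xh1 - 0.3)^2 + (xh2 + 0.1)^2) +
    w * (kl_sc(mu_q1, sig_q1, mu_p1, sig_p1) + kl_sc(mu_q2, sig_q2, mu_p2, sig_p2))
  r <- forward_pass(p, arch, x, a_mu, a_sig, eps = eps, w = w)
  expect_equal(r$loss, hand, tolerance = 1e-12)
  expect_equal(r$xhat[, 1], c(xh1, xh2), tolerance = 1e-12)
})

test_that("compiled forward pass agrees with the plain-R reference", {
  arch <- toy_arch()
  params <- toy_params(arch)
  set.seed(21)
  T_ <- 7
  x <- matrix(runif(T_ * 2, -1, 1), T_, 2)
  a_mu <- matrix(rnorm(T_ * 2, 0, 0.4), T_, 2)
  a_sig <- matrix(rnorm(T_ * 2, 0, 0.4), T_, 2)
  eps <- matrix(rnorm(T_ * 2), T_, 2)
  w <- c(0.3, 2.1)
  r <- forward_pass(params, arch, x, a_mu, a_sig, eps = eps, w = w,
                    keep_trace = TRUE)
  ref <- reference_forward(params, arch, x, a_mu, a_sig, eps, w)
  expect_equal(r$loss, ref$loss, tolerance = 1e-12)
  expect_equal(r$recon, ref$recon, tolerance = 1e-12)
  expect_equal(r$kl, ref$kl, tolerance = 1e-12)
  expect_equal(r$xhat, ref$xhat, tolerance = 1e-12)
  expect_equal(unclass(r$trace$mu_p), ref$mu_p, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(r$trace$sig_q), ref$sig_q, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on a 5-step toy", {
  arch <- toy_arch()
  params <- toy_params(arch)
  set.seed(31)
  T_ <- 5
  x <- matrix(runif(T_ * 2, -1, 1), T_, 2)
  a_mu <- matrix(rnorm(T_ * 2, 0, 0.3), T_, 2)
  a_sig <- matrix(rnorm(T_ * 2, 0, 0.3), T_, 2)
  eps <- matrix(rnorm(T_ * 2), T_, 2)
  w <- c(0.5, 2)
  r <- forward_pass(params, arch, x, a_mu, a_sig, eps = eps, w = w,
                    grad_params = TRUE, grad_a = TRUE)
  loss_at <- function(p, am, as) forward_pass(p, arch, x, am, as, eps = eps, w = w)$loss
  h <- 1e-6
  idx <- sample(length(params), 10)
  for (i in idx) {
    pp <- pm <- params; pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
    fd <- (loss_at(pp, a_mu, a_sig) - loss_at(pm, a_mu, a_sig)) / (2 * h)
    expect_lt(abs(r$grad_params[i] - fd) / max(abs(fd), 1e-4), 1e-4)
  }
  for (k in 1:5) {
    t <- sample(T_, 1); j <- sample(2, 1)
    ap <- am_ <- a_mu; ap[t, j] <- ap[t, j] + h; am_[t, j] <- am_[t, j] - h
    fd <- (loss_at(params, ap, a_sig) - loss_at(params, am_, a_sig)) / (2 * h)
    expect_lt(abs(r$grad_a_mu[t, j] - fd) / max(abs(fd), 1e-4), 1e-4)
    sp <- sm <- a_sig; sp[t, j] <- sp[t, j] + h; sm[t, j] <- sm[t, j] - h
    fd <- (loss_at(params, a_mu, sp) - loss_at(params, a_mu, sm)) / (2 * h)
    expect_lt(abs(r$grad_a_sig[t, j] - fd) / max(abs(fd), 1e-4), 1e-4)
  }
})

test_that("closed-loop generation respects mode, clamp and determinism", {
  arch <- toy_arch()
  params <- toy_params(arch)
  g <- generate(params, arch, 50, mode = "prior_sample", seed = 2)
  expect_equal(nrow(g$xhat), 50L)
  # clamped z entry is pinned at every step
  g <- generate(params, arch, 20, mode = "prior_sample",
                clamp = list(layer = 2, unit = 1, channel = "mean", value = 0.7),
                seed = 2)
  expect_true(all(g$trace$z[, arch$oz[2] + 1] == 0.7))
  # variance clamp pins sigma, not the sample
  g <- generate(params, arch, 20, mode = "prior_mean",
                clamp = list(layer = 1, unit = 1, channel = "variance",
                             value = -0.3))
  expect_true(all(g$trace$sig_p[, 1] == exp(-0.3)))
  # prior-mean rollouts repeat bit-for-bit
  g1 <- generate(params, arch, 30, mode = "prior_mean")
  g2 <- generate(params, arch, 30, mode = "prior_mean")
  expect_identical(g1$xhat, g2$xhat)
  expect_error(generate(params, arch, 10,
                        clamp = list(layer = 5, unit = 1, channel = "mean",
                                     value = 0)), "out of range")
})

test_that("sigma positivity and tanh bounds hold along sampled rollouts", {
  arch <- toy_arch()
  set.seed(99)
  for (k in 1:5) {
    params <- init_params(arch)
    g <- generate(params, arch, 200, mode = "prior_sample", seed = k)
    expect_true(all(g$trace$sig_p > 0))
    expect_true(all(abs(g$trace$d) < 1))
    expect_true(all(abs(g$trace$mu_p) < 1))
    expect_true(all(abs(g$xhat) < 1))
  }
})
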