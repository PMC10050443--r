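# Plain-R reference forward pass, written independently of the compiled
# core from the primitive operations, used as an oracle for the fast path.

reference_forward <- function(params, arch, x, a_mu, a_sig, eps, w,
                              h0 = NULL, d0 = NULL) {
  L <- arch$L
  T_ <- nrow(x)
  blocks <- function(v, off, n) lapply(seq_len(L), function(l)
    v[off[l] + seq_len(n[l])])
  h <- if (is.null(h0)) lapply(arch$n_d, function(n) numeric(n))
       else blocks(h0, arch$od, arch$n_d)
  d <- if (is.null(d0)) lapply(arch$n_d, function(n) numeric(n))
       else blocks(d0, arch$od, arch$n_d)

  W_dd <- lapply(seq_len(L), function(l) {
    nb <- intersect((l - 1L):(l + 1L), seq_len(L))
    stats::setNames(lapply(nb, function(m)
      param_block(params, arch, sprintf("W_dd_%d_%d", l, m))), as.character(nb))
  })
  W_zd <- lapply(seq_len(L), function(l) param_block(params, arch, sprintf("W_zd_%d", l)))
  b_d <- lapply(seq_len(L), function(l) param_block(params, arch, sprintf("b_d_%d", l)))
  W_pm <- lapply(seq_len(L), function(l) param_block(params, arch, sprintf("W_pm_%d", l)))
  b_pm <- lapply(seq_len(L), function(l) param_block(params, arch, sprintf("b_pm_%d", l)))
  W_ps <- lapply(seq_len(L), function(l) param_block(params, arch, sprintf("W_ps_%d", l)))
  b_ps <- lapply(seq_len(L), function(l) param_block(params, arch, sprintf("b_ps_%d", l)))
  W_out <- param_block(params, arch, "W_out")
  b_out <- param_block(params, arch, "b_out")

  xhat <- matrix(NA_real_, T_, arch$n_x)
  mu_q <- sig_q <- mu_p <- sig_p <- matrix(NA_real_, T_, arch$nz_total)
  recon <- 0
  kl <- numeric(L)
  for (t in seq_len(T_)) {
    z <- vector("list", L)
    for (l in seq_len(L)) {
      idx <- arch$oz[l] + seq_len(arch$n_z[l])
      pr <- prior_params(d[[l]], W_pm[[l]], b_pm[[l]], W_ps[[l]], b_ps[[l]])
      po <- posterior_params(a_mu[t, idx], a_sig[t, idx])
      mu_p[t, idx] <- pr$mu; sig_p[t, idx] <- pr$sigma
      mu_q[t, idx] <- po$mu; sig_q[t, idx] <- po$sigma
      z[[l]] <- reparameterize(po$mu, po$sigma, eps[t, idx])
      kl[l] <- kl[l] + kl_gaussians(po$mu, po$sigma, pr$mu, pr$sigma)
    }
    st <- mtrnn_step(h, d, z, W_dd, W_zd, b_d, arch$tau)
    h <- st$h; d <- st$d
    xhat[t, ] <- output_map(d[[1]], W_out, b_out)
    recon <- recon + 0.5 * sum((xhat[t, ] - x[t, ])^2)
  }
  list(loss = recon + sum(w * kl), recon = recon, kl = kl, xhat = xhat,
       mu_p = mu_p, sig_p = sig_p, mu_q = mu_q, sig_q = sig_q)
}
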