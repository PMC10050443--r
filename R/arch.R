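#' Network architecture
#'
#' Describes a multiple-timescale hierarchical network: per layer, the number
#' of deterministic units `n_d`, stochastic latent units `n_z` and the time
#' constant `tau`.  Layer 1 is the lowest (fastest) layer and drives the
#' two-dimensional output; the highest layer has the slowest dynamics.
#'
#' @param n_d integer vector, deterministic units per layer (lowest first).
#' @param n_z integer vector, latent units per layer.
#' @param tau numeric vector of time constants (>= 1), one per layer.
#' @param n_x output dimensionality (2 for the planar reaching signal).
#' @return An object of class `pvrnn_arch`.
#' @examples
#' arch <- pvrnn_arch()            # the default 3-layer network
#' arch$tau                        # c(2, 8, 32)
#' @export
pvrnn_arch <- function(n_d = c(20L, 10L, 10L), n_z = c(2L, 2L, 2L),
                       tau = c(2, 8, 32), n_x = 2L) {
  stopifnot(length(n_d) == length(n_z), length(n_d) == length(tau),
            all(n_d >= 1), all(n_z >= 1), all(tau >= 1), n_x >= 1)
  a <- list(n_d = as.integer(n_d), n_z = as.integer(n_z),
            tau = as.numeric(tau), n_x = as.integer(n_x),
            L = length(n_d))
  a$nd_total <- sum(a$n_d)
  a$nz_total <- sum(a$n_z)
  a$od <- cumsum(c(0L, a$n_d))[seq_len(a$L)]   # 0-based block offsets
  a$oz <- cumsum(c(0L, a$n_z))[seq_len(a$L)]
  class(a) <- "pvrnn_arch"
  a
}

#' @export
print.pvrnn_arch <- function(x, ...) {
  cat("Hierarchical variational RNN architecture (", x$L, " layers)\n", sep = "")
  for (l in seq_len(x$L))
    cat(sprintf("  layer %d: n_d = %d, n_z = %d, tau = %g\n",
                l, x$n_d[l], x$n_z[l], x$tau[l]))
  invisible(x)
}

#' Flat-parameter layout of a network
#'
#' All weights live in one flat numeric vector (convenient for Adam and for
#' finite-difference checks).  This returns the block table: name, 1-based
#' offset, and dimensions of each column-major block.  The order matches the
#' compiled core.
#'
#' @param arch a [pvrnn_arch()].
#' @return data.frame with columns `name`, `offset`, `nrow`, `ncol`.
#' @keywords internal
#' @export
param_layout <- function(arch) {
  rows <- list()
  off <- 0L
  add <- function(name, nr, nc) {
    rows[[length(rows) + 1L]] <<- data.frame(name = name, offset = off + 1L,
                                             nrow = nr, ncol = nc)
    off <<- off + nr * nc
  }
  for (l in seq_len(arch$L)) {
    for (m in (l - 1L):(l + 1L)) {
      if (m < 1L || m > arch$L) next
      add(sprintf("W_dd_%d_%d", l, m), arch$n_d[l], arch$n_d[m])
    }
    add(sprintf("W_zd_%d", l), arch$n_d[l], arch$n_z[l])
    add(sprintf("b_d_%d", l), arch$n_d[l], 1L)
    add(sprintf("W_pm_%d", l), arch$n_z[l], arch$n_d[l])
    add(sprintf("b_pm_%d", l), arch$n_z[l], 1L)
    add(sprintf("W_ps_%d", l), arch$n_z[l], arch$n_d[l])
    add(sprintf("b_ps_%d", l), arch$n_z[l], 1L)
  }
  add("W_out", arch$n_x, arch$n_d[1])
  add("b_out", arch$n_x, 1L)
  out <- do.call(rbind, rows)
  attr(out, "n_params") <- off
  out
}

#' Number of free parameters of an architecture
#' @param arch a [pvrnn_arch()].
#' @return integer scalar.
#' @export
n_params <- function(arch) attr(param_layout(arch), "n_params")

#' Extract one named weight block from a flat parameter vector
#' @param params flat numeric parameter vector.
#' @param arch a [pvrnn_arch()].
#' @param name block name as in [param_layout()] (e.g. `"W_out"`).
#' @return numeric matrix (or vector for bias blocks).
#' @export
param_block <- function(params, arch, name) {
  lay <- param_layout(arch)
  row <- lay[lay$name == name, ]
  if (nrow(row) != 1L) stop("unknown parameter block: ", name)
  v <- params[row$offset:(row$offset + row$nrow * row$ncol - 1L)]
  if (row$ncol == 1L) v else matrix(v, row$nrow, row$ncol)
}

#' Assign one named weight block in a flat parameter vector
#' @inheritParams param_block
#' @param value replacement values (recycled if scalar).
#' @return the modified flat parameter vector.
#' @export
set_param_block <- function(params, arch, name, value) {
  lay <- param_layout(arch)
  row <- lay[lay$name == name, ]
  if (nrow(row) != 1L) stop("unknown parameter block: ", name)
  idx <- row$offset:(row$offset + row$nrow * row$ncol - 1L)
  params[idx] <- value
  params
}

#' Initialize network weights
#'
#' Weights are drawn from Normal(0, 1/fan-in); biases start at zero.
#'
#' @param arch a [pvrnn_arch()].
#' @param seed optional integer; when given, seeds the R RNG first.
#' @return flat numeric parameter vector.
#' @export
init_params <- function(arch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lay <- param_layout(arch)
  params <- numeric(attr(lay, "n_params"))
  for (i in seq_len(nrow(lay))) {
    n <- lay$nrow[i] * lay$ncol[i]
    idx <- lay$offset[i]:(lay$offset[i] + n - 1L)
    if (grepl("^b_", lay$name[i])) {
      params[idx] <- 0
    } else {
      params[idx] <- rnorm(n, 0, 1 / sqrt(lay$ncol[i]))
    }
  }
  params
}

#' Meta-prior configuration
#'
#' The meta-prior `w` weights each layer's KL (regularization) term in the
#' free-energy loss; it controls the stochasticity of the learned dynamics.
#' The named presets set the *lowest*-layer weight to 0.1 (weak), 1 (normal)
#' or 10 (strong), keeping the other layers at 1.
#'
#' @param w numeric vector of per-layer weights (lowest first), or one of
#'   `"weak"`, `"normal"`, `"strong"`.
#' @param L number of layers (used for the presets).
#' @param w_test per-layer weights used in the test phase; defaults to `w`.
#' @return list with elements `w` and `w_test`.
#' @examples
#' meta_prior("strong")$w   # c(10, 1, 1)
#' @export
meta_prior <- function(w = "normal", L = 3L, w_test = NULL) {
  if (is.character(w)) {
    w0 <- switch(match.arg(w, c("weak", "normal", "strong")),
                 weak = 0.1, normal = 1, strong = 10)
    w <- c(w0, rep(1, L - 1L))
  }
  stopifnot(is.numeric(w), all(w >= 0))
  if (is.null(w_test)) w_test <- w
  stopifnot(length(w_test) == length(w))
  list(w = as.numeric(w), w_test = as.numeric(w_test))
}

#' Map global latent-unit ids to (layer, within-layer index)
#'
#' Units are numbered 0-based from the lowest layer up, so with two latents
#' per layer unit0/unit1 are the lowest layer and unit4/unit5 the highest.
#'
#' @param unit integer unit id (0-based).
#' @param arch a [pvrnn_arch()].
#' @return list with `layer` (1-based) and `index` (1-based within layer).
#' @export
unit_id <- function(unit, arch) {
  stopifnot(unit >= 0, unit < arch$nz_total)
  l <- findInterval(unit, arch$oz)   # oz is 0-based cumulative
  list(layer = l, index = unit - arch$oz[l] + 1L)
}
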