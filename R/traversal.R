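#' Discrete-state properties of a generated sequence
#'
#' Classifies every sample by nearest state center and summarizes: steps
#' spent in each state, number of entries (transitions) into each state, and
#' the per-state coordinate variance (sum of the two coordinate variances of
#' the samples classified to that state; 0 for states visited fewer than 2
#' steps).
#'
#' @param x `T x 2` trajectory.
#' @param cfg an [env_config()].
#' @return list with named numeric vectors `stay_steps`, `transitions`,
#'   `variance` (one entry per state).
#' @export
sequence_properties <- function(x, cfg) {
  lab <- classify_state(x, cfg)
  stay <- vapply(state_levels, function(s) sum(lab == s), 1)
  entries <- c(lab[1], lab[-1][lab[-1] != lab[-length(lab)]])
  trans <- vapply(state_levels, function(s) sum(entries == s), 1)
  vr <- vapply(state_levels, function(s) {
    pts <- x[lab == s, , drop = FALSE]
    if (nrow(pts) < 2) 0 else var(pts[, 1]) + var(pts[, 2])
  }, 1)
  list(stay_steps = stay, transitions = trans, variance = vr)
}

#' Latent-space traversal of one unit
#'
#' Generates one closed-loop sequence per grid value with the chosen latent
#' unit clamped at that value (mean channel: the sampled z entry is fixed;
#' variance channel: sigma is fixed at `exp(value)`), and summarizes each
#' generation by its discrete-state [sequence_properties()].  Non-clamped
#' latents are sampled from the prior with an independent seed per grid
#' point (`seed + i - 1`), so the property-versus-value correlation carries
#' the sampling variability of generation as its noise floor: only causal
#' effects that rise above run-to-run variability register as efficacy.
#'
#' @param params flat parameter vector (or a `pvrnn_fit`).
#' @param arch a [pvrnn_arch()] (ignored when a fit is given).
#' @param unit global latent-unit id, 0-based from the lowest layer
#'   (see [unit_id()]).
#' @param channel `"mean"` or `"variance"`.
#' @param grid fixing values; default 21 evenly spaced values in `[-1, 1]`.
#' @param T steps per generated sequence.
#' @param cfg an [env_config()] for state classification.
#' @param seed integer seed for the prior samples.
#' @return list of class `traversal_result`: `unit`, `channel`, `grid`,
#'   `properties` (list per grid value) and `efficacy`.
#' @export
traverse_unit <- function(params, arch = NULL, unit, channel = c("mean", "variance"),
                          grid = seq(-1, 1, length.out = 21), T = 1024L,
                          cfg = env_config(), seed = 1L) {
  if (inherits(params, "pvrnn_fit")) { arch <- params$arch; params <- params$params }
  channel <- match.arg(channel)
  if (length(grid) == 0) stop("grid must be nonempty")
  uid <- unit_id(unit, arch)
  props <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    g <- generate(params, arch, T, mode = "prior_sample",
                  clamp = list(layer = uid$layer, unit = uid$index,
                               channel = channel, value = grid[i]),
                  seed = seed + i - 1L)
    props[[i]] <- sequence_properties(g$xhat, cfg)
  }
  res <- structure(list(unit = unit, channel = channel, grid = grid,
                        properties = props),
                   class = "traversal_result")
  res$efficacy <- unit_efficacy(res)
  res
}

#' Efficacy of a latent unit from its traversal
#'
#' For every property channel (stay steps, transitions, variance, for each
#' state) the Pearson correlation between the grid of fixing values and the
#' property across generations is computed; the efficacy is the maximum
#' absolute correlation (zero-variance properties score 0).
#'
#' @param result a `traversal_result` with at least 3 grid points.
#' @return scalar in `[0, 1]`.
#' @export
unit_efficacy <- function(result) {
  stopifnot(length(result$grid) >= 3)
  vals <- sapply(result$properties, function(p)
    c(p$stay_steps, p$transitions, p$variance))   # 9 property channels x grid
  rr <- apply(vals, 1, safe_cor, b = result$grid)
  max(abs(rr))
}

#' Generative hierarchy of a layer
#'
#' Mean unit efficacy over the layer's latent units of one channel; measures
#' how much causal top-down control the layer's latents exert on generation.
#'
#' @param params flat parameter vector (or a `pvrnn_fit`).
#' @param arch a [pvrnn_arch()] (ignored when a fit is given).
#' @param layer layer index (1 = lowest).
#' @param channel `"mean"` or `"variance"`.
#' @param grid,T,cfg,seed passed to [traverse_unit()].
#' @return scalar in `[0, 1]`.
#' @export
generative_hierarchy <- function(params, arch = NULL, layer,
                                 channel = c("mean", "variance"),
                                 grid = seq(-1, 1, length.out = 21),
                                 T = 1024L, cfg = env_config(), seed = 1L) {
  if (inherits(params, "pvrnn_fit")) { arch <- params$arch; params <- params$params }
  channel <- match.arg(channel)
  stopifnot(layer >= 1, layer <= arch$L)
  units <- arch$oz[layer] + seq_len(arch$n_z[layer]) - 1L
  eff <- vapply(units, function(u)
    traverse_unit(params, arch, u, channel, grid, T, cfg, seed)$efficacy, 1)
  mean(eff)
}
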