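#' Environment configuration for the stochastic reaching task
#'
#' The environment generates two-dimensional reaching trajectories from a
#' three-level hidden generative process: a transition bias (the probability
#' that a reach from HOME targets LEFT), a Bernoulli target state per reach
#' (LEFT or RIGHT), and Gaussian signal noise on goal positions and
#' observations.  All coordinates live in the square `[-1, 1]^2`.
#'
#' Defaults: centers form a well-separated triangle, nine transition biases
#' spanning LEFT- and RIGHT-biased regimes, two sets of sequences of 512
#' steps, and signal-noise levels such that the three states overlap only in
#' the noisy condition.
#'
#' @param centers named list of 2-vectors for `HOME`, `LEFT`, `RIGHT`.
#' @param sigma_stable,sigma_noisy Gaussian s.d. of goal positions and
#'   per-step observation noise in the stable / noisy condition
#'   (`sigma_noisy > sigma_stable > 0`).
#' @param steps_per_segment steps per HOME-to-goal (or return) movement.
#' @param dwell_steps steps resting at a goal and at HOME.
#' @param seq_len sequence length in steps.
#' @param biases ordered vector of transition biases in (0, 1).
#' @param n_sets number of sequence sets in a training corpus.
#' @param seed integer seed recorded in the config.
#' @return An object of class `env_config`.
#' @examples
#' cfg <- env_config()
#' cfg$biases
#' @export
env_config <- function(centers = list(HOME = c(0, -0.6),
                                      LEFT = c(-0.6, 0.6),
                                      RIGHT = c(0.6, 0.6)),
                       sigma_stable = 0.05, sigma_noisy = 0.25,
                       steps_per_segment = 8L, dwell_steps = 4L,
                       seq_len = 512L,
                       biases = c(0.98, 0.87, 0.76, 0.65, 0.54,
                                  0.43, 0.32, 0.21, 0.10),
                       n_sets = 2L, seed = 1L) {
  stopifnot(setequal(names(centers), c("HOME", "LEFT", "RIGHT")),
            all(vapply(centers, length, 1L) == 2L),
            sigma_noisy > sigma_stable, sigma_stable > 0,
            steps_per_segment >= 1, dwell_steps >= 0,
            seq_len >= steps_per_segment,
            all(biases > 0 & biases < 1),
            n_sets >= 1)
  cm <- rbind(HOME = centers$HOME, LEFT = centers$LEFT, RIGHT = centers$RIGHT)
  if (any(dist(cm) == 0)) stop("state centers must be pairwise distinct")
  structure(list(centers = centers,
                 sigma_stable = sigma_stable, sigma_noisy = sigma_noisy,
                 steps_per_segment = as.integer(steps_per_segment),
                 dwell_steps = as.integer(dwell_steps),
                 seq_len = as.integer(seq_len),
                 biases = biases, n_sets = as.integer(n_sets),
                 seed = as.integer(seed)),
            class = "env_config")
}

state_levels <- c("HOME", "LEFT", "RIGHT")

env_sigma <- function(cfg, noise_condition) {
  switch(match.arg(noise_condition, c("stable", "noisy")),
         stable = cfg$sigma_stable, noisy = cfg$sigma_noisy)
}

#' Sample reach targets from the transition bias
#'
#' Each reach from HOME targets LEFT with probability `bias` and RIGHT
#' otherwise, independently (Bernoulli draws parameterized by the transition
#' bias).
#'
#' @param bias transition bias, strictly inside (0, 1) unless
#'   `allow_degenerate = TRUE` (used only for deterministic tests).
#' @param n number of reaches to draw.
#' @param seed optional integer seed.
#' @param allow_degenerate allow bias 0 or 1.
#' @return character vector of `"LEFT"` / `"RIGHT"` labels.
#' @examples
#' table(sample_target_states(0.76, 1000, seed = 1))
#' @export
sample_target_states <- function(bias, n, seed = NULL, allow_degenerate = FALSE) {
  if (allow_degenerate) stopifnot(bias >= 0, bias <= 1)
  else if (!(bias > 0 && bias < 1)) stop("bias must lie strictly inside (0, 1)")
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  ifelse(rbinom(n, 1L, bias) == 1L, "LEFT", "RIGHT")
}

#' Classify a point (or trajectory) into a discrete state
#'
#' Nearest-center classification under Euclidean distance; ties are broken
#' by the fixed order HOME < LEFT < RIGHT.
#'
#' @param point a length-2 coordinate or an `n x 2` matrix of coordinates.
#' @param cfg an [env_config()].
#' @return character state label(s).
#' @export
classify_state <- function(point, cfg) {
  cm <- rbind(cfg$centers$HOME, cfg$centers$LEFT, cfg$centers$RIGHT)
  if (is.null(dim(point))) point <- matrix(point, ncol = 2)
  stopifnot(all(is.finite(point)))
  d2 <- sapply(1:3, function(s)
    (point[, 1] - cm[s, 1])^2 + (point[, 2] - cm[s, 2])^2)
  if (is.null(dim(d2))) d2 <- matrix(d2, ncol = 3)
  state_levels[max.col(-d2, ties.method = "first")]
}

# One reach cycle: HOME -> goal (steps_per_segment), dwell at goal,
# goal -> HOME, dwell at HOME.  Returns the noiseless path and target labels.
reach_path <- function(goal, target, cfg) {
  home <- cfg$centers$HOME
  s <- cfg$steps_per_segment
  fr <- seq_len(s) / s
  out_leg <- cbind(home[1] + fr * (goal[1] - home[1]),
                   home[2] + fr * (goal[2] - home[2]))
  back_leg <- cbind(goal[1] + fr * (home[1] - goal[1]),
                    goal[2] + fr * (home[2] - goal[2]))
  dwell_goal <- matrix(goal, cfg$dwell_steps, 2, byrow = TRUE)
  dwell_home <- matrix(home, cfg$dwell_steps, 2, byrow = TRUE)
  path <- rbind(out_leg, dwell_goal, back_leg, dwell_home)
  tgt <- c(rep(target, s + cfg$dwell_steps),        # outbound + dwell at goal
           rep("HOME", s + cfg$dwell_steps))        # return + dwell at HOME
  list(path = path, target = tgt)
}

#' Render a reaching trajectory from a list of targets
#'
#' For each target a goal is drawn from a Gaussian centered on the target's
#' coordinate with s.d. equal to the condition's signal noise; the object
#' moves HOME -> goal -> HOME by linear interpolation, dwelling at the goal
#' and at HOME.  The target-draw process repeats until `cfg$seq_len` steps
#' are filled (extra targets are drawn with the same `bias` if needed), then
#' i.i.d. Gaussian observation noise of the same s.d. is added per step and
#' coordinates are clipped to `[-1, 1]`.
#'
#' @param targets character vector of `"LEFT"`/`"RIGHT"` reach targets.
#' @param bias the transition bias that produced `targets` (recorded in the
#'   ground truth and used for any extra target draws).
#' @param cfg an [env_config()].
#' @param noise_condition `"stable"` or `"noisy"`.
#' @param seed optional integer seed.
#' @return A `trajectory_sequence`: list with `x` (`seq_len x 2` observed
#'   signal), `truth` (data.frame `bias`, `target`, `state`) and `meta`.
#' @export
render_trajectory <- function(targets, bias, cfg,
                              noise_condition = c("stable", "noisy"),
                              seed = NULL) {
  stopifnot(length(targets) >= 1, all(targets %in% c("LEFT", "RIGHT")))
  noise_condition <- match.arg(noise_condition)
  if (!is.null(seed)) set.seed(seed)
  sigma <- env_sigma(cfg, noise_condition)

  path <- matrix(numeric(0), 0, 2)
  tgt <- character(0)
  i <- 0L
  while (nrow(path) < cfg$seq_len) {
    i <- i + 1L
    target <- if (i <= length(targets)) targets[i] else
      sample_target_states(bias, 1L)
    goal <- cfg$centers[[target]] + rnorm(2, 0, sigma)
    rp <- reach_path(goal, target, cfg)
    path <- rbind(path, rp$path)
    tgt <- c(tgt, rp$target)
  }
  path <- path[seq_len(cfg$seq_len), , drop = FALSE]
  tgt <- tgt[seq_len(cfg$seq_len)]

  state <- classify_state(path, cfg)          # noiseless nearest-state label
  x <- path + matrix(rnorm(2L * cfg$seq_len, 0, sigma), ncol = 2)
  x[x > 1] <- 1; x[x < -1] <- -1

  structure(list(x = x,
                 truth = data.frame(bias = rep(bias, cfg$seq_len),
                                    target = tgt, state = state,
                                    stringsAsFactors = FALSE),
                 meta = list(bias = bias, noise_condition = noise_condition,
                             seed = seed)),
            class = "trajectory_sequence")
}

#' @export
print.trajectory_sequence <- function(x, ...) {
  cat(sprintf("trajectory_sequence: %d steps, bias %s, %s condition\n",
              nrow(x$x), paste(unique(x$truth$bias), collapse = " -> "),
              x$meta$noise_condition))
  invisible(x)
}

#' Build the training corpus
#'
#' `n_sets` sets of sequences, one per configured transition bias (the
#' default yields 18 sequences of 512 steps over nine biases).
#'
#' @param cfg an [env_config()].
#' @param noise_condition `"stable"` or `"noisy"`.
#' @param seed optional integer seed.
#' @return list of `trajectory_sequence` objects.
#' @export
build_training_set <- function(cfg, noise_condition = c("stable", "noisy"),
                               seed = NULL) {
  noise_condition <- match.arg(noise_condition)
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (s in seq_len(cfg$n_sets)) {
    for (b in cfg$biases) {
      n_reach <- ceiling(cfg$seq_len / (2L * (cfg$steps_per_segment + cfg$dwell_steps)))
      targets <- sample_target_states(b, n_reach)
      out[[length(out) + 1L]] <- render_trajectory(targets, b, cfg, noise_condition)
    }
  }
  out
}

#' Build a context-switching test sequence
#'
#' Two half-sequences with different transition biases are concatenated: the
#' first half's bias is drawn from the configured bias list (or given), the
#' second half's bias is drawn uniformly from the configured biases on the
#' opposite side of 0.5.  The ground-truth bias switches at the first step of
#' the second half (step `seq_len/2 + 1`, 1-based).
#'
#' @param cfg an [env_config()]; `cfg$biases` must contain values on both
#'   sides of 0.5 and `cfg$seq_len` must be even.
#' @param noise_condition `"stable"` or `"noisy"`.
#' @param seed optional integer seed.
#' @param first_bias optional fixed bias for the first half.
#' @return a `trajectory_sequence` whose `truth$bias` is piecewise constant
#'   with exactly one change.
#' @export
build_test_sequence <- function(cfg, noise_condition = c("stable", "noisy"),
                                seed = NULL, first_bias = NULL) {
  noise_condition <- match.arg(noise_condition)
  if (!is.null(seed)) set.seed(seed)
  if (cfg$seq_len %% 2L != 0L) stop("seq_len must be even for a test sequence")
  if (!any(cfg$biases > 0.5) || !any(cfg$biases < 0.5))
    stop("biases must include values on both sides of 0.5")
  half <- cfg$seq_len %/% 2L
  hcfg <- cfg; hcfg$seq_len <- half

  b1 <- if (is.null(first_bias)) sample(cfg$biases, 1L) else first_bias
  opp <- if (b1 > 0.5) cfg$biases[cfg$biases < 0.5] else cfg$biases[cfg$biases > 0.5]
  b2 <- if (length(opp) == 1L) opp else sample(opp, 1L)

  n_reach <- ceiling(half / (2L * (cfg$steps_per_segment + cfg$dwell_steps)))
  s1 <- render_trajectory(sample_target_states(b1, n_reach), b1, hcfg, noise_condition)
  s2 <- render_trajectory(sample_target_states(b2, n_reach), b2, hcfg, noise_condition)

  structure(list(x = rbind(s1$x, s2$x),
                 truth = rbind(s1$truth, s2$truth),
                 meta = list(bias = c(b1, b2), noise_condition = noise_condition,
                             seed = seed, switch_step = half + 1L)),
            class = "trajectory_sequence")
}
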