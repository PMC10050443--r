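test_that("target-state sampling follows the transition bias", {
  expect_error(sample_target_states(0, 5), "strictly inside")
  expect_error(sample_target_states(1.2, 5, allow_degenerate = TRUE))
  # degenerate Bernoulli behind the explicit flag
  expect_equal(sample_target_states(1, 5, seed = 1, allow_degenerate = TRUE),
               rep("LEFT", 5))
  expect_equal(sample_target_states(0, 5, seed = 1, allow_degenerate = TRUE),
               rep("RIGHT", 5))
  # calibration at the LEFT-biased level used throughout the study
  n <- 10000L
  frac <- mean(sample_target_states(0.76, n, seed = 42) == "LEFT")
  expect_lt(abs(frac - 0.76), 4 * sqrt(0.76 * 0.24 / n))
})

test_that("zero-noise trajectories follow the home-goal geometry exactly", {
  cfg <- noise_free_env(seq_len = 24L)   # exactly one reach cycle
  s <- render_trajectory("LEFT", 0.76, cfg, "stable", seed = 1)
  home <- cfg$centers$HOME; left <- cfg$centers$LEFT
  # every sample lies on the HOME-LEFT segment
  dir <- (left - home) / sqrt(sum((left - home)^2))
  perp <- apply(s$x, 1, function(p) {
    v <- p - home
    sqrt(max(0, sum(v^2) - sum(v * dir)^2))
  })
  expect_lt(max(perp), 1e-7)
  # reaches the goal exactly and returns home
  expect_equal(s$x[cfg$steps_per_segment, ], left, ignore_attr = TRUE)
  expect_equal(s$x[nrow(s$x), ], home, ignore_attr = TRUE)
})

test_that("zero-noise state labels visit HOME, LEFT, HOME, RIGHT, HOME in order", {
  cfg <- noise_free_env(seq_len = 48L)
  s <- render_trajectory(c("LEFT", "RIGHT"), 0.76, cfg, "stable", seed = 1)
  lab <- classify_state(s$x, cfg)
  runs <- rle(lab)$values
  expect_equal(runs, c("HOME", "LEFT", "HOME", "RIGHT", "HOME"))
  # and classification reproduces the recorded ground truth
  expect_equal(lab, s$truth$state)
})

test_that("noisy condition spreads per-state coordinates more than stable", {
  cfg <- tiny_env(seq_len = 512L)
  targets <- sample_target_states(0.76, 40, seed = 9)
  st <- render_trajectory(targets, 0.76, cfg, "stable", seed = 10)
  no <- render_trajectory(targets, 0.76, cfg, "noisy", seed = 10)
  v <- function(s) {
    lab <- s$truth$target
    var(s$x[lab == "LEFT", 1]) + var(s$x[lab == "LEFT", 2])
  }
  expect_gt(v(no), v(st))
})

test_that("training corpus has the configured shape and bias multiset", {
  cfg <- env_config()
  seqs <- build_training_set(cfg, "stable", seed = 1)
  expect_length(seqs, 18L)
  expect_true(all(vapply(seqs, function(s) nrow(s$x), 1L) == 512L))
  biases <- vapply(seqs, function(s) s$meta$bias, 1)
  expect_equal(sort(unique(biases)), sort(cfg$biases))
  expect_true(all(table(biases) == 2L))
  # every sequence carries a complete, aligned ground truth
  ok <- vapply(seqs, function(s)
    nrow(s$truth) == nrow(s$x) && all(is.finite(s$x)) &&
      length(unique(s$truth$bias)) == 1L, TRUE)
  expect_true(all(ok))

  one <- build_training_set(env_config(biases = 0.5, n_sets = 1L), "stable",
                            seed = 1)
  expect_length(one, 1L)
})

test_that("test sequences switch bias once, to the opposite side of 0.5", {
  cfg <- env_config()
  s <- build_test_sequence(cfg, "stable", seed = 3)
  expect_equal(nrow(s$x), 512L)
  changes <- which(diff(s$truth$bias) != 0)
  expect_equal(changes, 256L)   # first step of the second half (t_code = 256)
  for (seed in 1:200) {
    s <- build_test_sequence(cfg, "stable", seed = seed)
    b <- unique(s$truth$bias)
    expect_length(b, 2L)
    expect_true(sign(b[1] - 0.5) != sign(b[2] - 0.5))
  }
  # forcing a LEFT-biased first half restricts the second half
  for (seed in 1:50) {
    s <- build_test_sequence(cfg, "stable", seed = seed, first_bias = 0.98)
    expect_true(unique(s$truth$bias)[2] %in% c(0.43, 0.32, 0.21, 0.10))
  }
  expect_error(build_test_sequence(env_config(biases = c(0.7, 0.9))),
               "both sides")
})

test_that("state classification uses nearest centers with HOME-first ties", {
  cfg <- env_config()
  expect_equal(classify_state(cfg$centers$LEFT, cfg), "LEFT")
  expect_equal(classify_state(cfg$centers$RIGHT, cfg), "RIGHT")
  mid <- (cfg$centers$HOME + cfg$centers$LEFT) / 2   # exact tie
  expect_equal(classify_state(mid, cfg), "HOME")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- tiny_env()
  a <- build_training_set(cfg, "noisy", seed = 77)
  b <- build_training_set(cfg, "noisy", seed = 77)
  expect_identical(a, b)
  t1 <- build_test_sequence(cfg, "stable", seed = 5)
  t2 <- build_test_sequence(cfg, "stable", seed = 5)
  expect_identical(t1, t2)
})

test_that("sequences round-trip through CSV plus manifest", {
  cfg <- tiny_env(seq_len = 32L)
  seqs <- build_training_set(cfg, "stable", seed = 2)
  dir <- withr::local_tempdir()
  write_sequences(seqs, dir, cfg)
  back <- read_sequences(dir)
  expect_length(back, length(seqs))
  for (i in seq_along(seqs)) {
    expect_equal(back[[i]]$x, seqs[[i]]$x, ignore_attr = TRUE)
    expect_equal(back[[i]]$truth$state, seqs[[i]]$truth$state)
    expect_equal(back[[i]]$truth$bias, seqs[[i]]$truth$bias)
  }
})
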