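test_that("IQR filter removes values beyond the 1.5-fence", {
  r <- iqr_filter(c(1:9, 100))
  # type-7 quartiles of {1..9,100}: Q1 = 3.25, Q3 = 6.75, upper fence 12.0
  expect_equal(r$removed, 100)
  expect_equal(r$kept, 1:9)
  expect_length(iqr_filter(rep(5, 10))$removed, 0L)
  expect_length(iqr_filter(c(1:9, 100), k = Inf)$removed, 0L)
  expect_warning(r <- iqr_filter(c(1, 2, 3)), "fewer than 4")
  expect_equal(r$kept, c(1, 2, 3))
})

test_that("one-way ANOVA agrees with a brute-force sum-of-squares oracle", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  g <- list(a = c(6.1, 5.8, 6.4, 6.0), b = c(7.2, 7.0, 6.8), c = c(5.1, 5.6, 5.3, 5.0, 5.2))
  res <- anova_oneway(g)
  # independent oracle: explicit between/within sums of squares
  y <- unlist(g); gm <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  k <- length(g); n <- length(y)
  F_oracle <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(res$F, F_oracle, tolerance = 1e-10)
  expect_equal(res$df1, k - 1)
  expect_equal(res$df2, n - k)
  expect_equal(res$p, pf(F_oracle, k - 1, n - k, lower.tail = FALSE),
               tolerance = 1e-12)
  # and with the standard linear-model route
  d <- data.frame(y = y, g = rep(names(g), lengths(g)))
  expect_equal(res$F, summary(aov(y ~ g, d))[[1]]$`F value`[1], tolerance = 1e-10)
})

test_that("two-way ANOVA detects an environment offset in one level only", {
  set.seed(10)
  d <- expand.grid(meta_prior = c("weak", "normal", "strong"),
                   environment = c("stable", "noisy"), rep = 1:8)
  d$y <- rnorm(nrow(d), 50, 0.5)
  d$y[d$meta_prior == "strong" & d$environment == "noisy"] <-
    d$y[d$meta_prior == "strong" & d$environment == "noisy"] + 20
  res <- anova_twoway(d)
  inter <- res$effects[res$effects$effect == "meta_prior:environment", ]
  expect_gt(inter$F, 10)
  se <- res$simple_effects
  strong <- se[grepl("strong", se$effect), ]
  expect_equal(strong$F, max(se$F))
  expect_lt(strong$p, 1e-6)
})

test_that("identical observations in every cell give zero F throughout", {
  d <- expand.grid(meta_prior = c("weak", "normal", "strong"),
                   environment = c("stable", "noisy"), rep = 1:4)
  d$y <- 42
  res <- anova_twoway(d)
  expect_equal(res$effects$F, rep(0, 3))
  expect_equal(res$simple_effects$F, rep(0, 3))
})

test_that("balanced designs make Type-III and sequential ANOVA coincide", {
  set.seed(11)
  d <- expand.grid(meta_prior = c("weak", "normal", "strong"),
                   environment = c("stable", "noisy"), rep = 1:6)
  d$y <- rnorm(nrow(d)) + as.numeric(factor(d$meta_prior)) * 0.5
  res <- anova_twoway(d)
  fit <- lm(y ~ mp * env, data = data.frame(y = d$y, mp = factor(d$meta_prior),
                                            env = factor(d$environment)))
  seq_tab <- anova(fit)   # Type-I
  expect_equal(res$effects$F, seq_tab$`F value`[1:3], tolerance = 1e-10)
  expect_error(anova_twoway(d[d$meta_prior != "weak" | d$environment != "noisy", ]),
               "nonempty")
})

test_that("Shaffer's sequentially rejective procedure follows its thresholds", {
  expect_equal(shaffer_posthoc(c(1, 1, 1)), rep(FALSE, 3))
  # smallest clears alpha/3, remaining clear alpha/1
  expect_equal(shaffer_posthoc(c(0.001, 0.02, 0.03), alpha = 0.05), rep(TRUE, 3))
  # smallest p fails alpha/3: testing stops, nothing is rejected
  expect_equal(shaffer_posthoc(c(0.02, 0.04, 0.03), alpha = 0.05), rep(FALSE, 3))
  # middle hypothesis fails alpha after the first rejection
  expect_equal(shaffer_posthoc(c(0.01, 0.2, 0.03), alpha = 0.05),
               c(TRUE, FALSE, TRUE))
  # order of the input is preserved in the decisions
  expect_equal(shaffer_posthoc(c(0.2, 0.001, 0.03), alpha = 0.05),
               c(FALSE, TRUE, TRUE))
})

test_that("pairwise t statistics use the pooled error term", {
  g <- list(weak = c(5, 6, 7), normal = c(6, 7, 8), strong = c(1, 2, 3))
  res <- pairwise_t(g)
  expect_equal(nrow(res), 3L)
  expect_equal(unique(res$df), 6L)   # N - g = 9 - 3
  mse <- sum(sapply(g, function(v) sum((v - mean(v))^2))) / 6
  t_oracle <- (mean(g$weak) - mean(g$strong)) / sqrt(mse * (2 / 3))
  expect_equal(res$t[res$pair == "weak-strong"], t_oracle, tolerance = 1e-12)
})

test_that("condition means filter outliers within each cell", {
  res <- data.frame(meta_prior = rep("normal", 10),
                    environment = rep("stable", 10),
                    behavioral = c(rep(80, 9), 5))
  cm <- condition_means(res, "behavioral")
  expect_equal(cm$mean, 80)
  expect_equal(cm$n_kept, 9)
})
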