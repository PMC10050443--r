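#' Remove outliers by the 1.5 x IQR rule
#'
#' Values below `Q1 - k*IQR` or above `Q3 + k*IQR` are removed, with
#' quartiles computed by the linear-interpolation convention
#' (`stats::quantile` type 7).  Fewer than 4 values are returned unchanged
#' with a warning.
#'
#' @param values numeric vector.
#' @param k fence multiplier (default 1.5).
#' @return list with `kept` and `removed`.
#' @examples
#' iqr_filter(c(1:9, 100))$removed   # 100
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4) {
    warning("fewer than 4 values; no outlier filtering applied")
    return(list(kept = values, removed = numeric(0)))
  }
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - k * iqr; hi <- q[2] + k * iqr
  out <- values < lo | values > hi
  out[is.na(out)] <- FALSE
  list(kept = values[!out], removed = values[out])
}

#' One-way between-subject ANOVA
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @return data.frame with `effect`, `F`, `df1`, `df2`, `p`.  A zero pooled
#'   within-group variance yields `F = Inf` (flagged, `p = 0`) unless the
#'   between-group variance is also zero, in which case `F = 0`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2, all(vapply(groups, length, 1L) >= 2))
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  n <- length(y); k <- nlevels(g)
  ss_b <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
  ss_w <- sum((y - ave(y, g))^2)
  df1 <- k - 1L; df2 <- n - k
  if (ss_w == 0) {
    F <- if (ss_b == 0) 0 else Inf
    p <- if (ss_b == 0) 1 else 0
  } else {
    F <- (ss_b / df1) / (ss_w / df2)
    p <- pf(F, df1, df2, lower.tail = FALSE)
  }
  data.frame(effect = "group", F = F, df1 = df1, df2 = df2, p = p)
}

#' Two-way between-subject ANOVA with simple effects of environment
#'
#' Meta-prior x environment design with Type-III sums of squares
#' (sum-to-zero contrasts, via `car::Anova`), as appropriate for cells left
#' unbalanced by outlier removal.  Simple effects of environment within each
#' meta-prior level use the pooled error term of the full model.
#'
#' @param data data.frame with numeric `y` and factors (or strings)
#'   `meta_prior` and `environment`; all six cells must be nonempty.
#' @return list with `effects` (main effects and interaction) and
#'   `simple_effects` (environment within each meta-prior level), both
#'   data.frames with `effect`, `F`, `df1`, `df2`, `p`.
#' @export
anova_twoway <- function(data) {
  stopifnot(all(c("y", "meta_prior", "environment") %in% names(data)))
  d <- data.frame(y = data$y,
                  mp = factor(data$meta_prior),
                  env = factor(data$environment))
  tab <- table(d$mp, d$env)
  if (any(tab == 0)) stop("every meta_prior x environment cell must be nonempty")
  lab <- c("meta_prior", "environment", "meta_prior:environment")
  if (var(d$y) < 1e-24) {
    # degenerate data: no variation anywhere, every effect is null
    dfm <- nlevels(d$mp) - 1L; dfe <- nlevels(d$env) - 1L
    zero_eff <- data.frame(effect = lab, F = 0, df1 = c(dfm, dfe, dfm * dfe),
                           df2 = nrow(d) - nlevels(d$mp) * nlevels(d$env), p = 1)
    zero_se <- data.frame(effect = paste0("environment | meta_prior=",
                                          levels(d$mp)),
                          F = 0, df1 = dfe,
                          df2 = nrow(d) - nlevels(d$mp) * nlevels(d$env), p = 1)
    return(list(effects = zero_eff, simple_effects = zero_se))
  }
  fit <- lm(y ~ mp * env, data = d,
            contrasts = list(mp = "contr.sum", env = "contr.sum"))
  a3 <- car::Anova(fit, type = 3)
  rows <- c("mp", "env", "mp:env")
  df2 <- a3["Residuals", "Df"]
  mse <- a3["Residuals", "Sum Sq"] / df2
  effects <- data.frame(effect = lab,
                        F = a3[rows, "F value"],
                        df1 = a3[rows, "Df"], df2 = df2,
                        p = a3[rows, "Pr(>F)"], row.names = NULL)
  # degenerate data: a zero effect SS is "no effect", not 0/0
  zero <- a3[rows, "Sum Sq"] < 1e-12
  effects$F[zero] <- 0
  effects$p[zero] <- 1
  if (mse < 1e-12) mse <- NA_real_
  # simple effect of environment within each meta-prior level (pooled error)
  se <- lapply(levels(d$mp), function(lv) {
    dd <- d[d$mp == lv, ]
    m <- tapply(dd$y, dd$env, mean)
    n <- tapply(dd$y, dd$env, length)
    gm <- sum(n * m) / sum(n)
    ss <- sum(n * (m - gm)^2)
    df1 <- length(m) - 1L
    F <- if (ss < 1e-12) 0 else (ss / df1) / mse
    data.frame(effect = paste0("environment | meta_prior=", lv),
               F = F, df1 = df1, df2 = df2,
               p = if (F == 0) 1 else pf(F, df1, df2, lower.tail = FALSE))
  })
  list(effects = effects, simple_effects = do.call(rbind, se))
}

#' Pairwise t statistics with a pooled error term
#'
#' All pairwise comparisons between groups using the pooled within-group
#' variance of the one-way design (error df `N - g`), the usual post-hoc
#' companion to a between-subject ANOVA.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame with `pair`, `t`, `df`, `p` (two-sided).
#' @export
pairwise_t <- function(groups) {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  y <- unlist(groups)
  g <- rep(names(groups), vapply(groups, length, 1L))
  df2 <- length(y) - length(groups)
  mse <- sum((y - ave(y, g))^2) / df2
  cmb <- combn(names(groups), 2)
  out <- apply(cmb, 2, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    t <- (mean(a) - mean(b)) / sqrt(mse * (1 / length(a) + 1 / length(b)))
    data.frame(pair = paste(pr[1], pr[2], sep = "-"), t = t, df = df2,
               p = 2 * pt(abs(t), df2, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' Shaffer's modified sequentially rejective Bonferroni procedure
#'
#' For three groups (three pairwise hypotheses): order the p-values
#' ascending and test them against `alpha/3, alpha, alpha` — after one true
#' rejection at most one pairwise null can still hold, so the later
#' denominators drop to 1.  Testing stops at the first retention.
#'
#' @param p numeric vector of 3 pairwise p-values.
#' @param alpha familywise error rate.
#' @return logical vector, `TRUE` where the hypothesis is rejected, in the
#'   original order of `p`.
#' @export
shaffer_posthoc <- function(p, alpha = 0.05) {
  stopifnot(length(p) == 3, all(p >= 0 & p <= 1))
  ord <- order(p)
  crit <- alpha / c(3, 1, 1)
  rej <- logical(3)
  for (i in 1:3) {
    if (p[ord[i]] <= crit[i]) rej[ord[i]] <- TRUE else break
  }
  rej
}

#' Scaled-down environment and training presets
#'
#' A reduced version of the full study design for desk-scale replication:
#' one set of six transition biases (three per side of 0.5), 256-step
#' sequences, five networks per condition, and a fixed developmental
#' budget of 2,000 batch-gradient epochs at Adam learning rate 3e-3 (the
#' epoch count where the normal condition's training loss sits on its
#' plateau at this corpus size; the same budget is applied to every
#' condition).
#'
#' @param seed integer seed.
#' @return list with `env` (an [env_config()]) and `train` (a
#'   [train_config()]).
#' @export
scaled_preset <- function(seed = 1L) {
  list(env = env_config(seq_len = 256L,
                        biases = c(0.98, 0.87, 0.76, 0.32, 0.21, 0.10),
                        n_sets = 1L, seed = seed),
       train = train_config(epochs = 2000L, learning_rate = 3e-3,
                            n_networks = 5L, seed = seed))
}

#' Run the meta-prior x environment condition grid
#'
#' For every combination of meta-prior condition (weak/normal/strong) and
#' environment (stable/noisy): builds a training corpus, trains
#' `n_networks` networks (seeds `seed + i - 1`), runs error regression on
#' `n_test` freshly generated context-switching test sequences per network,
#' and computes behavioral flexibility, cognitive flexibility and the
#' per-layer generative hierarchy (mean channel, plus the pooled
#' variance-channel score).
#'
#' @param env_cfg an [env_config()] (e.g. `scaled_preset()$env`).
#' @param train_cfg a [train_config()]; its `meta_prior` is overridden per
#'   condition.
#' @param arch a [pvrnn_arch()].
#' @param reg_cfg a [regression_config()].
#' @param meta_priors,environments condition levels to run.
#' @param n_test test sequences per network (metrics are averaged).
#' @param seed base seed; condition c uses `seed + 1000*c`.
#' @param verbose print one line per trained network.
#' @return data.frame with one row per network: `meta_prior`,
#'   `environment`, `network`, `behavioral`, `cognitive`, `gh_lower`,
#'   `gh_middle`, `gh_higher`, `gh_variance`, and `error` (NA on success).
#' @export
run_grid <- function(env_cfg = scaled_preset()$env,
                     train_cfg = scaled_preset()$train,
                     arch = pvrnn_arch(),
                     reg_cfg = regression_config(),
                     meta_priors = c("weak", "normal", "strong"),
                     environments = c("stable", "noisy"),
                     n_test = 2L, seed = 1L, verbose = FALSE) {
  rows <- list()
  ci <- 0L
  for (mp in meta_priors) for (env in environments) {
    ci <- ci + 1L
    cond_seed <- seed + 1000L * ci
    tc <- train_cfg
    tc$meta_prior <- meta_prior(mp, L = arch$L)
    tc$seed <- cond_seed
    for (i in seq_len(tc$n_networks)) {
      net_seed <- cond_seed + i - 1L
      row <- data.frame(meta_prior = mp, environment = env, network = net_seed,
                        behavioral = NA_real_, cognitive = NA_real_,
                        gh_lower = NA_real_, gh_middle = NA_real_,
                        gh_higher = NA_real_, gh_variance = NA_real_,
                        error = NA_character_, stringsAsFactors = FALSE)
      res <- tryCatch({
        corpus <- build_training_set(env_cfg, env, seed = net_seed)
        tci <- tc; tci$seed <- net_seed; tci$n_networks <- 1L
        fit <- train_network(corpus, arch, tci)
        beh <- cog <- numeric(n_test)
        for (k in seq_len(n_test)) {
          test <- build_test_sequence(env_cfg, env, seed = net_seed + 500L * k)
          er <- error_regression(fit, test, reg_cfg, seed = net_seed + 900L * k)
          beh[k] <- behavioral_flexibility(er$pred, test, env_cfg)
          cog[k] <- cognitive_flexibility(er$trace, test, arch)$score
        }
        gh <- vapply(seq_len(arch$L), function(l)
          generative_hierarchy(fit$params, arch, l, "mean",
                               cfg = env_cfg, seed = net_seed), 1)
        ghv <- vapply(seq_len(arch$L), function(l)
          generative_hierarchy(fit$params, arch, l, "variance",
                               cfg = env_cfg, seed = net_seed), 1)
        row$behavioral <- mean(beh); row$cognitive <- mean(cog)
        row$gh_lower <- gh[1]; row$gh_middle <- gh[2]; row$gh_higher <- gh[3]
        row$gh_variance <- mean(ghv)
        row
      }, error = function(e) { row$error <- conditionMessage(e); row })
      if (verbose)
        message(sprintf("[%s/%s] network %d: behavioral=%.1f cognitive=%.2f",
                        mp, env, net_seed, res$behavioral, res$cognitive))
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

#' Condition means after per-metric outlier filtering
#'
#' Applies the 1.5 x IQR filter within each condition cell independently
#' per metric (matching the study's per-analysis filtering), then averages.
#'
#' @param results a [run_grid()] results table.
#' @param metric column name to summarize.
#' @param k fence multiplier for [iqr_filter()].
#' @return data.frame `meta_prior`, `environment`, `mean`, `n_kept`.
#' @export
condition_means <- function(results, metric = "behavioral", k = 1.5) {
  stopifnot(metric %in% names(results))
  cells <- unique(results[, c("meta_prior", "environment")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    v <- results[results$meta_prior == cells$meta_prior[i] &
                   results$environment == cells$environment[i], metric]
    v <- v[!is.na(v)]
    kept <- if (length(v) >= 4) iqr_filter(v, k)$kept else v
    data.frame(meta_prior = cells$meta_prior[i],
               environment = cells$environment[i],
               mean = mean(kept), n_kept = length(kept))
  })
  do.call(rbind, out)
}
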