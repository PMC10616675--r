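test_that("stage-1 per-timepoint t tests match stats::t.test", {
  times <- c(0, 15, 30, 45, 60)
  set.seed(10)
  ctrl <- array(100, dim = c(3, 4, 5))
  ko <- array(100, dim = c(3, 4, 5))
  means_c <- c(70, 50, 35, 25); means_k <- c(70, 95, 93, 90)
  for (ti in 2:5) {
    ctrl[, , ti] <- means_c[ti - 1] + rnorm(12, 0, 2)
    ko[, , ti] <- means_k[ti - 1] + rnorm(12, 0, 2)
  }
  cv <- curves_from_percent(list(control = ctrl, ko = ko), times)
  s1 <- stage1_screen(cv, c("control", "ko"))
  for (g in 1:3) for (ti in 2:5) {
    oracle <- stats::t.test(ko[g, , ti], ctrl[g, , ti], var.equal = TRUE)
    expect_equal(unname(s1$p[g, ti - 1]), oracle$p.value, tolerance = 1e-12)
    expect_equal(unname(s1$t[g, ti - 1]), unname(oracle$statistic),
                 tolerance = 1e-12)
  }
  # the separation at 30/45/60 gives p << 1e-4 and a qualifying window at 30
  expect_true(all(s1$p[, c("30", "45", "60")] < 1e-4))
  expect_true(all(s1$result$stage1_pass))
  expect_equal(s1$result$window_start_min, rep(30, 3))

  # Welch variant agrees with t.test(var.equal = FALSE)
  s1w <- stage1_screen(cv, c("control", "ko"),
                       screen_config(stage1_test_variant = "welch"))
  oracle <- stats::t.test(ko[1, , 2], ctrl[1, , 2])
  expect_equal(unname(s1w$p[1, "15"]), oracle$p.value, tolerance = 1e-12)
})

test_that("stage 1 needs consecutive significant timepoints and direction", {
  times <- c(0, 15, 30, 45, 60, 90, 120)
  set.seed(2)
  ctrl <- array(100, dim = c(1, 4, 7)); ko <- ctrl
  for (ti in 2:7) {
    ctrl[, , ti] <- 50 + rnorm(4, 0, 2)
    # significant only at 15, 45 and 120 (non-consecutive)
    ko[, , ti] <- (if (times[ti] %in% c(15, 45, 120)) 95 else 51) + rnorm(4, 0, 2)
  }
  cv <- curves_from_percent(list(control = ctrl, ko = ko), times)
  s1 <- stage1_screen(cv, c("control", "ko"))
  expect_true(all(s1$p[, c("15", "45", "120")] < 0.008))
  expect_false(s1$result$stage1_pass)

  # identical groups: zero difference, p = 1, no pass
  cv0 <- curves_from_percent(list(control = ctrl, ko = ctrl), times)
  s0 <- stage1_screen(cv0, c("control", "ko"))
  expect_true(all(abs(s0$diff) < 1e-12))
  expect_false(s0$result$stage1_pass)

  # stabilization in the wrong direction is rejected when direction required
  destab <- noisy_decay_percents(1, 120, 20, times = times, sd = 2, seed = 8)
  cvd <- curves_from_percent(destab, times)
  expect_false(stage1_screen(cvd, c("control", "ko"))$result$stage1_pass)
  expect_true(stage1_screen(cvd, c("control", "ko"),
                            screen_config(require_direction = FALSE))$result$stage1_pass)

  # lowering alpha never adds genes
  set.seed(30)
  noisy <- noisy_decay_percents(200, 25, 32, seed = 30)
  cvn <- curves_from_percent(noisy, default_grid)
  lo <- stage1_screen(cvn, c("control", "ko"), screen_config(stage1_alpha = 0.001))
  hi <- stage1_screen(cvn, c("control", "ko"), screen_config(stage1_alpha = 0.008))
  expect_true(all(lo$result$gene_id[lo$result$stage1_pass] %in%
                    hi$result$gene_id[hi$result$stage1_pass]))
})

test_that("repeated-measures ANOVA matches car::Anova with GG correction", {
  set.seed(77)
  k <- 7; n <- 4
  Y <- rbind(matrix(rnorm(n * k, rep(c(100, 80, 60, 45, 35, 25, 20), each = n), 6), n),
             matrix(rnorm(n * k, rep(c(100, 92, 85, 80, 74, 66, 60), each = n), 6), n))
  grp <- rep(c("control", "ko"), each = n)
  mine <- rm_anova_gg(Y, grp)

  df <- data.frame(group = factor(grp))
  # type-3 tests need sum-to-zero contrasts
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  mod <- stats::lm(Y ~ group, data = df)
  A <- car::Anova(mod, idata = data.frame(time = factor(seq_len(k))),
                  idesign = ~time, type = 3)
  s <- summary(A, multivariate = FALSE)
  ut <- s$univariate.tests
  expect_equal(mine$F_group, ut["group", "F value"], tolerance = 1e-10)
  expect_equal(mine$p_group, ut["group", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(mine$F_time, ut["time", "F value"], tolerance = 1e-10)
  expect_equal(mine$F_interaction, ut["group:time", "F value"],
               tolerance = 1e-10)
  pa <- s$pval.adjustments
  expect_equal(mine$epsilon, pa["time", "GG eps"], tolerance = 1e-10)
  expect_equal(mine$p_time_gg, pa["time", "Pr(>F[GG])"], tolerance = 1e-10)
  expect_equal(mine$p_interaction_gg, pa["group:time", "Pr(>F[GG])"],
               tolerance = 1e-10)
})

test_that("ANOVA reductions: F = t squared at one timepoint, eps = 1 at two", {
  times <- c(0, 60)
  set.seed(5)
  ctrl <- array(c(rep(100, 4), 40 + rnorm(4, 0, 5)), dim = c(1, 4, 2))
  ko <- array(c(rep(100, 4), 75 + rnorm(4, 0, 5)), dim = c(1, 4, 2))
  cv <- curves_from_percent(list(control = ctrl, ko = ko), times)
  s1 <- stage1_screen(cv, c("control", "ko"))
  s2 <- stage2_rm_anova(cv, c("control", "ko"), include_t0 = FALSE)
  expect_lt(abs(s2$F_genotype / s1$t[1, "60"]^2 - 1), 1e-8)

  # two within-subject levels: sphericity is vacuous, eps exactly 1,
  # corrected p equals uncorrected p
  s2b <- stage2_rm_anova(cv, c("control", "ko"), include_t0 = TRUE)
  expect_identical(s2b$gg_epsilon, 1)
  expect_equal(s2b$p_interaction_gg, s2b$p_interaction)
})

test_that("GG epsilon stays in bounds and matches the Box oracle under
           compound symmetry", {
  box_eps <- function(S) {
    k <- nrow(S)
    sbar <- mean(S); d <- mean(diag(S))
    k^2 * (d - sbar)^2 /
      ((k - 1) * (sum(S^2) - 2 * k * sum(rowMeans(S)^2) + k^2 * sbar^2))
  }
  set.seed(99)
  k <- 5; n <- 4
  eps_mine <- eps_oracle <- numeric(200)
  for (r in 1:200) {
    # compound-symmetric covariance: subject intercept + iid noise
    mk <- function() matrix(rnorm(n, 0, 2), n, k) + matrix(rnorm(n * k), n, k)
    Y <- rbind(mk(), mk())
    grp <- rep(c("a", "b"), each = n)
    an <- rm_anova_gg(Y, grp)
    eps_mine[r] <- an$epsilon
    S <- (stats::cov(Y[1:n, ]) * (n - 1) + stats::cov(Y[-(1:n), ]) * (n - 1)) /
      (2 * n - 2)
    eps_oracle[r] <- min(max(box_eps(S), 1 / (k - 1)), 1)
    expect_gte(an$epsilon, 1 / (k - 1))
    expect_lte(an$epsilon, 1)
  }
  expect_equal(eps_mine, eps_oracle, tolerance = 1e-10)
  expect_lt(abs(mean(eps_mine) - mean(eps_oracle)), 0.05)
})

test_that("stage-2 gate calibrates near alpha under the null", {
  # exchangeable noise, no genotype effect: gate-term p roughly uniform
  set.seed(123)
  n_gene <- 400
  null_p <- numeric(n_gene)
  for (g in seq_len(n_gene)) {
    Y <- matrix(rnorm(8 * 4, 50, 5), 8, 4)
    null_p[g] <- rm_anova_gg(Y, rep(c("c", "k"), each = 4))$p_interaction_gg
  }
  rej <- mean(null_p < 0.05)
  expect_lt(rej, 0.10)
  expect_gt(mean(null_p), 0.35) # not degenerate
})

test_that("Sidak adjustment uses the number of post-anchor timepoints", {
  noisy <- noisy_decay_percents(3, 20, 120, seed = 6)
  cv <- curves_from_percent(noisy, default_grid)
  s1 <- stage1_screen(cv, c("control", "ko"))
  s2 <- stage2_rm_anova(cv, c("control", "ko"))
  m <- sum(default_grid > 0)
  expected <- apply(1 - (1 - s1$p)^m, 1, min)
  expect_equal(s2$min_sidak_p, unname(expected), tolerance = 1e-12)
  expect_true(all(s2$min_sidak_p >= apply(s1$p, 1, min)))
})

test_that("half-life interpolation and censoring behave as reported", {
  times <- default_grid
  hl <- estimate_half_life(times, 100 * exp(-log(2) / 20 * times))
  expect_false(hl$censored)
  expect_lt(abs(hl$halflife - 20), 1)

  flat <- estimate_half_life(times, rep(100, length(times)))
  expect_true(flat$censored)
  expect_equal(flat$halflife, 120)

  exact <- estimate_half_life(c(0, 20, 40), c(100, 50, 25))
  expect_equal(exact$halflife, 20)
  expect_false(exact$censored)

  # log-scale interpolation is exact for a pure exponential
  hlog <- estimate_half_life(times, 100 * exp(-log(2) / 20 * times),
                             log_scale = TRUE)
  expect_equal(hlog$halflife, 20, tolerance = 1e-12)
  expect_error(estimate_half_life(numeric(0), numeric(0)), "empty")
})

test_that("ranking orders by mean 60/120 difference with deterministic ties", {
  tab <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                    rank_metric = c(35, 45, 35, 10),
                    stabilized = c(TRUE, TRUE, TRUE, FALSE))
  r <- rank_stabilized(tab)
  expect_equal(r$gene_id, c("gB", "gA", "gC"))
})

test_that("full screen is invariant to gene and sample order", {
  cfg <- decay_sim_config(n_genes = 150, stabilized_fraction = 0.08,
                          stabilized_control_halflife = 20, seed = 77)
  e <- simulate_chase(cfg)$experiment
  res <- run_screen(e, pair = c("control", "ko"))

  set.seed(1)
  gi <- sample(nrow(e$counts)); si <- sample(ncol(e$counts))
  e2 <- chase_experiment(e$counts[gi, si],
                         e$gene_annotation[gi, ],
                         e$sample_sheet[si, ])
  res2 <- run_screen(e2, pair = c("control", "ko"))
  expect_setequal(res$table$gene_id[res$table$stabilized],
                  res2$table$gene_id[res2$table$stabilized])
  expect_setequal(res$filter_report$gene_id[res$filter_report$retained],
                  res2$filter_report$gene_id[res2$filter_report$retained])

  # output schema mirrors the published table layout
  expect_true(all(c("gene_id", "symbol", "has_ttp_site", "known_target",
                    paste0("ctrl_mean_t", default_grid),
                    paste0("ctrl_sd_t", default_grid),
                    paste0("ko_mean_t", default_grid),
                    paste0("ko_sd_t", default_grid),
                    paste0("t_test_p_t", default_grid[-1]),
                    "window_start_min", "p_genotype", "p_interaction_gg",
                    "gg_epsilon", "min_sidak_p", "rank_metric",
                    "half_life_control", "half_life_ko", "stabilized")
                  %in% names(res$table)))
})
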