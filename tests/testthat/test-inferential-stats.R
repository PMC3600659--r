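test_that("gg_epsilon matches Box's formula and its bounds", {
  # compound symmetry -> 1
  S_cs <- diag(4) * 2 + matrix(1, 4, 4)
  expect_equal(gg_epsilon(S_cs), 1)
  # hand oracle: Box's original double-sum formula
  S <- matrix(c(1, .5, .25, .5, 1, .5, .25, .5, 1), 3, 3)
  k <- 3
  sbar <- mean(S)
  sdiag <- mean(diag(S))
  srow <- rowMeans(S)
  eps_or <- (k^2 * (sdiag - sbar)^2) /
    ((k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2))
  expect_equal(gg_epsilon(S), eps_or, tolerance = 1e-10)
  # analytic lower bound 1/(k-1) for random PSD matrices
  set.seed(9)
  for (i in 1:10) {
    A <- matrix(rnorm(16), 4)
    S4 <- crossprod(A)
    e <- gg_epsilon(S4)
    expect_gte(e, 1 / 3)
    expect_lte(e, 1)
  }
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

# small balanced factory: n subjects per group, 4x4 within cells
sim_design <- function(n_per = 4, groups = c("A", "B", "C"),
                       noise = 1, seed = 1) {
  set.seed(seed)
  d <- expand.grid(id = seq_len(n_per * length(groups)),
                   phase = 1:4, block = 1:4)
  d$group <- rep(groups, each = n_per)[d$id]
  d$y <- rnorm(nrow(d), sd = noise)
  d
}

test_that("mixed_anova between-group F matches a hand-computed oracle", {
  d <- sim_design(seed = 3)
  sv <- rnorm(12) + rep(c(0, 1, 2), each = 4)[unique(d$id)]
  d$y <- sv[d$id] + rnorm(nrow(d), sd = 0.4)
  res <- mixed_anova(d, "y", c("phase", "block"), "group", "id")
  # SS-by-hand one-way ANOVA on subject means
  ym <- tapply(d$y, d$id, mean)
  g <- rep(c("A", "B", "C"), each = 4)
  gm <- tapply(ym, g, mean)
  ssb <- sum(4 * (gm - mean(ym))^2)
  ssw <- sum((ym - gm[g])^2)
  f_or <- (ssb / 2) / (ssw / 9)
  expect_equal(res$F[res$effect == "group"], f_or, tolerance = 1e-10)
  expect_equal(res$df_num[res$effect == "group"], 2)
  expect_equal(res$df_den[res$effect == "group"], 9)
})

test_that("mixed_anova agrees with stats::aov on a balanced design", {
  d <- sim_design(seed = 5)
  d$y <- d$y + 0.4 * d$phase + 0.2 * d$phase * (d$group == "B")
  res <- mixed_anova(d, "y", c("phase", "block"), "group", "id")
  d2 <- transform(d, id = factor(id), phase = factor(phase),
                  block = factor(block), group = factor(group))
  av <- summary(stats::aov(y ~ group * phase * block +
                             Error(id / (phase * block)), data = d2))
  pick <- function(stratum, row) av[[stratum]][[1]][row, "F value"]
  expect_equal(res$F[res$effect == "group"], pick("Error: id", "group"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "phase"],
               pick("Error: id:phase", "phase"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "phase:group"],
               pick("Error: id:phase", "group:phase"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "phase:block"],
               pick("Error: id:phase:block", "phase:block"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "phase:block:group"],
               pick("Error: id:phase:block", "group:phase:block"),
               tolerance = 1e-8)
})

test_that("group-effect p values are uniform under label permutation", {
  d <- sim_design(seed = 11)
  ids <- unique(d$id)
  set.seed(12)
  ps <- replicate(400, {
    gl <- sample(rep(c("A", "B", "C"), each = 4))
    d$group <- gl[d$id]
    res <- mixed_anova(d, "y", c("phase", "block"), "group", "id")
    res$p_uncorrected[res$effect == "group"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("mixed_anova is location invariant and rejects unbalanced data", {
  d <- sim_design(seed = 7)
  r1 <- mixed_anova(d, "y", c("phase", "block"), "group", "id")
  d2 <- d; d2$y <- d$y + 100
  r2 <- mixed_anova(d2, "y", c("phase", "block"), "group", "id")
  expect_equal(r1$F, r2$F, tolerance = 1e-8)
  expect_error(mixed_anova(d[-1, ], "y", c("phase", "block"), "group",
                           "id"),
               "unbalanced")
})

test_that("GG correction is Mauchly-gated and never anti-conservative", {
  set.seed(13)
  for (i in 1:6) {
    # strongly non-spherical within-covariance
    n <- 14
    d <- expand.grid(id = 1:n, phase = 1:4)
    d$group <- rep(c("A", "B"), each = n / 2)[d$id]
    lat <- rnorm(n)
    d$y <- rnorm(nrow(d), sd = 0.3) + lat[d$id] * d$phase
    res <- mixed_anova(d, "y", "phase", "group", "id")
    w <- res[res$effect == "phase", ]
    expect_gte(w$epsilon, 1 / 3)
    expect_lte(w$epsilon, 1)
    # adjusted p exceeds the unadjusted p wherever significance is in
    # play (for F < 1 shrinking both dfs can lower p, but such effects
    # are far from significant under either convention)
    if (w$F >= 1) expect_gte(w$p + 1e-15, w$p_uncorrected)
    if (w$gg_applied) {
      expect_lt(w$mauchly_p, 0.05)
      expect_equal(w$df_num_adj, w$df_num * w$epsilon)
    }
  }
})

test_that("ancova_rm calibrates and powers its covariate tests", {
  # null: covariate orthogonal to response -> p uniform over 300 sims
  set.seed(17)
  ps <- replicate(300, {
    n <- 12
    d <- expand.grid(id = 1:n, phase = 1:4)
    d$y <- rnorm(nrow(d))
    d$c1 <- rnorm(n)[d$id]
    d$c2 <- rnorm(n)[d$id]
    res <- ancova_rm(d, "y", "phase", c("c1", "c2"), "id")
    res$p[res$effect == "c1"]
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # power: linear covariate effect with small noise detected at n = 21
  set.seed(18)
  hits <- replicate(100, {
    n <- 21
    d <- expand.grid(id = 1:n, phase = 1:4)
    cv <- rnorm(n)
    d$c1 <- cv[d$id]
    d$c2 <- rnorm(n)[d$id]
    d$y <- 2 + 1.5 * d$c1 + rnorm(nrow(d), sd = 1)
    res <- ancova_rm(d, "y", "phase", c("c1", "c2"), "id")
    res$p[res$effect == "c1"] < 0.05
  })
  expect_gte(mean(hits), 0.95)
  # degenerate design: duplicated covariate
  n <- 10
  d <- expand.grid(id = 1:n, phase = 1:4)
  d$y <- rnorm(nrow(d)); d$c1 <- rnorm(n)[d$id]; d$c2 <- d$c1
  expect_error(ancova_rm(d, "y", "phase", c("c1", "c2"), "id"),
               "collinear")
})

test_that("posthoc pairwise t tests match the pooled-variance oracle", {
  set.seed(19)
  d <- data.frame(g = rep(c("A", "B", "C"), times = c(8, 7, 9)))
  d$y <- rnorm(nrow(d)) + (d$g == "C")
  ph <- posthoc(d, "y", "g", method = "bonferroni")
  expect_equal(nrow(ph), 3)
  a <- d$y[d$g == "A"]; b <- d$y[d$g == "B"]
  sp2 <- (7 * var(a) + 6 * var(b)) / 13
  t_or <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 7))
  row <- ph[ph$group1 == "A" & ph$group2 == "B", ]
  expect_equal(row$t, t_or, tolerance = 1e-12)
  expect_equal(row$df, 13)
  expect_equal(row$p_adjusted, min(1, 3 * row$p_raw))
  lsd <- posthoc(d, "y", "g", method = "lsd")
  expect_equal(lsd$p_adjusted, lsd$p_raw)
  # identical groups: t = 0, p = 1 exactly
  d2 <- data.frame(g = rep(c("A", "B"), each = 5),
                   y = rep(c(1, 2, 3, 4, 5), 2))
  ph2 <- posthoc(d2, "y", "g")
  expect_equal(ph2$t, 0)
  expect_equal(ph2$p_raw, 1)
})
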