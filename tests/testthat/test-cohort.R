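test_that("exposure composites follow the amount x frequency x duration rule", {
  e <- compute_exposure(2, 10, 24)
  expect_equal(e$intensity, 20)
  expect_equal(e$severity, 480)
  expect_equal(compute_exposure(3, 7, 0)$severity, 0)
  expect_equal(compute_exposure(3, 7, 0)$intensity, 21)
  expect_equal(compute_exposure(0, 9, 12)$intensity, 0)
  expect_equal(compute_exposure(0, 9, 12)$severity, 0)
  expect_error(compute_exposure(-1, 2, 3), "non-negative")
})

test_that("choice_policy has the softmax-lapse form", {
  p <- agent_params(beta = 4, lapse = 0, stickiness = 0)
  expect_equal(choice_policy(c(0.3, 0.3), NA, p), 0.5)
  p0 <- agent_params(beta = 0, lapse = 0)
  expect_equal(choice_policy(c(0.9, -0.9), NA, p0), 0.5)
  pl <- agent_params(beta = 10, lapse = 0.5)
  # maximal lapse bounds the policy within [lapse/2, 1 - lapse/2]
  expect_equal(choice_policy(c(1, -1), NA, pl),
               (1 - 0.5) / (1 + exp(-10 * 2)) + 0.25)
  expect_gte(choice_policy(c(-5, 5), NA, pl), 0.25)
  # stickiness biases toward the previous choice
  ps <- agent_params(beta = 5, lapse = 0, stickiness = 0.3)
  expect_gt(choice_policy(c(0, 0), 1, ps), 0.5)
  expect_lt(choice_policy(c(0, 0), 2, ps), 0.5)
})

test_that("update_values is the valence-asymmetric delta rule", {
  p <- agent_params(alpha_gain = 0.5, alpha_loss = 0)
  expect_equal(update_values(c(0, 0), 1, 1, p), c(0.5, 0))
  expect_equal(update_values(c(0.4, -0.2), 2, -1, p), c(0.4, -0.2))
  # repeated wins approach +1 monotonically
  v <- 0
  for (i in 1:50) {
    v_new <- update_values(c(v, 0), 1, 1, p)[1]
    expect_gt(v_new, v)
    v <- v_new
  }
  expect_lt(abs(v - 1), 1e-6)
})

test_that("sample_latency matches its closed form and lognormal mean oracle", {
  p0 <- agent_params(latency_base_ms = 600, latency_conflict_gain_ms = 200,
                     latency_intensity_gain_ms = 100, latency_sd_log = 0)
  expect_equal(sample_latency(p0, value_gap = 1, intensity_score = 0), 600)
  expect_equal(sample_latency(p0, value_gap = 0, intensity_score = 0), 800)
  l1 <- sample_latency(p0, 1, 0.2)
  l2 <- sample_latency(p0, 1, 0.8)
  expect_gt(l2, l1) # monotone in intensity at sd_log = 0
  # lognormal mean: E[latency] = mu * exp(sd^2 / 2)
  ps <- agent_params(latency_base_ms = 600, latency_conflict_gain_ms = 200,
                     latency_sd_log = 0.3)
  set.seed(42)
  draws <- sample_latency(ps, value_gap = 0.5, intensity_score = 0,
                          n = 1e4)
  mu <- 600 + 200 * 0.5
  expect_lt(abs(mean(draws) / (mu * exp(0.3^2 / 2)) - 1), 0.02)
})

test_that("make_cohort returns exact group sizes deterministically", {
  cohort <- quiet_cohort(cohort_config(), seed = 1)
  groups <- vapply(cohort, `[[`, "", "group")
  expect_equal(unname(table(groups)[c("HC", "PG", "CDI")]),
               c(23L, 21L, 20L),
               ignore_attr = TRUE)
  cohort2 <- quiet_cohort(cohort_config(), seed = 1)
  expect_identical(as.data.frame(cohort), as.data.frame(cohort2))
  expect_error(make_cohort(cohort_config(n_pg = 1)), "n_pg >= 2")
})

test_that("HC exposure is zero and clinical exposure is positive", {
  cohort <- quiet_cohort(cohort_config(), seed = 4)
  man <- as.data.frame(cohort)
  expect_true(all(man$severity[man$group == "HC"] == 0))
  expect_true(all(man$intensity[man$group != "HC"] > 0))
  expect_equal(man$intensity, man$amount * man$frequency)
  expect_equal(man$severity, man$intensity * man$duration)
})

test_that("zero effect slopes leave mapped parameters at baseline", {
  cc <- cohort_config(n_hc = 6, n_pg = 6, n_cdi = 6,
                      severity_lapse_slope = 0,
                      intensity_alpha_loss_slope = 0,
                      intensity_stickiness_slope = 0,
                      intensity_latency_slope_ms = 0)
  cohort <- quiet_cohort(cc, seed = 8)
  for (p in cohort) {
    expect_equal(p$agent$lapse, p$base_agent$lapse)
    expect_equal(p$agent$alpha_loss, p$base_agent$alpha_loss)
    expect_equal(p$agent$stickiness, p$base_agent$stickiness)
  }
})

test_that("effect maps are monotone in the exposure rank scores", {
  # no parameter jitter on lapse: lapse must then be non-decreasing in
  # the severity rank score within each clinical group
  cc <- cohort_config(param_jitter_sd = c(alpha_gain = 0.03,
                                          alpha_loss = 0.03, beta = 1.5,
                                          lapse = 0,
                                          latency_base_ms = 80))
  cohort <- quiet_cohort(cc, seed = 12)
  man <- as.data.frame(cohort)
  for (g in c("PG", "CDI")) {
    m <- man[man$group == g, ]
    o <- order(m$severity_score)
    expect_true(all(diff(m$lapse[o]) >= 0))
  }
})

test_that("simulate_participant reproduces the exported kernels exactly", {
  # oracle re-implementation using choice_policy / update_values /
  # play_trial with the same RNG consumption order
  cfg <- task_config()
  sched <- build_schedule(cfg, seed = 31)
  prof <- list(id = "P001", intensity_score = 0.4,
               agent = agent_params(alpha_gain = 0.3, alpha_loss = 0.2,
                                    beta = 5, lapse = 0.1,
                                    stickiness = 0.15,
                                    latency_intensity_gain_ms = 120,
                                    latency_sd_log = 0.2))
  log <- simulate_participant(prof, sched, seed = 77)

  par <- prof$agent
  set.seed(77)
  n <- nrow(sched)
  u <- runif(n)
  eps <- rnorm(n, 0, par$latency_sd_log)
  v <- c(0, 0); prev <- NA; st <- task_state()
  tokens <- cfg$option_tokens
  for (t in seq_len(n)) {
    p1 <- choice_policy(v, prev, par)
    ch <- if (u[t] < p1) 1L else 2L
    gap <- abs(v[1] - v[2])
    lat <- (par$latency_base_ms +
              par$latency_intensity_gain_ms * prof$intensity_score +
              par$latency_conflict_gain_ms * (1 - min(gap, 1))) *
      exp(eps[t])
    r <- play_trial(sched, st, tokens[ch])
    st <- r$state
    v <- update_values(v, ch, sign(r$feedback), par)
    expect_identical(log$chosen_option[t], tokens[ch])
    expect_equal(log$feedback_points[t], r$feedback)
    expect_equal(log$latency_ms[t], lat)
    prev <- ch
  }
  expect_equal(log$cumulative_points[n], st$points)
})

test_that("agents learn within phases and lapse = 1/2-at-ceiling is chance", {
  # learning curve rises: blocks 3-4 of phase 1 beat block 1
  prof <- list(id = "X", intensity_score = 0,
               agent = agent_params(alpha_gain = 0.5, alpha_loss = 0.5,
                                    beta = 10, lapse = 0))
  acc1 <- acc34 <- numeric(40)
  for (s in 1:40) {
    tl <- simulate_participant(prof, build_schedule(task_config(),
                                                    seed = s),
                               seed = s + 500)
    p1 <- tl[tl$phase == 1, ]
    acc1[s] <- sum(p1$accurate[p1$block == 1])
    acc34[s] <- mean(c(sum(p1$accurate[p1$block == 3]),
                       sum(p1$accurate[p1$block == 4])))
  }
  expect_gt(mean(acc34), mean(acc1))
  # maximal lapse: accuracy compatible with chance in every block
  prof$agent <- agent_params(lapse = 0.5, beta = 0)
  acc <- unlist(lapply(1:25, function(s) {
    tl <- simulate_participant(prof, build_schedule(task_config(),
                                                    seed = s),
                               seed = s + 900)
    tapply(tl$accurate, interaction(tl$phase, tl$block), sum)
  }))
  # 400 blocks of 10 at p = 0.5: mean within 4 binomial SEs
  expect_lt(abs(mean(acc) - 5), 4 * sqrt(0.25 * 10 / length(acc)))
})

test_that("low alpha_loss increases reversal cost (simulation oracle)", {
  fb_mean <- function(aloss, n = 120) {
    prof <- list(id = "X", intensity_score = 0,
                 agent = agent_params(alpha_loss = aloss))
    mean(vapply(seq_len(n), function(s) {
      tl <- simulate_participant(prof,
                                 build_schedule(task_config(), seed = s),
                                 seed = s + 2000)
      tab <- tabulate_blocks(tl)
      mean(reversal_cost_scores(tab)[2:4])
    }, numeric(1)))
  }
  expect_lt(fb_mean(0.1), fb_mean(0.9))
})

test_that("null-effect cohorts are exchangeable across groups", {
  cc <- cohort_config(n_hc = 8, n_pg = 8, n_cdi = 8,
                      severity_lapse_slope = 0,
                      intensity_alpha_loss_slope = 0,
                      intensity_stickiness_slope = 0,
                      intensity_latency_slope_ms = 0)
  cohort <- quiet_cohort(cc, seed = 5)
  d <- derived_measures(cohort, seed = 55)
  # permutation test on the between-group spread of mean asymptote
  stat <- function(g) {
    m <- tapply(d$asymptote, g, mean)
    max(m) - min(m)
  }
  obs <- stat(d$group)
  set.seed(99)
  perm <- replicate(400, stat(sample(d$group)))
  p <- (1 + sum(perm >= obs)) / (1 + length(perm))
  expect_gt(p, 0.01)
})
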