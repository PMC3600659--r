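# Synthetic cohort: exposure covariates, reinforcement-learning agents,
# and decision latencies. The agent is a stand-in for participants (the
# behavioural study fits no model); its parameters carry the exposure
# effects reported for real cohorts: cocaine-use severity suppresses the
# learning asymptote (via lapse), gambling intensity raises reversal cost
# (via a reduced loss learning rate) and slows decisions (via a latency
# slope).

#' Exposure composite measures from interview triples
#'
#' Computes the two composite exposure measures used for addictive
#' behaviours: `intensity = amount * frequency` (per-month exposure) and
#' `severity = amount * frequency * duration` (estimated lifetime
#' exposure). Vectorised.
#'
#' @param amount Average amount consumed/gambled per episode (grams or
#'   units); non-negative.
#' @param frequency Average episodes per month; non-negative.
#' @param duration Total duration of the usage period in months;
#'   non-negative.
#' @return A data frame with columns `amount`, `frequency`, `duration`,
#'   `intensity`, `severity`.
#' @export
#' @examples
#' compute_exposure(2, 10, 24) # intensity 20, severity 480
compute_exposure <- function(amount, frequency, duration) {
  if (any(!is.finite(c(amount, frequency, duration))) ||
      any(c(amount, frequency, duration) < 0)) {
    stop("exposure inputs must be finite and non-negative")
  }
  n <- max(length(amount), length(frequency), length(duration))
  amount <- rep_len(amount, n)
  frequency <- rep_len(frequency, n)
  duration <- rep_len(duration, n)
  data.frame(amount = amount, frequency = frequency, duration = duration,
             intensity = amount * frequency,
             severity = amount * frequency * duration)
}

#' Reinforcement-learning agent parameters
#'
#' A two-option delta-rule learner with valence-asymmetric learning rates,
#' softmax choice with choice stickiness and a lapse (uniform-choice)
#' probability, and a lognormal decision-latency model.
#'
#' @param alpha_gain Learning rate for positive feedback, in `[0, 1]`.
#' @param alpha_loss Learning rate for negative feedback, in `[0, 1]`.
#' @param beta Softmax inverse temperature, `>= 0`.
#' @param lapse Probability of a uniform random choice, in `[0, 0.5]`.
#' @param stickiness Additive value bonus for repeating the previous
#'   choice.
#' @param latency_base_ms Baseline of the latency model (ms), `> 0`.
#' @param latency_conflict_gain_ms Latency increase (ms) at maximal choice
#'   conflict (value gap 0).
#' @param latency_intensity_gain_ms Latency increase (ms) per unit of the
#'   intensity rank score (which spans (0, 1) within a group).
#' @param latency_sd_log SD of the multiplicative lognormal latency noise.
#' @return An object of class `prlt_agent_params` (a named list).
#' @export
agent_params <- function(alpha_gain = 0.15, alpha_loss = 0.95, beta = 15,
                         lapse = 0.02, stickiness = 0.02,
                         latency_base_ms = 650,
                         latency_conflict_gain_ms = 250,
                         latency_intensity_gain_ms = 0,
                         latency_sd_log = 0.25) {
  p <- list(alpha_gain = alpha_gain, alpha_loss = alpha_loss, beta = beta,
            lapse = lapse, stickiness = stickiness,
            latency_base_ms = latency_base_ms,
            latency_conflict_gain_ms = latency_conflict_gain_ms,
            latency_intensity_gain_ms = latency_intensity_gain_ms,
            latency_sd_log = latency_sd_log)
  stopifnot(all(vapply(p, function(z)
    is.numeric(z) && length(z) == 1L && is.finite(z), logical(1))))
  if (alpha_gain < 0 || alpha_gain > 1 || alpha_loss < 0 || alpha_loss > 1)
    stop("learning rates must lie in [0, 1]")
  if (beta < 0) stop("`beta` must be non-negative")
  if (lapse < 0 || lapse > 0.5) stop("`lapse` must lie in [0, 0.5]")
  if (latency_base_ms <= 0) stop("`latency_base_ms` must be positive")
  if (latency_sd_log < 0) stop("`latency_sd_log` must be non-negative")
  structure(p, class = "prlt_agent_params")
}

#' Softmax choice policy with stickiness and lapse
#'
#' Probability of choosing option 1 given the two option values:
#' `P = (1 - lapse) * softmax(beta * (V + stickiness * prev)) + lapse / 2`,
#' where `prev` adds the stickiness bonus to the previously chosen option.
#'
#' @param values Numeric length-2 option values.
#' @param previous_choice 1, 2, or `NA`/0 for no previous choice.
#' @param params An [agent_params()].
#' @return Probability of choosing option 1, in
#'   `[lapse/2, 1 - lapse/2]`.
#' @export
choice_policy <- function(values, previous_choice, params) {
  stopifnot(inherits(params, "prlt_agent_params"),
            length(values) == 2L, all(is.finite(values)))
  u <- values
  if (!is.na(previous_choice) && previous_choice %in% c(1, 2)) {
    u[previous_choice] <- u[previous_choice] + params$stickiness
  }
  p_soft <- 1 / (1 + exp(-params$beta * (u[1] - u[2])))
  (1 - params$lapse) * p_soft + params$lapse / 2
}

#' Valence-asymmetric delta-rule value update
#'
#' `V[chosen] <- V[chosen] + alpha * (reward - V[chosen])` with
#' `alpha = alpha_gain` for `reward = +1` and `alpha_loss` for
#' `reward = -1`; the unchosen value is unchanged.
#'
#' @param values Numeric length-2 option values.
#' @param chosen Index (1 or 2) of the chosen option.
#' @param reward Normalised reward, `+1` or `-1`.
#' @param params An [agent_params()].
#' @return Updated values.
#' @export
update_values <- function(values, chosen, reward, params) {
  stopifnot(inherits(params, "prlt_agent_params"),
            chosen %in% c(1L, 2L), reward %in% c(-1, 1))
  alpha <- if (reward > 0) params$alpha_gain else params$alpha_loss
  values[chosen] <- values[chosen] + alpha * (reward - values[chosen])
  values
}

#' Sample a decision latency
#'
#' `latency = (base + conflict_gain * (1 - value_gap) +
#' intensity_gain * intensity_score) * exp(eps)`, `eps ~ N(0, sd_log)`.
#' Larger choice conflict (small value gap) and larger exposure intensity
#' both slow decisions.
#'
#' @param params An [agent_params()].
#' @param value_gap Absolute value difference `|V1 - V2|`, `>= 0`; values
#'   live in `[-1, 1]`, so gaps above 1 are clamped to 1 for the conflict
#'   term.
#' @param intensity_score Within-group intensity rank score in `[0, 1]`
#'   (0 for unexposed participants).
#' @param n Number of draws.
#' @return Latency draw(s) in ms, strictly positive.
#' @export
sample_latency <- function(params, value_gap, intensity_score = 0, n = 1L) {
  stopifnot(inherits(params, "prlt_agent_params"), value_gap >= 0,
            intensity_score >= 0)
  mu <- params$latency_base_ms +
    params$latency_conflict_gain_ms * (1 - min(value_gap, 1)) +
    params$latency_intensity_gain_ms * intensity_score
  if (mu <= 0) stop("latency mean term must be strictly positive")
  mu * exp(rnorm(n, 0, params$latency_sd_log))
}

#' Synthetic cohort configuration
#'
#' Group sizes default to 23 healthy controls (HC), 21 pathological
#' gamblers (PG) and 20 cocaine-dependent individuals (CDI). Exposure
#' triples (amount per episode, episodes/month, months of use) are drawn
#' from lognormal distributions; effects enter the agent through
#' within-group exposure rank scores `u = (rank - 0.5) / n` in (0, 1):
#'
#' * `lapse = lapse + severity_lapse_slope * u_severity` (asymptote
#'   suppression),
#' * `alpha_loss = alpha_loss + intensity_alpha_loss_slope * u_intensity`
#'   and `stickiness = stickiness + intensity_stickiness_slope *
#'   u_intensity` (reversal-cost increase: slower loss unlearning plus
#'   choice perseveration),
#' * `latency_intensity_gain_ms = intensity_latency_slope_ms` applied to
#'   `u_intensity` (decision slowing).
#'
#' Mapped parameters are clipped into their legal ranges with a warning.
#'
#' @param n_hc,n_pg,n_cdi Group sizes (each `>= 2`).
#' @param base Baseline [agent_params()] shared by all groups.
#' @param param_jitter_sd Named numeric: between-participant SD of
#'   `alpha_gain`, `alpha_loss`, `beta` and `lapse` around the baseline
#'   (drawn identically in every group, before effect mapping).
#' @param exposure_pg,exposure_cdi Named lists with `meanlog`/`sdlog`
#'   length-3 vectors for (amount, frequency, duration).
#' @param severity_lapse_slope Lapse increase across the within-group
#'   severity rank range.
#' @param intensity_alpha_loss_slope Change in `alpha_loss` across the
#'   intensity rank range (negative by default).
#' @param intensity_stickiness_slope Change in choice stickiness across
#'   the intensity rank range (positive: perseveration).
#' @param intensity_latency_slope_ms Latency increase (ms) across the
#'   intensity rank range.
#' @param frn_differential Named numeric, mean differential FRN (uV, PF
#'   minus NF component) per group.
#' @param frn_differential_sd Between-participant SD of the differential.
#' @return An object of class `prlt_cohort_config`.
#' @export
cohort_config <- function(n_hc = 23L, n_pg = 21L, n_cdi = 20L,
                          base = agent_params(),
                          param_jitter_sd = c(alpha_gain = 0.03,
                                              alpha_loss = 0.03,
                                              beta = 1.5, lapse = 0.01,
                                              latency_base_ms = 80),
                          exposure_pg = list(
                            meanlog = log(c(30, 12, 84)),
                            sdlog = c(0.8, 0.6, 1.5)),
                          exposure_cdi = list(
                            meanlog = log(c(1, 10, 120)),
                            sdlog = c(0.7, 0.7, 1.2)),
                          severity_lapse_slope = 0.40,
                          intensity_alpha_loss_slope = -0.87,
                          intensity_stickiness_slope = 0.05,
                          intensity_latency_slope_ms = 350,
                          frn_differential = c(HC = 3.0, PG = 1.5,
                                               CDI = 2.2),
                          frn_differential_sd = 0.8) {
  stopifnot(n_hc >= 2L, n_pg >= 2L, n_cdi >= 2L,
            is.finite(severity_lapse_slope),
            is.finite(intensity_alpha_loss_slope),
            is.finite(intensity_stickiness_slope),
            is.finite(intensity_latency_slope_ms),
            inherits(base, "prlt_agent_params"),
            all(c("HC", "PG", "CDI") %in% names(frn_differential)))
  structure(list(
    n_hc = as.integer(n_hc), n_pg = as.integer(n_pg),
    n_cdi = as.integer(n_cdi),
    base = base, param_jitter_sd = param_jitter_sd,
    exposure_pg = exposure_pg, exposure_cdi = exposure_cdi,
    severity_lapse_slope = severity_lapse_slope,
    intensity_alpha_loss_slope = intensity_alpha_loss_slope,
    intensity_stickiness_slope = intensity_stickiness_slope,
    intensity_latency_slope_ms = intensity_latency_slope_ms,
    frn_differential = frn_differential,
    frn_differential_sd = frn_differential_sd),
    class = "prlt_cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws exposure records and agent parameters for every participant.
#' Baseline agent parameters are drawn from the same jittered
#' distributions in all groups; exposure effects are then added through
#' the rank-score effect maps, so setting all slopes to zero makes the
#' groups exchangeable.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return A list of participant profiles (class `prlt_cohort`); each
#'   profile has `id`, `group`, `exposure` (one-row data frame),
#'   `intensity_score`/`severity_score` (rank scores), `agent`
#'   ([agent_params()]), `base_agent`, and `erp` (FRN effect parameters).
#'   Use [as.data.frame()] for the cohort manifest.
#' @export
#' @examples
#' cohort <- make_cohort(cohort_config(), seed = 1)
#' table(vapply(cohort, `[[`, "", "group"))
make_cohort <- function(config, seed) {
  stopifnot(inherits(config, "prlt_cohort_config"))
  with_seed(seed, {
    groups <- rep(c("HC", "PG", "CDI"),
                  times = c(config$n_hc, config$n_pg, config$n_cdi))
    n <- length(groups)
    ids <- sprintf("P%03d", seq_len(n))
    js <- config$param_jitter_sd
    base <- config$base

    # baseline params: identical generative process in every group
    ag <- clip(rnorm(n, base$alpha_gain, js[["alpha_gain"]]), 0.01, 1)
    al0 <- rnorm(n, base$alpha_loss, js[["alpha_loss"]])
    bt <- clip(rnorm(n, base$beta, js[["beta"]]), 0.5, 50)
    lp0 <- rnorm(n, base$lapse, js[["lapse"]])
    lat_base <- clip(rnorm(n, base$latency_base_ms,
                           js[["latency_base_ms"]]), 200, Inf)

    # exposure triples per group
    exposure <- data.frame(amount = numeric(n), frequency = numeric(n),
                           duration = numeric(n))
    for (g in c("PG", "CDI")) {
      idx <- which(groups == g)
      d <- if (g == "PG") config$exposure_pg else config$exposure_cdi
      exposure$amount[idx] <- rlnorm(length(idx), d$meanlog[1], d$sdlog[1])
      exposure$frequency[idx] <- rlnorm(length(idx), d$meanlog[2],
                                        d$sdlog[2])
      exposure$duration[idx] <- rlnorm(length(idx), d$meanlog[3],
                                       d$sdlog[3])
    }
    exposure <- compute_exposure(exposure$amount, exposure$frequency,
                                 exposure$duration)

    # within-group rank scores in (0, 1); zero for HC (no exposure)
    int_score <- sev_score <- numeric(n)
    for (g in c("PG", "CDI")) {
      idx <- which(groups == g)
      int_score[idx] <- (rank(exposure$intensity[idx]) - 0.5) / length(idx)
      sev_score[idx] <- (rank(exposure$severity[idx]) - 0.5) / length(idx)
    }

    lapse <- clip(lp0 + config$severity_lapse_slope * sev_score,
                  0, 0.5, warn_label = "lapse")
    # floor at 0.08: below it the delta rule's reversal behaviour becomes
    # non-monotone (punished options retain value, shrinking the
    # end-of-phase value gap and paradoxically easing reversals)
    alpha_loss <- clip(al0 + config$intensity_alpha_loss_slope * int_score,
                       0.08, 1, warn_label = "alpha_loss")
    stickiness <- clip(base$stickiness +
                         config$intensity_stickiness_slope * int_score,
                       0, 2, warn_label = "stickiness")
    frn_mu <- config$frn_differential[groups]
    frn_diff <- rnorm(n, frn_mu, config$frn_differential_sd)

    cohort <- vector("list", n)
    for (i in seq_len(n)) {
      agent <- agent_params(
        alpha_gain = ag[i], alpha_loss = alpha_loss[i], beta = bt[i],
        lapse = lapse[i], stickiness = stickiness[i],
        latency_base_ms = lat_base[i],
        latency_conflict_gain_ms = base$latency_conflict_gain_ms,
        latency_intensity_gain_ms = config$intensity_latency_slope_ms,
        latency_sd_log = base$latency_sd_log)
      base_agent <- agent
      base_agent$alpha_loss <- clip(al0[i], 0.08, 1)
      base_agent$lapse <- clip(lp0[i], 0, 0.5)
      base_agent$stickiness <- base$stickiness
      cohort[[i]] <- list(
        id = ids[i], group = groups[i],
        exposure = exposure[i, , drop = FALSE],
        intensity_score = int_score[i], severity_score = sev_score[i],
        agent = agent, base_agent = base_agent,
        erp = list(frn_differential = frn_diff[i]))
    }
    class(cohort) <- "prlt_cohort"
    cohort
  })
}

#' @export
print.prlt_cohort <- function(x, ...) {
  tab <- table(vapply(x, `[[`, "", "group"))
  cat("PRLT synthetic cohort:", length(x), "participants (",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

#' Cohort manifest as a data frame
#'
#' @param x A `prlt_cohort`.
#' @param ... Unused.
#' @return One row per participant: id, group, exposure triple and
#'   composites, rank scores, and mapped agent parameters.
#' @export
as.data.frame.prlt_cohort <- function(x, ...) {
  do.call(rbind, lapply(x, function(p) {
    cbind(data.frame(participant_id = p$id, group = p$group,
                     stringsAsFactors = FALSE),
          p$exposure,
          data.frame(intensity_score = p$intensity_score,
                     severity_score = p$severity_score,
                     alpha_gain = p$agent$alpha_gain,
                     alpha_loss = p$agent$alpha_loss,
                     beta = p$agent$beta, lapse = p$agent$lapse,
                     stickiness = p$agent$stickiness,
                     frn_differential = p$erp$frn_differential))
  }))
}

#' Simulate one participant on a PRLT schedule
#'
#' Runs the agent over the schedule: softmax choice with stickiness and
#' lapse, valence-asymmetric delta-rule updates on normalised +/-1
#' feedback, and lognormal latencies. Option values start at 0 and are
#' *not* reset at reversals, so reversal cost emerges from relearning.
#'
#' The trial loop inlines the arithmetic of [choice_policy()],
#' [update_values()] and [sample_latency()] for speed; equivalence is
#' enforced by tests.
#'
#' @param profile One element of a [make_cohort()] result.
#' @param schedule A [build_schedule()] result.
#' @param seed Integer seed.
#' @return A data frame of trial records: `participant_id`, `phase`,
#'   `trial`, `block`, `correct_option`, `chosen_option`, `accurate`,
#'   `veridical`, `feedback_points`, `cumulative_points`, `latency_ms`.
#' @export
simulate_participant <- function(profile, schedule, seed) {
  stopifnot(inherits(schedule, "prlt_schedule"))
  config <- attr(schedule, "config")
  par <- profile$agent
  tokens <- config$option_tokens
  n <- nrow(schedule)
  correct_idx <- match(schedule$correct_option, tokens)
  veridical <- schedule$veridical
  pts <- config$points_per_feedback
  int_score <- if (is.null(profile$intensity_score)) 0 else
    profile$intensity_score
  lat_mu_fixed <- par$latency_base_ms +
    par$latency_intensity_gain_ms * int_score

  with_seed(seed, {
    u_choice <- runif(n)
    eps_lat <- rnorm(n, 0, par$latency_sd_log)
    v <- c(0, 0)
    prev <- 0L
    chosen <- integer(n)
    accurate <- logical(n)
    feedback <- numeric(n)
    cumpts <- numeric(n)
    latency <- numeric(n)
    total <- 0
    for (t in seq_len(n)) {
      u1 <- v[1]; u2 <- v[2]
      if (prev == 1L) u1 <- u1 + par$stickiness
      else if (prev == 2L) u2 <- u2 + par$stickiness
      p1 <- (1 - par$lapse) / (1 + exp(-par$beta * (u1 - u2))) +
        par$lapse / 2
      ch <- if (u_choice[t] < p1) 1L else 2L
      gap <- abs(v[1] - v[2])
      latency[t] <- (lat_mu_fixed +
                       par$latency_conflict_gain_ms * (1 - min(gap, 1))) *
        exp(eps_lat[t])
      acc <- ch == correct_idx[t]
      rewarded <- acc == veridical[t]
      r <- if (rewarded) 1 else -1
      feedback[t] <- r * pts
      total <- total + feedback[t]
      cumpts[t] <- total
      alpha <- if (r > 0) par$alpha_gain else par$alpha_loss
      v[ch] <- v[ch] + alpha * (r - v[ch])
      chosen[t] <- ch
      accurate[t] <- acc
      prev <- ch
    }
    data.frame(
      participant_id = if (is.null(profile$id)) "P000" else profile$id,
      phase = schedule$phase, trial = schedule$trial,
      block = schedule$block,
      correct_option = schedule$correct_option,
      chosen_option = tokens[chosen],
      accurate = accurate, veridical = veridical,
      feedback_points = feedback, cumulative_points = cumpts,
      latency_ms = latency, stringsAsFactors = FALSE)
  })
}

#' Simulate a whole cohort on the PRLT
#'
#' Builds one schedule per participant (contingency order balanced within
#' each group: alternating easy-late / easy-early) and runs the agent.
#'
#' @param cohort A [make_cohort()] result.
#' @param task A [task_config()]; its `contingency_order` is overridden by
#'   the balancing scheme unless `balance_order = FALSE`.
#' @param seed Integer seed.
#' @param balance_order Alternate the two contingency orders within each
#'   group (default `TRUE`).
#' @return A data frame of trial records for the whole cohort.
#' @export
simulate_cohort <- function(cohort, task = task_config(), seed,
                            balance_order = TRUE) {
  stopifnot(inherits(cohort, "prlt_cohort"))
  groups <- vapply(cohort, `[[`, "", "group")
  orders <- rep("easy-late", length(cohort))
  if (balance_order && task$n_phases == 4L) {
    for (g in unique(groups)) {
      idx <- which(groups == g)
      orders[idx] <- rep(c("easy-late", "easy-early"),
                         length.out = length(idx))
    }
  }
  logs <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    cfg_i <- task_config(n_phases = task$n_phases,
                         trials_per_phase = task$trials_per_phase,
                         block_size = task$block_size,
                         contingency_order = orders[i],
                         points_per_feedback = task$points_per_feedback,
                         option_tokens = task$option_tokens)
    sched <- build_schedule(cfg_i, seed = derive_seed(seed,
                                                      paste0("sched.", i)))
    logs[[i]] <- simulate_participant(cohort[[i]], sched,
                                      seed = derive_seed(seed,
                                                         paste0("agent.", i)))
  }
  do.call(rbind, logs)
}
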