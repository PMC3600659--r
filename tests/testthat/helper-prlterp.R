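# Shared fixtures, all built in code.

# Play a whole schedule with a fixed strategy; returns feedback signs and
# accuracy per trial.
play_strategy <- function(schedule, strategy = c("correct", "wrong")) {
  strategy <- match.arg(strategy)
  cfg <- attr(schedule, "config")
  st <- task_state()
  fb <- numeric(nrow(schedule))
  for (t in seq_len(nrow(schedule))) {
    ch <- schedule$correct_option[t]
    if (strategy == "wrong") ch <- setdiff(cfg$option_tokens, ch)
    r <- play_trial(schedule, st, ch)
    fb[t] <- r$feedback
    st <- r$state
  }
  list(feedback = fb, points = st$points)
}

# Standard 250 Hz sample grid from -200 to +348 ms.
grid_times <- function() seq(-200, 348, by = 4)

# Piecewise-constant waveform on the grid: `pieces` is a list of
# c(lo, hi, value); later pieces overwrite earlier ones; 0 elsewhere.
pw_wave <- function(pieces, times = grid_times()) {
  w <- numeric(length(times))
  for (p in pieces) w[times >= p[1] & times <= p[2]] <- p[3]
  w
}

# Epoch set built from a list of channel x sample matrices (one per
# epoch) or a single matrix recycled.
make_epochs <- function(mats, condition, channels = c("Fz", "FCz", "Pz"),
                        times = grid_times(), srate = 250) {
  if (is.matrix(mats)) mats <- rep(list(mats), length(condition))
  amp <- array(0, dim = c(length(channels), length(times), length(mats)))
  for (e in seq_along(mats)) amp[, , e] <- mats[[e]]
  epoch_set(amp, times = times, channels = channels,
            condition = condition, srate = srate)
}

# One-channel epoch set from per-epoch waveform vectors.
make_epochs_1ch <- function(waves, condition, times = grid_times()) {
  amp <- array(0, dim = c(1, length(times), length(waves)))
  for (e in seq_along(waves)) amp[1, , e] <- waves[[e]]
  epoch_set(amp, times = times, channels = "FCz",
            condition = condition, srate = 250)
}

# A small cohort with warnings (parameter clipping) silenced.
quiet_cohort <- function(config, seed) {
  suppressWarnings(make_cohort(config, seed))
}

# Subset a cohort by group, preserving the class.
cohort_group <- function(cohort, group) {
  out <- cohort[vapply(cohort, `[[`, "", "group") == group]
  class(out) <- "prlt_cohort"
  out
}

# Per-participant derived behavioural measures used by recovery tests.
derived_measures <- function(cohort, seed, task = task_config()) {
  man <- as.data.frame(cohort)
  tl <- simulate_cohort(cohort, task, seed = seed)
  mets <- cohort_metrics(tl, block_size = task$block_size)
  per <- do.call(rbind, lapply(man$participant_id, function(id) {
    m <- mets[mets$participant_id == id & mets$block == 1, ]
    data.frame(participant_id = id,
               reversal_cost = mean(m$first_block[m$phase >= 2]),
               asymptote = sum(m$last_two_blocks),
               latency = mean(mets$latency_ms[mets$participant_id == id]))
  }))
  merge(man, per, by = "participant_id")
}
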