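# PRLT task engine: phase/reversal structure, exact-count false-feedback
# scheduling, and point accounting.
#
# Conventions (documented in trial logs as well): trials, phases and blocks
# are 1-based; `veridical = TRUE` means the feedback matched the accuracy
# of the choice; feedback is +points for (accurate AND veridical) or
# (inaccurate AND NOT veridical), -points otherwise.

#' PRLT task configuration
#'
#' Defines the structure of the probabilistic reversal learning task: four
#' 40-trial phases whose correct option reverses at every phase boundary,
#' 10-trial scoring blocks, and a reward contingency per phase. Feedback is
#' occasionally false: in a phase with contingency `p`, exactly
#' `round(p * trials_per_phase)` trials are veridical.
#'
#' @param n_phases Number of phases (default 4).
#' @param trials_per_phase Trials per phase (default 40); must be divisible
#'   by `block_size`.
#' @param block_size Trials per scoring block (default 10).
#' @param contingency_order Either one of `"easy-late"`
#'   (`c(0.75, 0.75, 0.875, 0.875)`) or `"easy-early"`
#'   (`c(0.875, 0.875, 0.75, 0.75)`), or a numeric vector of length
#'   `n_phases` with values in (0.5, 1) such that `p * trials_per_phase`
#'   is an integer.
#' @param points_per_feedback Points won/lost per feedback event (default 5).
#' @param option_tokens Length-2 character vector of colour tokens naming
#'   the two response options.
#' @return An object of class `prlt_task_config`.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$contingencies
task_config <- function(n_phases = 4L,
                        trials_per_phase = 40L,
                        block_size = 10L,
                        contingency_order = "easy-late",
                        points_per_feedback = 5,
                        option_tokens = c("blue", "green")) {
  n_phases <- as.integer(n_phases)
  trials_per_phase <- as.integer(trials_per_phase)
  block_size <- as.integer(block_size)
  stopifnot(n_phases >= 1L, trials_per_phase >= 1L, block_size >= 1L,
            points_per_feedback > 0,
            is.character(option_tokens), length(option_tokens) == 2L,
            !anyDuplicated(option_tokens))
  if (trials_per_phase %% block_size != 0L) {
    stop("`trials_per_phase` must be divisible by `block_size`")
  }
  if (is.character(contingency_order)) {
    contingency_order <- match.arg(contingency_order,
                                   c("easy-late", "easy-early"))
    p <- switch(contingency_order,
                "easy-late" = c(0.75, 0.75, 0.875, 0.875),
                "easy-early" = c(0.875, 0.875, 0.75, 0.75))
    if (n_phases != 4L) stop("named contingency orders require 4 phases")
    order_label <- contingency_order
  } else {
    p <- as.numeric(contingency_order)
    order_label <- "custom"
    if (length(p) != n_phases) {
      stop("`contingency_order` must have one contingency per phase")
    }
  }
  if (any(p <= 0.5 | p >= 1)) {
    stop("contingencies must lie strictly between 0.5 and 1")
  }
  n_ver <- p * trials_per_phase
  if (any(abs(n_ver - round(n_ver)) > 1e-8)) {
    stop("each contingency times `trials_per_phase` must be an integer ",
         "(exact-count scheduling)")
  }
  structure(
    list(n_phases = n_phases,
         trials_per_phase = trials_per_phase,
         block_size = block_size,
         n_blocks = trials_per_phase %/% block_size,
         contingencies = p,
         order_label = order_label,
         points_per_feedback = points_per_feedback,
         option_tokens = option_tokens),
    class = "prlt_task_config")
}

#' @export
print.prlt_task_config <- function(x, ...) {
  cat("PRLT task configuration\n")
  cat(sprintf("  %d phases x %d trials (%d blocks of %d)\n",
              x$n_phases, x$trials_per_phase, x$n_blocks, x$block_size))
  cat(sprintf("  contingencies (%s): %s\n", x$order_label,
              paste(x$contingencies, collapse = ", ")))
  cat(sprintf("  feedback: +/-%g points; options: %s\n",
              x$points_per_feedback, paste(x$option_tokens, collapse = "/")))
  invisible(x)
}

#' Build a PRLT trial schedule
#'
#' Pre-schedules the whole task for one participant: the correct-option
#' identity (flipping at every phase boundary and nowhere else), the exact
#' per-phase placement of veridical vs. false-feedback trials, and a
#' balanced-random left/right position bit.
#'
#' The veridical flag is a property of the trial: whichever option is
#' chosen, feedback is truthful on veridical trials and inverted on false
#' ones, which makes the schedule choice-independent.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A data frame of class `prlt_schedule` with one row per trial:
#'   `phase`, `trial` (global, 1-based), `trial_in_phase`, `block` (within
#'   phase), `correct_option`, `veridical`, `correct_on_left`.
#' @export
#' @examples
#' sched <- build_schedule(task_config(), seed = 1)
#' table(sched$phase, sched$veridical)
build_schedule <- function(config, seed) {
  stopifnot(inherits(config, "prlt_task_config"))
  with_seed(seed, {
    tpp <- config$trials_per_phase
    first_correct <- sample(config$option_tokens, 1L)
    other <- setdiff(config$option_tokens, first_correct)
    # alternate correct identity across phases
    correct_by_phase <- rep(c(first_correct, other),
                            length.out = config$n_phases)
    phase <- rep(seq_len(config$n_phases), each = tpp)
    trial_in_phase <- rep(seq_len(tpp), times = config$n_phases)
    veridical <- logical(config$n_phases * tpp)
    left <- logical(config$n_phases * tpp)
    for (ph in seq_len(config$n_phases)) {
      idx <- which(phase == ph)
      n_ver <- as.integer(round(config$contingencies[ph] * tpp))
      v <- c(rep(TRUE, n_ver), rep(FALSE, tpp - n_ver))
      veridical[idx] <- sample(v)
      # balanced-random position: correct option left on half the trials
      n_left <- tpp %/% 2L
      l <- c(rep(TRUE, n_left), rep(FALSE, tpp - n_left))
      left[idx] <- sample(l)
    }
    out <- data.frame(
      phase = phase,
      trial = seq_along(phase),
      trial_in_phase = trial_in_phase,
      block = (trial_in_phase - 1L) %/% config$block_size + 1L,
      correct_option = correct_by_phase[phase],
      veridical = veridical,
      correct_on_left = left,
      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("prlt_schedule", "data.frame")
    out
  })
}

#' Initial task state for [play_trial()]
#'
#' @return A list with `cursor` (next trial, 1-based) and `points`
#'   (cumulative score).
#' @export
task_state <- function() list(cursor = 1L, points = 0)

#' Play one PRLT trial
#'
#' Resolves the feedback for a choice at the current schedule cursor and
#' updates the cumulative point count. Feedback is `+points` iff the choice
#' accuracy matches the trial's veridical flag (accurate & veridical, or
#' inaccurate & false), `-points` otherwise.
#'
#' @param schedule A [build_schedule()] result.
#' @param state State list from [task_state()] or a previous call.
#' @param choice Option token chosen on this trial.
#' @return A list with `feedback` (signed points), `accurate` (logical),
#'   `veridical`, and the updated `state`.
#' @export
play_trial <- function(schedule, state, choice) {
  stopifnot(inherits(schedule, "prlt_schedule"))
  config <- attr(schedule, "config")
  if (state$cursor > nrow(schedule)) {
    stop("schedule exhausted: no trials left to play")
  }
  if (!choice %in% config$option_tokens) {
    stop(sprintf("unknown option token '%s'", choice))
  }
  row <- schedule[state$cursor, ]
  accurate <- identical(choice, row$correct_option)
  rewarded <- accurate == row$veridical
  feedback <- if (rewarded) config$points_per_feedback else
    -config$points_per_feedback
  state$points <- state$points + feedback
  state$cursor <- state$cursor + 1L
  list(feedback = feedback, accurate = accurate,
       veridical = row$veridical, state = state)
}

#' Write / read a task configuration as YAML
#'
#' @param config A [task_config()].
#' @param path File path.
#' @return `read_task_config()` returns a `prlt_task_config`.
#' @export
write_task_config <- function(config, path) {
  stopifnot(inherits(config, "prlt_task_config"))
  yaml::write_yaml(list(
    n_phases = config$n_phases,
    trials_per_phase = config$trials_per_phase,
    block_size = config$block_size,
    contingency_order = if (config$order_label == "custom")
      config$contingencies else config$order_label,
    points_per_feedback = config$points_per_feedback,
    option_tokens = config$option_tokens), path)
  invisible(path)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(path) {
  f <- yaml::read_yaml(path)
  task_config(n_phases = f$n_phases,
              trials_per_phase = f$trials_per_phase,
              block_size = f$block_size,
              contingency_order = if (is.numeric(f$contingency_order))
                as.numeric(f$contingency_order) else f$contingency_order,
              points_per_feedback = f$points_per_feedback,
              option_tokens = unlist(f$option_tokens))
}
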