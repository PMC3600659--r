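# Behavioural dependent measures: block-wise correct-choice counts,
# reversal cost (first-block counts), asymptotic learning (collapsed
# last-two-block counts), rank transforms, and partial correlations.

#' Tabulate a trial log into phase-by-block counts and latencies
#'
#' @param trials A trial-record data frame from [simulate_participant()]
#'   (or an equivalent log with columns `phase`, `trial_in_phase` or
#'   `trial`, `block`, `accurate`, `latency_ms`). Must be a complete log:
#'   every (phase, trial) cell exactly once.
#' @param block_size Trials per block (default 10), used for validation.
#' @return An object of class `prlt_block_table`: a list with `counts`
#'   (phase x block matrix of correct-choice counts) and `latency`
#'   (matching matrix of mean latencies in ms).
#' @export
tabulate_blocks <- function(trials, block_size = 10L) {
  need <- c("phase", "block", "accurate", "latency_ms")
  if (!all(need %in% names(trials))) {
    stop("trial log must have columns: ", paste(need, collapse = ", "))
  }
  phases <- sort(unique(trials$phase))
  blocks <- sort(unique(trials$block))
  if (!identical(phases, seq_along(phases)) ||
      !identical(blocks, seq_along(blocks))) {
    stop("phase and block indices must be contiguous and 1-based")
  }
  tab <- table(factor(trials$phase, levels = phases),
               factor(trials$block, levels = blocks))
  if (any(tab != block_size)) {
    stop(sprintf(
      "incomplete or duplicated trial log: expected %d trials per cell",
      block_size))
  }
  if (any(trials$latency_ms <= 0)) stop("latencies must be positive")
  counts <- matrix(0L, length(phases), length(blocks),
                   dimnames = list(phase = phases, block = blocks))
  latency <- counts * 0
  for (ph in phases) {
    for (bl in blocks) {
      sel <- trials$phase == ph & trials$block == bl
      counts[ph, bl] <- sum(trials$accurate[sel])
      latency[ph, bl] <- mean(trials$latency_ms[sel])
    }
  }
  structure(list(counts = counts, latency = latency,
                 block_size = as.integer(block_size)),
            class = "prlt_block_table")
}

#' @export
print.prlt_block_table <- function(x, ...) {
  cat("PRLT block table (correct choices per block):\n")
  print(x$counts)
  invisible(x)
}

#' Reversal-cost scores: first-block correct counts per phase
#'
#' Returns the block-1 correct-choice count of every phase. Only phases 2
#' onward follow a reversal; phase 1 is retained for design completeness
#' and flagged via the `"reversal"` attribute (`FALSE` for phase 1).
#'
#' @param table A [tabulate_blocks()] result.
#' @return Named numeric vector (one entry per phase) with attribute
#'   `reversal`.
#' @export
reversal_cost_scores <- function(table) {
  stopifnot(inherits(table, "prlt_block_table"))
  out <- table$counts[, 1]
  names(out) <- paste0("phase", seq_along(out))
  attr(out, "reversal") <- c(FALSE, rep(TRUE, length(out) - 1L))
  out
}

#' Asymptotic-learning scores: collapsed last-two-block counts per phase
#'
#' Per phase, the sum of correct choices in the last two blocks (range
#' 0 to `2 * block_size`). Collapsing by summation keeps the score
#' integer-valued; it is scale-equivalent to the mean for all correlation
#' and ANOVA purposes.
#'
#' @param table A [tabulate_blocks()] result.
#' @return Named numeric vector, one entry per phase.
#' @export
asymptote_scores <- function(table) {
  stopifnot(inherits(table, "prlt_block_table"))
  nb <- ncol(table$counts)
  if (nb < 2L) stop("need at least two blocks per phase")
  out <- table$counts[, nb - 1L] + table$counts[, nb]
  names(out) <- paste0("phase", seq_along(out))
  out
}

#' Within-design rank transform
#'
#' Average ranks with ties averaged; order-preserving and invariant to
#' strictly monotone transforms of the input. Used to de-skew exposure
#' covariates before correlation/ANCOVA analyses.
#'
#' @param values Numeric vector without missing values.
#' @return Rank scores (a permutation of `1..n` with ties averaged).
#' @export
#' @examples
#' rank_transform(c(5, 1, 9)) # 2 1 3
#' rank_transform(c(3, 1, 3)) # 2.5 1 2.5
rank_transform <- function(values) {
  if (anyNA(values)) stop("missing values not allowed in rank transform")
  rank(values, ties.method = "average")
}

#' First-order partial correlation
#'
#' Pearson correlation between the least-squares residuals of `x` on
#' `control` and of `y` on `control`, with a two-sided p value from the t
#' distribution on `n - 3` degrees of freedom. With `use_ranks = TRUE`
#' (the default convention for skewed exposure covariates) all three
#' variables are rank-transformed first, giving a Spearman-type partial
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param control Numeric vector (the variable partialled out).
#' @param use_ranks Rank-transform inputs first (default `FALSE`).
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, control, use_ranks = FALSE) {
  n <- length(x)
  if (length(y) != n || length(control) != n) {
    stop("`x`, `y` and `control` must have equal length")
  }
  if (n < 4L) stop("partial correlation needs n >= 4")
  if (anyNA(c(x, y, control))) stop("missing values not allowed")
  if (use_ranks) {
    x <- rank_transform(x); y <- rank_transform(y)
    control <- rank_transform(control)
  }
  z <- cbind(1, control)
  rx <- lm.fit(z, x)$residuals
  ry <- lm.fit(z, y)$residuals
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    stop("residuals are (numerically) constant; ",
         "partial correlation undefined")
  }
  r <- cor(rx, ry)
  df <- n - 3L
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n)
}

#' Behavioural metrics for a whole cohort
#'
#' Convenience wrapper: tabulates each participant's log and assembles a
#' tidy per-participant table of block counts, latencies, reversal-cost
#' and asymptote scores.
#'
#' @param trial_log Cohort trial log from [simulate_cohort()].
#' @param block_size Trials per block.
#' @return A data frame with one row per participant x phase x block plus
#'   derived per-phase scores in the attribute-free columns
#'   `first_block` and `last_two_blocks` (repeated within phase).
#' @export
cohort_metrics <- function(trial_log, block_size = 10L) {
  ids <- unique(trial_log$participant_id)
  rows <- lapply(ids, function(id) {
    tl <- trial_log[trial_log$participant_id == id, ]
    tab <- tabulate_blocks(tl, block_size = block_size)
    rc <- reversal_cost_scores(tab)
    as <- asymptote_scores(tab)
    np <- nrow(tab$counts); nb <- ncol(tab$counts)
    data.frame(participant_id = id,
               phase = rep(seq_len(np), each = nb),
               block = rep(seq_len(nb), times = np),
               correct = as.vector(t(tab$counts)),
               latency_ms = as.vector(t(tab$latency)),
               first_block = rep(unname(rc), each = nb),
               last_two_blocks = rep(unname(as), each = nb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
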