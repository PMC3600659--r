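# Feedback-locked ERP scoring: amplitude-threshold artifact rejection,
# baseline-corrected condition averages, FRN and P3 component scores.
#
# Window boundaries are inclusive throughout; at 250 Hz samples fall at
# 4 ms steps with t = 0 at feedback onset. The FRN per condition is the
# mean amplitude in 220-350 ms minus the positive peak (maximum sample)
# in 150-220 ms; the differential FRN score is PF minus NF. The P3 per
# condition is the mean of the last 50 ms referenced to the mean of the
# immediately preceding 100 ms; the differential P3 score is NF minus PF
# (note the opposite order).

#' ERP scoring configuration
#'
#' @param rejection_threshold Absolute amplitude threshold in uV (default
#'   100); an epoch is excluded iff any sample on any channel is strictly
#'   outside the `+/-threshold` range (a sample at exactly the threshold
#'   is retained).
#' @param frn_mean_window,frn_peak_window FRN windows in ms (defaults
#'   220-350 and 150-220).
#' @param p3_late_window,p3_ref_window P3 windows in ms (defaults 300-350
#'   and 200-300).
#' @param baseline_window Baseline-correction window in ms (default
#'   -200-0).
#' @param min_retained Named counts (`NF`, `PF`); falling below them
#'   after rejection raises a warning (a reporting threshold, not a hard
#'   gate).
#' @return An object of class `prlt_scoring_config`.
#' @export
scoring_config <- function(rejection_threshold = 100,
                           frn_mean_window = c(220, 350),
                           frn_peak_window = c(150, 220),
                           p3_late_window = c(300, 350),
                           p3_ref_window = c(200, 300),
                           baseline_window = c(-200, 0),
                           min_retained = c(NF = 27, PF = 51)) {
  stopifnot(rejection_threshold > 0,
            frn_peak_window[1] < frn_peak_window[2],
            frn_mean_window[1] < frn_mean_window[2],
            frn_peak_window[2] <= frn_mean_window[2],
            frn_peak_window[1] <= frn_mean_window[1],
            p3_late_window[1] < p3_late_window[2],
            p3_ref_window[2] <= p3_late_window[1] + 1e-9,
            all(c("NF", "PF") %in% names(min_retained)))
  structure(list(rejection_threshold = rejection_threshold,
                 frn_mean_window = frn_mean_window,
                 frn_peak_window = frn_peak_window,
                 p3_late_window = p3_late_window,
                 p3_ref_window = p3_ref_window,
                 baseline_window = baseline_window,
                 min_retained = min_retained),
            class = "prlt_scoring_config")
}

#' Reject high-amplitude epochs
#'
#' An epoch is excluded iff any sample on any channel lies strictly
#' outside `+/-rejection_threshold` uV. Retention counts below
#' `min_retained` trigger a warning; losing *all* epochs of a condition
#' is a hard error. The operation is idempotent.
#'
#' @param epochs An [epoch_set()].
#' @param config A [scoring_config()].
#' @return A list with `epochs` (retained [epoch_set()]) and `report`
#'   (list with `excluded` indices, `n_retained` and `n_excluded` per
#'   condition, and the threshold).
#' @export
reject_artifacts <- function(epochs, config = scoring_config()) {
  stopifnot(inherits(epochs, "prlt_epoch_set"),
            inherits(config, "prlt_scoring_config"))
  thr <- config$rejection_threshold
  bad <- apply(abs(epochs$amplitudes) > thr, 3, any)
  retained <- subset_epochs(epochs, !bad)
  for (cond in c("PF", "NF")) { # hard errors take precedence
    if (sum(epochs$condition == cond) > 0 &&
        sum(retained$condition == cond) == 0) {
      stop(sprintf("all %s epochs rejected at +/-%g uV", cond, thr))
    }
  }
  for (cond in c("PF", "NF")) {
    n_out <- sum(retained$condition == cond)
    if (n_out < config$min_retained[[cond]]) {
      warning(sprintf("only %d %s epochs retained (minimum %d)",
                      n_out, cond, config$min_retained[[cond]]),
              call. = FALSE)
    }
  }
  list(epochs = retained,
       report = list(
         threshold = thr,
         excluded = which(bad),
         n_excluded = sum(bad),
         n_retained = c(PF = sum(retained$condition == "PF"),
                        NF = sum(retained$condition == "NF"))))
}

#' Baseline-corrected condition averages
#'
#' Subtracts each epoch's per-channel mean over the baseline window, then
#' averages pointwise within condition.
#'
#' @param epochs An [epoch_set()].
#' @param config A [scoring_config()] (for the baseline window).
#' @return A list with `PF` and `NF` channel-by-sample matrices, `times`
#'   and `channels`.
#' @export
condition_average <- function(epochs, config = scoring_config()) {
  stopifnot(inherits(epochs, "prlt_epoch_set"))
  bw <- config$baseline_window
  sel <- epochs$times >= bw[1] & epochs$times <= bw[2]
  if (!any(sel)) stop("baseline window contains no samples")
  avg <- function(cond) {
    idx <- which(epochs$condition == cond)
    if (length(idx) == 0L) stop("no epochs in condition ", cond)
    acc <- matrix(0, dim(epochs$amplitudes)[1],
                  dim(epochs$amplitudes)[2])
    for (e in idx) {
      ep <- epochs$amplitudes[, , e, drop = FALSE]
      dim(ep) <- dim(ep)[1:2]
      ep <- ep - rowMeans(ep[, sel, drop = FALSE])
      acc <- acc + ep
    }
    out <- acc / length(idx)
    rownames(out) <- epochs$channels
    out
  }
  list(PF = avg("PF"), NF = avg("NF"), times = epochs$times,
       channels = epochs$channels)
}

#' FRN component for one average waveform
#'
#' Mean amplitude over the FRN mean window minus the maximum sample in
#' the preceding peak window (inclusive bounds; the maximum sample is
#' used even when negative, with a warning).
#'
#' @param waveform Numeric vector, one channel's condition average (uV).
#' @param times Sample times in ms.
#' @param config A [scoring_config()].
#' @return FRN component value in uV.
#' @export
frn_component <- function(waveform, times, config = scoring_config()) {
  mw <- config$frn_mean_window
  pw <- config$frn_peak_window
  in_mean <- times >= mw[1] & times <= mw[2]
  in_peak <- times >= pw[1] & times <= pw[2]
  if (!any(in_mean) || !any(in_peak)) {
    stop("FRN window contains no samples at this sampling rate")
  }
  peak <- max(waveform[in_peak])
  if (peak < 0) {
    warning("no positive peak in the peak window; using maximum sample",
            call. = FALSE)
  }
  mean(waveform[in_mean]) - peak
}

#' Differential FRN score per channel
#'
#' FRN component of the PF average minus FRN component of the NF average,
#' per channel.
#'
#' @param erp_pf,erp_nf Channel-by-sample condition-average matrices (as
#'   from [condition_average()]).
#' @param times Sample times in ms.
#' @param config A [scoring_config()].
#' @return A data frame with `channel`, `frn_pf`, `frn_nf`,
#'   `differential` (`frn_pf - frn_nf`).
#' @export
frn_score <- function(erp_pf, erp_nf, times, config = scoring_config()) {
  stopifnot(nrow(erp_pf) == nrow(erp_nf))
  channels <- rownames(erp_pf)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(erp_pf)))
  pf <- vapply(seq_len(nrow(erp_pf)), function(ch)
    frn_component(erp_pf[ch, ], times, config), numeric(1))
  nf <- vapply(seq_len(nrow(erp_nf)), function(ch)
    frn_component(erp_nf[ch, ], times, config), numeric(1))
  data.frame(channel = channels, frn_pf = pf, frn_nf = nf,
             differential = pf - nf, stringsAsFactors = FALSE)
}

#' Differential P3 score per channel
#'
#' Per condition: mean over the late window minus mean over the
#' immediately preceding reference window. The differential is NF minus
#' PF (opposite order to the FRN score).
#'
#' @inheritParams frn_score
#' @return A data frame with `channel`, `p3_pf`, `p3_nf`, `differential`
#'   (`p3_nf - p3_pf`).
#' @export
p3_score <- function(erp_pf, erp_nf, times, config = scoring_config()) {
  lw <- config$p3_late_window
  rw <- config$p3_ref_window
  in_late <- times >= lw[1] & times <= lw[2]
  in_ref <- times >= rw[1] & times <= rw[2]
  if (!any(in_late) || !any(in_ref)) {
    stop("P3 window contains no samples at this sampling rate")
  }
  one <- function(m) {
    vapply(seq_len(nrow(m)), function(ch)
      mean(m[ch, in_late]) - mean(m[ch, in_ref]), numeric(1))
  }
  channels <- rownames(erp_pf)
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(erp_pf)))
  pf <- one(erp_pf); nf <- one(erp_nf)
  data.frame(channel = channels, p3_pf = pf, p3_nf = nf,
             differential = nf - pf, stringsAsFactors = FALSE)
}

#' Full ERP scoring pipeline for one participant
#'
#' Rejection, baseline-corrected averaging, FRN and P3 scoring.
#'
#' @param epochs An [epoch_set()].
#' @param config A [scoring_config()].
#' @return A list with `frn` and `p3` score data frames and the
#'   `rejection` report.
#' @export
score_participant <- function(epochs, config = scoring_config()) {
  rej <- reject_artifacts(epochs, config)
  avg <- condition_average(rej$epochs, config)
  list(frn = frn_score(avg$PF, avg$NF, avg$times, config),
       p3 = p3_score(avg$PF, avg$NF, avg$times, config),
       rejection = rej$report)
}
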