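# Synthetic feedback-locked EEG and cortical current-density generators.
#
# Epoch waveforms are built from compact-support Gaussian components
# (positive fronto-central peak at 150-220 ms, valence-dependent FRN
# deflection at 220-350 ms, late P3) so that every windowed component
# score has a closed form on the sample grid; the NF deflection amplitude
# is calibrated per participant so that the downstream differential FRN
# score at FCz equals the configured value exactly in the zero-noise
# limit.

#' Synthetic EEG configuration
#'
#' @param channels Ordered channel labels (default `Fz`, `FCz`, `Pz`).
#' @param srate Sampling rate in Hz (default 250).
#' @param window Epoch window in ms relative to feedback onset (default
#'   `c(-200, 350)`); samples are placed at `1000/srate` ms steps starting
#'   at `window[1]`, with t = 0 on the grid.
#' @param n_pf,n_nf Epochs per condition (positive / negative feedback).
#' @param noise_white_sd,noise_pink_sd Per-sample SD (uV) of the white and
#'   1/f-like noise added to each epoch and channel.
#' @param artifact_rate Fraction of epochs receiving an injected
#'   high-amplitude artifact (default 0).
#' @param artifact_amp Absolute amplitude (uV) of injected artifacts; must
#'   exceed any rejection threshold under test (default 150).
#' @param peak,frn,p3 Component definitions: lists with `center`, `width`
#'   (Gaussian, ms), `support` (ms interval outside which the component is
#'   exactly zero), amplitudes (uV) and `chan_w` (per-channel weight; the
#'   FRN weight is largest at FCz).
#' @param frn_calibration_window Window (ms) of the mean term of the FRN
#'   component score the NF amplitude is calibrated against (must match
#'   the scoring configuration; default `c(220, 350)`).
#' @return An object of class `prlt_eeg_config`.
#' @export
synth_eeg_config <- function(channels = c("Fz", "FCz", "Pz"),
                             srate = 250,
                             window = c(-200, 350),
                             n_pf = 90L, n_nf = 60L,
                             noise_white_sd = 1.5,
                             noise_pink_sd = 2.5,
                             artifact_rate = 0,
                             artifact_amp = 150,
                             peak = list(center = 185, width = 18,
                                         support = c(150, 220), amp = 6,
                                         chan_w = c(0.8, 1, 0.6)),
                             frn = list(center = 285, width = 30,
                                        support = c(220, 350),
                                        amp_pf = -1,
                                        chan_w = c(0.85, 1, 0.4)),
                             p3 = list(center = 330, width = 40,
                                       support = c(250, 350),
                                       amp_pf = 5, amp_nf = 5,
                                       chan_w = c(0.5, 0.7, 1)),
                             frn_calibration_window = c(220, 350)) {
  stopifnot(length(window) == 2L, window[1] < 0, window[2] > 0,
            srate > 0, n_pf >= 1L, n_nf >= 1L,
            artifact_rate >= 0, artifact_rate <= 1,
            noise_white_sd >= 0, noise_pink_sd >= 0,
            "FCz" %in% channels)
  for (comp in list(peak, frn, p3)) {
    if (comp$support[1] < window[1] || comp$support[2] > window[2]) {
      stop("component support must lie inside the epoch window")
    }
    if (length(comp$chan_w) != length(channels)) {
      stop("each component needs one channel weight per channel")
    }
  }
  structure(list(channels = channels, srate = srate, window = window,
                 n_pf = as.integer(n_pf), n_nf = as.integer(n_nf),
                 noise_white_sd = noise_white_sd,
                 noise_pink_sd = noise_pink_sd,
                 artifact_rate = artifact_rate,
                 artifact_amp = artifact_amp,
                 peak = peak, frn = frn, p3 = p3,
                 frn_calibration_window = frn_calibration_window),
            class = "prlt_eeg_config")
}

# Sample grid for an epoch config: window[1], window[1] + step, ... <=
# window[2], step = 1000/srate; t = 0 lies on the grid because window[1]
# is a multiple of the step in all supported configs.
epoch_times <- function(config) {
  step <- 1000 / config$srate
  seq(config$window[1], config$window[2], by = step)
}

# Truncated Gaussian bump on the sample grid (exactly zero off support).
gauss_bump <- function(times, center, width, support) {
  b <- exp(-0.5 * ((times - center) / width)^2)
  b[times < support[1] | times > support[2]] <- 0
  b
}

# 1/f-like noise: white spectrum shaped by 1/sqrt(f), normalised to unit
# per-sample SD.
pink_noise <- function(n) {
  x <- rnorm(n)
  X <- fft(x)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1) # symmetric (two-sided) frequency index
  X <- X / sqrt(f)
  y <- Re(fft(X, inverse = TRUE)) / n
  y / sd(y)
}

# Condition templates (channel x sample) for one participant. The NF
# deflection amplitude is solved from the participant's configured
# differential FRN score d at FCz: with mbar the mean of the unit bump
# over the calibration window, d = (amp_pf - amp_nf) * w_FCz * mbar.
build_templates <- function(config, frn_differential) {
  times <- epoch_times(config)
  nchan <- length(config$channels)
  fcz <- match("FCz", config$channels)
  bump_peak <- gauss_bump(times, config$peak$center, config$peak$width,
                          config$peak$support)
  bump_frn <- gauss_bump(times, config$frn$center, config$frn$width,
                         config$frn$support)
  bump_p3 <- gauss_bump(times, config$p3$center, config$p3$width,
                        config$p3$support)
  w <- config$frn_calibration_window
  mbar <- mean(bump_frn[times >= w[1] & times <= w[2]])
  amp_nf <- config$frn$amp_pf -
    frn_differential / (config$frn$chan_w[fcz] * mbar)
  tpl <- function(frn_amp, p3_amp) {
    out <- matrix(0, nchan, length(times),
                  dimnames = list(config$channels, NULL))
    for (ch in seq_len(nchan)) {
      out[ch, ] <- config$peak$amp * config$peak$chan_w[ch] * bump_peak +
        frn_amp * config$frn$chan_w[ch] * bump_frn +
        p3_amp * config$p3$chan_w[ch] * bump_p3
    }
    out
  }
  list(PF = tpl(config$frn$amp_pf, config$p3$amp_pf),
       NF = tpl(amp_nf, config$p3$amp_nf),
       times = times, amp_nf = amp_nf)
}

#' Generate feedback-locked synthetic epochs for one participant
#'
#' Epochs are the participant's condition template plus per-channel
#' 1/f-like and white noise; an `artifact_rate` fraction of epochs
#' additionally receives a short `artifact_amp` uV pulse on one channel.
#' In the zero-noise limit the condition averages equal the templates
#' exactly, and the differential FRN score at FCz equals the profile's
#' configured `frn_differential`.
#'
#' @param profile A participant profile from [make_cohort()] (uses
#'   `profile$erp$frn_differential`), or a number giving the differential
#'   directly.
#' @param config A [synth_eeg_config()].
#' @param seed Integer seed.
#' @return An [epoch_set()] with `config$n_pf + config$n_nf` epochs.
#' @export
generate_epochs <- function(profile, config = synth_eeg_config(), seed) {
  stopifnot(inherits(config, "prlt_eeg_config"))
  d <- if (is.numeric(profile)) profile else profile$erp$frn_differential
  tpl <- build_templates(config, d)
  times <- tpl$times
  nchan <- length(config$channels)
  ns <- length(times)
  n_epochs <- config$n_pf + config$n_nf
  condition <- c(rep("PF", config$n_pf), rep("NF", config$n_nf))
  with_seed(seed, {
    amp <- array(0, dim = c(nchan, ns, n_epochs))
    for (e in seq_len(n_epochs)) {
      base <- if (condition[e] == "PF") tpl$PF else tpl$NF
      noise <- matrix(0, nchan, ns)
      if (config$noise_pink_sd > 0 || config$noise_white_sd > 0) {
        for (ch in seq_len(nchan)) {
          noise[ch, ] <- config$noise_pink_sd * pink_noise(ns) +
            rnorm(ns, 0, config$noise_white_sd)
        }
      }
      amp[, , e] <- base + noise
    }
    if (config$artifact_rate > 0) {
      hit <- which(runif(n_epochs) < config$artifact_rate)
      for (e in hit) {
        ch <- sample.int(nchan, 1L)
        s0 <- sample.int(ns - 4L, 1L)
        sgn <- sample(c(-1, 1), 1L)
        amp[ch, s0:(s0 + 4L), e] <- amp[ch, s0:(s0 + 4L), e] +
          sgn * config$artifact_amp
      }
    }
    epoch_set(amp, times = times, channels = config$channels,
              condition = condition, srate = config$srate)
  })
}

#' Table-calibrated targets for the density-FRN correlation generator
#'
#' Per-area target correlations between window-averaged voxel current
#' density and the differential FRN score, for each group, as estimated in
#' the reference cohorts (controls: strong negative correlations in right
#' frontal, insular and posterior cingulate areas; cocaine-dependent:
#' attenuated negative; gamblers: mostly sign-reversed). Two null areas
#' are included for false-positive calibration.
#'
#' @param group `"HC"`, `"PG"` or `"CDI"`.
#' @return Named numeric vector of target correlations.
#' @export
source_targets <- function(group = c("HC", "PG", "CDI")) {
  group <- match.arg(group)
  switch(group,
         HC = c(BA9 = -0.70, BA10 = -0.75, BA13 = -0.71, BA23 = -0.75,
                BA46 = -0.74, null1 = 0, null2 = 0),
         CDI = c(BA9 = -0.47, BA10 = -0.43, BA13 = -0.53, BA23 = -0.42,
                 BA46 = -0.36, null1 = 0, null2 = 0),
         PG = c(BA9 = 0.35, BA10 = 0.34, BA13 = 0.72, BA23 = 0.78,
                BA46 = 0.07, null1 = 0, null2 = 0))
}

#' Source-map generator configuration
#'
#' @param target_r Named numeric vector of per-area target density-FRN
#'   correlations, each strictly inside (-1, 1); defaults to the control
#'   calibration ([source_targets()]).
#' @param n_voxels Named integer vector of voxels per area (same names as
#'   `target_r`); defaults to the reference voxel counts for the labelled
#'   areas and 20 voxels per null area.
#' @param offset,scale Location and scale of the generated densities
#'   (arbitrary units; densities are shifted to be non-negative).
#' @param share_area_noise Fraction of the noise variance shared by all
#'   voxels of an area (spatial smoothness of the inverse solution);
#'   in (0, 1).
#' @return An object of class `prlt_source_config`.
#' @export
source_synth_config <- function(target_r = source_targets("HC"),
                                n_voxels = c(BA9 = 10, BA10 = 16,
                                             BA13 = 9, BA23 = 4,
                                             BA46 = 16, null1 = 20,
                                             null2 = 20),
                                offset = 10, scale = 2,
                                share_area_noise = 0.7) {
  stopifnot(is.numeric(target_r), !is.null(names(target_r)),
            all(names(target_r) %in% names(n_voxels)),
            all(n_voxels >= 1), scale > 0,
            share_area_noise >= 0, share_area_noise < 1)
  if (any(abs(target_r) >= 1)) {
    stop("target correlations must lie strictly inside (-1, 1) ",
         "when voxel noise is present")
  }
  n_voxels <- n_voxels[names(target_r)]
  structure(list(target_r = target_r,
                 n_voxels = setNames(as.integer(n_voxels),
                                     names(target_r)),
                 offset = offset, scale = scale,
                 share_area_noise = share_area_noise),
            class = "prlt_source_config")
}

#' Generate participant-by-voxel current-density maps
#'
#' For each voxel of area `a` with target correlation `rho_a`, the
#' (window-averaged) density is `offset + scale * (rho_a * z + e)` where
#' `z` is the standardised FRN score and `e` is unit-variance noise split
#' into an area-shared and a voxel-specific part, so the population
#' correlation with the FRN score equals `rho_a`. Null areas
#' (`rho_a = 0`) are independent of the FRN. If any density comes out
#' negative the whole map is shifted by a constant (correlations are
#' unaffected).
#'
#' @param frn_scores Named numeric vector of per-participant differential
#'   FRN scores (n >= 4, non-constant).
#' @param config A [source_synth_config()].
#' @param seed Integer seed.
#' @return An object of class `prlt_density_map`: list with `densities`
#'   (participant x voxel matrix), `voxel_id`, `area` (label per voxel)
#'   and `window` (the nominal averaging window, ms).
#' @export
generate_source_maps <- function(frn_scores,
                                 config = source_synth_config(), seed) {
  stopifnot(inherits(config, "prlt_source_config"))
  n <- length(frn_scores)
  if (n < 4L) stop("need at least 4 participants")
  if (sd(frn_scores) < 1e-12) stop("FRN scores must be non-constant")
  z <- (frn_scores - mean(frn_scores)) / sd(frn_scores)
  areas <- names(config$target_r)
  nv <- config$n_voxels
  with_seed(seed, {
    cols <- list(); labels <- character(0)
    for (a in areas) {
      rho <- config$target_r[[a]]
      k <- nv[[a]]
      shared <- rnorm(n)
      noise_sd <- sqrt(1 - rho^2)
      w_sh <- sqrt(config$share_area_noise)
      w_id <- sqrt(1 - config$share_area_noise)
      block <- matrix(0, n, k)
      for (v in seq_len(k)) {
        e <- w_sh * shared + w_id * rnorm(n)
        block[, v] <- config$offset +
          config$scale * (rho * z + noise_sd * e)
      }
      cols[[a]] <- block
      labels <- c(labels, rep(a, k))
    }
    dens <- do.call(cbind, cols)
    if (min(dens) < 0) dens <- dens - min(dens) # shift; r-invariant
    rownames(dens) <- if (!is.null(names(frn_scores))) names(frn_scores)
    colnames(dens) <- sprintf("v%03d", seq_len(ncol(dens)))
    structure(list(densities = dens,
                   voxel_id = colnames(dens),
                   area = labels,
                   window = c(220, 330)),
              class = "prlt_density_map")
  })
}

#' @export
print.prlt_density_map <- function(x, ...) {
  cat(sprintf("Current-density map: %d participants x %d voxels (%d areas)\n",
              nrow(x$densities), ncol(x$densities),
              length(unique(x$area))))
  invisible(x)
}

#' Write / read a density map as CSV
#'
#' Long format: `participant_id`, `voxel_id`, `area`, `density`.
#'
#' @param map A `prlt_density_map`.
#' @param path File path.
#' @export
write_density_map <- function(map, path) {
  stopifnot(inherits(map, "prlt_density_map"))
  ids <- rownames(map$densities)
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(map$densities)))
  long <- data.frame(
    participant_id = rep(ids, times = ncol(map$densities)),
    voxel_id = rep(map$voxel_id, each = nrow(map$densities)),
    area = rep(map$area, each = nrow(map$densities)),
    density = as.vector(map$densities))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$participant_id)
  vox <- unique(long$voxel_id)
  dens <- matrix(NA_real_, length(ids), length(vox),
                 dimnames = list(ids, vox))
  dens[cbind(match(long$participant_id, ids),
             match(long$voxel_id, vox))] <- long$density
  area <- long$area[match(vox, long$voxel_id)]
  structure(list(densities = dens, voxel_id = vox, area = area,
                 window = c(220, 330)),
            class = "prlt_density_map")
}
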