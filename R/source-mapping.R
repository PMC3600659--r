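# Correlation-based identification of cortical FRN sources: window
# averaging of voxel time series, voxelwise density-FRN correlations
# (parametric or bootstrap p), the >=10-significant-voxel area rule, and
# Fisher-z contrasts of correlations across groups.

#' Window-average a voxel current-density time series
#'
#' Arithmetic mean over all samples whose time lies inside the window
#' (inclusive bounds).
#'
#' @param density_series Numeric array `participant x voxel x time`.
#' @param times Sample times in ms (length = third dim).
#' @param window Averaging window in ms (default `c(220, 330)`, the
#'   FRN-interval convention for source maps, which differs from the
#'   220-350 ms FRN scoring window).
#' @param area Optional voxel area labels.
#' @return A `prlt_density_map` (see [generate_source_maps()]).
#' @export
window_average <- function(density_series, times, window = c(220, 330),
                           area = NULL) {
  stopifnot(is.array(density_series), length(dim(density_series)) == 3L,
            length(times) == dim(density_series)[3])
  sel <- times >= window[1] & times <= window[2]
  if (!any(sel)) stop("averaging window contains no samples")
  dens <- apply(density_series[, , sel, drop = FALSE], c(1, 2), mean)
  if (is.null(colnames(dens))) {
    colnames(dens) <- sprintf("v%03d", seq_len(ncol(dens)))
  }
  if (is.null(area)) area <- rep("unlabelled", ncol(dens))
  structure(list(densities = dens, voxel_id = colnames(dens),
                 area = area, window = window),
            class = "prlt_density_map")
}

#' Voxelwise density-FRN correlations
#'
#' Pearson correlation, across participants, between each voxel's
#' window-averaged current density and the differential FRN score. The p
#' value is two-sided, either parametric (t on n - 2 df) or from a
#' seedable percentile bootstrap over participants.
#'
#' @param map A `prlt_density_map`.
#' @param frn Per-participant FRN scores (length = rows of the map).
#' @param method `"parametric"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @return A data frame with `voxel_id`, `area`, `r`, `p`; constant-
#'   density voxels get `NA` with a warning (flagged, not fatal).
#' @export
voxel_frn_correlations <- function(map, frn, method = c("parametric",
                                                        "bootstrap"),
                                   n_boot = 2000L, seed = 1L) {
  stopifnot(inherits(map, "prlt_density_map"))
  method <- match.arg(method)
  n <- nrow(map$densities)
  if (length(frn) != n) stop("FRN vector does not match the map")
  if (n < 4L) stop("need at least 4 participants")
  if (sd(frn) < 1e-12) stop("FRN scores must be non-constant")
  nv <- ncol(map$densities)
  r <- p <- rep(NA_real_, nv)
  const <- apply(map$densities, 2, sd) < 1e-12
  if (any(const)) {
    warning(sprintf("%d voxel(s) have constant density; r undefined",
                    sum(const)), call. = FALSE)
  }
  ok <- which(!const)
  r[ok] <- as.vector(cor(map$densities[, ok, drop = FALSE], frn))
  if (method == "parametric") {
    tval <- r[ok] * sqrt((n - 2) / pmax(1 - r[ok]^2,
                                        .Machine$double.eps))
    p[ok] <- 2 * pt(-abs(tval), n - 2)
  } else {
    p[ok] <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
      vapply(ok, function(v) {
        d <- map$densities[, v]
        rb <- vapply(seq_len(n_boot), function(b) {
          i <- idx[, b]
          if (sd(d[i]) < 1e-12 || sd(frn[i]) < 1e-12) return(NA_real_)
          cor(d[i], frn[i])
        }, numeric(1))
        rb <- rb[!is.na(rb)]
        # percentile bootstrap: two-sided p for H0: rho = 0
        lo <- (1 + sum(rb <= 0)) / (1 + length(rb))
        hi <- (1 + sum(rb >= 0)) / (1 + length(rb))
        min(1, 2 * min(lo, hi))
      }, numeric(1))
    })
  }
  data.frame(voxel_id = map$voxel_id, area = map$area, r = r, p = p,
             stringsAsFactors = FALSE)
}

#' Area-level voxel-count rule
#'
#' An area is singled out as a candidate FRN generator iff at least
#' `min_voxels` of its voxels correlate significantly (`p < alpha`) with
#' the FRN score. Counts are reported for every area regardless of
#' inclusion so that other conventions can be applied.
#'
#' @param voxel_stats Data frame from [voxel_frn_correlations()].
#' @param alpha Voxelwise significance level (default 0.05).
#' @param min_voxels Minimum significant voxels for inclusion (default
#'   10).
#' @return A data frame with one row per area: `area`, `n_voxels`,
#'   `n_significant`, `mean_r_significant` (mean r over significant
#'   voxels, `NA` if none), `included`.
#' @export
identify_areas <- function(voxel_stats, alpha = 0.05, min_voxels = 10L) {
  stopifnot(alpha >= 0, alpha <= 1, min_voxels >= 1)
  areas <- unique(voxel_stats$area)
  out <- do.call(rbind, lapply(areas, function(a) {
    s <- voxel_stats[voxel_stats$area == a, ]
    sig <- !is.na(s$p) & s$p < alpha
    data.frame(area = a, n_voxels = nrow(s), n_significant = sum(sig),
               mean_r_significant = if (any(sig)) mean(s$r[sig]) else
                 NA_real_,
               included = sum(sig) >= min_voxels,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fisher-z contrast of two independent correlations
#'
#' Tests `rho1 = rho2` for correlations estimated in two independent
#' samples: `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' two-sided normal p, Bonferroni-multiplied by `n_comparisons` and
#' capped at 1.
#'
#' @param r1,r2 Sample correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes (each `>= 4`).
#' @param n_comparisons Bonferroni family size (default 1).
#' @return A list with `z`, `p_raw`, `p_adjusted`.
#' @export
compare_correlations <- function(r1, n1, r2, n2, n_comparisons = 1L) {
  stopifnot(n1 >= 4, n2 >= 4, n_comparisons >= 1)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("Fisher transform undefined for |r| = 1")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p_raw <- 2 * pnorm(-abs(z))
  list(z = z, p_raw = p_raw,
       p_adjusted = min(1, p_raw * n_comparisons))
}
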