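test_that("window_average matches the direct summation oracle", {
  times <- grid_times()
  np <- 3; nv <- 2
  # constant series
  const <- array(4.2, dim = c(np, nv, length(times)))
  m <- window_average(const, times)
  expect_true(all(m$densities == 4.2))
  # ramp series: density(t) = t; oracle = direct mean over in-window
  # samples (220, 224, ..., 328 on this grid)
  ramp <- array(rep(times, each = np * nv),
                dim = c(np, nv, length(times)))
  m2 <- window_average(ramp, times, window = c(220, 330))
  oracle <- sum(times[times >= 220 & times <= 330]) /
    sum(times >= 220 & times <= 330)
  expect_equal(unname(m2$densities[1, 1]), oracle)
  expect_equal(oracle, 274) # grid anchored at -200: 330 is not a sample
  # single-sample window returns that sample
  m3 <- window_average(ramp, times, window = c(300, 301))
  expect_equal(unname(m3$densities[2, 2]), 300)
  expect_error(window_average(ramp, times, window = c(349, 350)),
               "no samples")
})

test_that("voxelwise correlations recover exact and degenerate cases", {
  frn <- c(3, 1, 4, 1.5, 2.6, 5.3, 0.5, 2.2)
  dens <- cbind(frn, -frn, rep(2, 8), 10 - 2 * frn)
  map <- structure(list(densities = dens,
                        voxel_id = paste0("v", 1:4),
                        area = c("a", "a", "b", "b"),
                        window = c(220, 330)),
                   class = "prlt_density_map")
  expect_warning(vs <- voxel_frn_correlations(map, frn), "constant")
  expect_equal(vs$r[1], 1)
  expect_equal(vs$r[2], -1)
  expect_true(is.na(vs$r[3]))
  expect_equal(vs$r[4], -1)
  expect_error(voxel_frn_correlations(map, rep(1, 8)), "non-constant")
})

test_that("sampling distribution of r is centred on the target (oracle)", {
  # n = 23, rho = -0.70 (the middle-frontal calibration value):
  # the mean sample r over 200 seeds lies within +/-0.05 of rho
  set.seed(2024)
  rs <- replicate(200, {
    x <- rnorm(23)
    y <- -0.70 * x + sqrt(1 - 0.70^2) * rnorm(23)
    cor(x, y)
  })
  expect_lt(abs(mean(rs) - (-0.70)), 0.05)
})

test_that("parametric and bootstrap decisions agree for strong effects", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    frn <- rnorm(23)
    d <- matrix(-0.75 * frn + sqrt(1 - 0.75^2) * rnorm(23), ncol = 1)
    map <- structure(list(densities = d, voxel_id = "v1", area = "a",
                          window = c(220, 330)),
                     class = "prlt_density_map")
    pp <- voxel_frn_correlations(map, frn, method = "parametric")$p
    pb <- voxel_frn_correlations(map, frn, method = "bootstrap",
                                 n_boot = 2000, seed = s)$p
    (pp < 0.05) == (pb < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("the >=10-significant-voxel area rule is exact", {
  mk_stats <- function(n_sig, n_tot) {
    data.frame(voxel_id = paste0("v", seq_len(n_tot)), area = "a",
               r = 0.6,
               p = c(rep(0.01, n_sig), rep(0.5, n_tot - n_sig)))
  }
  expect_true(identify_areas(mk_stats(10, 16))$included)
  expect_false(identify_areas(mk_stats(9, 16))$included)
  expect_equal(identify_areas(mk_stats(9, 16))$n_significant, 9)
  # alpha = 0 admits nothing
  expect_false(identify_areas(mk_stats(16, 16), alpha = 0)$included)
  # NA p values (constant voxels) are not counted
  s <- mk_stats(10, 16); s$p[1] <- NA
  expect_false(identify_areas(s)$included)
})

test_that("null areas pass the area rule in fewer than 10% of seeds", {
  frn <- rnorm(23, 3, 1)
  inc <- vapply(1:100, function(s) {
    m <- generate_source_maps(frn, source_synth_config(), seed = s)
    vs <- voxel_frn_correlations(m, frn)
    ar <- identify_areas(vs)
    any(ar$included[ar$area %in% c("null1", "null2")])
  }, logical(1))
  expect_lt(mean(inc), 0.10)
})

test_that("control-calibrated maps recover the reference areas end-to-end", {
  # areas with >= 10 voxels (BA9, BA10, BA46) are flagged and null areas
  # are not, in >= 90% of 100 seeds; BA13 (9 voxels) and BA23 (4) cannot
  # pass the rule by construction
  set.seed(555)
  ok <- vapply(1:100, function(s) {
    frn <- rnorm(23, 3, 1)
    m <- generate_source_maps(frn, source_synth_config(), seed = s)
    ar <- identify_areas(voxel_frn_correlations(m, frn))
    flag <- setNames(ar$included, ar$area)
    all(flag[c("BA9", "BA10", "BA46")]) &&
      !any(flag[c("null1", "null2")])
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("correlations are invariant to affine maps and participant order", {
  set.seed(77)
  frn <- rnorm(12, 3, 1)
  m <- generate_source_maps(frn, source_synth_config(), seed = 6)
  vs <- voxel_frn_correlations(m, frn)
  m2 <- m; m2$densities <- 3 * m$densities + 7
  expect_equal(voxel_frn_correlations(m2, frn)$r, vs$r,
               tolerance = 1e-12)
  m3 <- m; m3$densities <- -2 * m$densities
  expect_equal(voxel_frn_correlations(m3, frn)$r, -vs$r,
               tolerance = 1e-12)
  perm <- sample(12)
  m4 <- m; m4$densities <- m$densities[perm, ]
  expect_equal(voxel_frn_correlations(m4, frn[perm])$r, vs$r,
               tolerance = 1e-12)
})

test_that("compare_correlations implements the Fisher-z contrast", {
  eq <- compare_correlations(0.4, 20, 0.4, 25)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_adjusted, 1)
  # closed-form oracle: r1 = 0.8, r2 = -0.8, n = 20 each
  cc <- compare_correlations(0.8, 20, -0.8, 20)
  z_or <- (atanh(0.8) - atanh(-0.8)) / sqrt(1 / 17 + 1 / 17)
  expect_equal(cc$z, z_or, tolerance = 1e-12)
  expect_equal(cc$p_raw, 2 * pnorm(-abs(z_or)), tolerance = 1e-12)
  expect_lt(cc$p_raw, 0.01)
  # Bonferroni multiplies and caps
  c5 <- compare_correlations(0.3, 20, 0.1, 20, n_comparisons = 5)
  expect_equal(c5$p_adjusted, min(1, 5 * c5$p_raw))
  expect_equal(compare_correlations(0.1, 20, 0.05, 20,
                                    n_comparisons = 50)$p_adjusted, 1)
  expect_error(compare_correlations(1, 20, 0.5, 20), "undefined")
  expect_error(compare_correlations(0.5, 3, 0.5, 20), "n1 >= 4")
})
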