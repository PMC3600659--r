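# End-to-end synthetic study runner: one master seed, labelled substreams
# per stage, structured logging, and a reproducible report bundle.

#' Study configuration
#'
#' Bundles all stage configurations and the master seed. Stage seeds are
#' derived deterministically from the master seed with per-stage labels
#' ([derive_seed()]), so stages are reproducible in isolation.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_config()].
#' @param eeg A [synth_eeg_config()].
#' @param scoring A [scoring_config()].
#' @param sources A [source_synth_config()] used for the control group;
#'   clinical groups reuse its voxel layout with their own
#'   [source_targets()].
#' @param alpha Voxelwise significance level for area identification.
#' @param min_voxels Area-inclusion voxel count.
#' @param seed Master seed.
#' @return An object of class `prlt_study_config`.
#' @export
study_config <- function(task = task_config(),
                         cohort = cohort_config(),
                         eeg = synth_eeg_config(),
                         scoring = scoring_config(),
                         sources = source_synth_config(),
                         alpha = 0.05, min_voxels = 10L, seed = 1L) {
  stopifnot(inherits(task, "prlt_task_config"),
            inherits(cohort, "prlt_cohort_config"),
            inherits(eeg, "prlt_eeg_config"),
            inherits(scoring, "prlt_scoring_config"),
            inherits(sources, "prlt_source_config"))
  structure(list(task = task, cohort = cohort, eeg = eeg,
                 scoring = scoring, sources = sources, alpha = alpha,
                 min_voxels = as.integer(min_voxels),
                 seed = as.integer(seed)),
            class = "prlt_study_config")
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic study
#'
#' Chains all stages: cohort generation, PRLT simulation, behavioural
#' metrics and covariate analyses, synthetic EEG and ERP scoring, FRN
#' group analysis, source-map generation and correlation mapping, and a
#' summary report. Re-running with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if missing). If `NULL`,
#'   nothing is written and the results are only returned.
#' @param verbose Emit per-stage progress messages.
#' @return (Invisibly) a list with `manifest`, `trial_log`, `metrics`,
#'   `behavior_anova`, `ancova` (per clinical group), `frn_scores`,
#'   `frn_anova`, `source` (per-group voxel stats, area results, and
#'   cross-group contrasts), and `summary`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(config, "prlt_study_config"))
  seed <- config$seed
  t0 <- proc.time()[["elapsed"]]

  # -- cohort ---------------------------------------------------------
  cohort <- make_cohort(config$cohort, seed = derive_seed(seed, "cohort"))
  manifest <- as.data.frame(cohort)
  groups <- manifest$group
  stage_log(verbose, "cohort", "%d participants", nrow(manifest))

  # -- behaviour ------------------------------------------------------
  trial_log <- simulate_cohort(cohort, config$task,
                               seed = derive_seed(seed, "behavior"))
  metrics <- cohort_metrics(trial_log,
                            block_size = config$task$block_size)
  metrics$group <- groups[match(metrics$participant_id,
                                manifest$participant_id)]
  stage_log(verbose, "behavior", "%d trials", nrow(trial_log))

  behavior_anova <- mixed_anova(metrics, dv = "correct",
                                within = c("phase", "block"),
                                between = "group",
                                id = "participant_id")

  # per-group rank-score ANCOVAs (intensity, severity)
  ancova <- list()
  partials <- list()
  for (g in c("PG", "CDI")) {
    man_g <- manifest[manifest$group == g, ]
    mu_rank <- rank_transform(man_g$intensity)
    sev_rank <- rank_transform(man_g$severity)
    cov_df <- data.frame(participant_id = man_g$participant_id,
                         intensity_rank = mu_rank,
                         severity_rank = sev_rank)
    per_phase <- metrics[metrics$group == g & metrics$block == 1, ]
    per_phase <- merge(per_phase, cov_df, by = "participant_id")
    first_df <- unique(per_phase[, c("participant_id", "phase",
                                     "first_block", "intensity_rank",
                                     "severity_rank")])
    last_df <- unique(merge(
      metrics[metrics$group == g & metrics$block == 1,
              c("participant_id", "phase", "last_two_blocks")],
      cov_df, by = "participant_id"))
    ancova[[g]] <- list(
      reversal_cost = ancova_rm(first_df, dv = "first_block",
                                within = "phase",
                                covariates = c("intensity_rank",
                                               "severity_rank"),
                                id = "participant_id"),
      asymptote = ancova_rm(last_df, dv = "last_two_blocks",
                            within = "phase",
                            covariates = c("intensity_rank",
                                           "severity_rank"),
                            id = "participant_id"))
    # partial correlations per phase (reference-table style)
    partials[[g]] <- do.call(rbind, lapply(
      sort(unique(first_df$phase)), function(ph) {
        fd <- first_df[first_df$phase == ph, ]
        ld <- last_df[last_df$phase == ph, ]
        pc_rc <- partial_correlation(fd$intensity_rank, fd$first_block,
                                     fd$severity_rank)
        pc_as <- partial_correlation(ld$severity_rank,
                                     ld$last_two_blocks,
                                     ld$intensity_rank)
        data.frame(group = g, phase = ph,
                   r_intensity_first_block = pc_rc$r, p_rc = pc_rc$p,
                   r_severity_asymptote = pc_as$r, p_as = pc_as$p)
      }))
  }
  stage_log(verbose, "stats", "behavioural ANOVA/ANCOVAs done")

  # -- EEG + ERP scoring ---------------------------------------------
  frn_rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    ep <- generate_epochs(cohort[[i]], config$eeg,
                          seed = derive_seed(seed, paste0("eeg.", i)))
    sc <- score_participant(ep, config$scoring)
    frn_rows[[i]] <- cbind(participant_id = cohort[[i]]$id,
                           group = cohort[[i]]$group,
                           sc$frn,
                           p3_differential = sc$p3$differential,
                           n_retained_pf = sc$rejection$n_retained[["PF"]],
                           n_retained_nf = sc$rejection$n_retained[["NF"]])
  }
  frn_scores <- do.call(rbind, frn_rows)
  stage_log(verbose, "erp", "%d participants scored",
            length(unique(frn_scores$participant_id)))

  frn_fz_fcz <- frn_scores[frn_scores$channel %in% c("Fz", "FCz"), ]
  frn_anova <- mixed_anova(frn_fz_fcz, dv = "differential",
                           within = "channel", between = "group",
                           id = "participant_id")
  frn_posthoc <- posthoc(frn_fz_fcz, dv = "differential",
                         between = "group", id = "participant_id",
                         method = "bonferroni")

  # -- source mapping -------------------------------------------------
  fcz <- frn_scores[frn_scores$channel == "FCz", ]
  source_res <- list()
  for (g in c("HC", "PG", "CDI")) {
    frn_g <- setNames(fcz$differential[fcz$group == g],
                      fcz$participant_id[fcz$group == g])
    cfg_g <- source_synth_config(
      target_r = source_targets(g),
      n_voxels = config$sources$n_voxels,
      offset = config$sources$offset, scale = config$sources$scale,
      share_area_noise = config$sources$share_area_noise)
    map <- generate_source_maps(frn_g, cfg_g,
                                seed = derive_seed(seed,
                                                   paste0("sources.", g)))
    vs <- voxel_frn_correlations(map, frn_g)
    source_res[[g]] <- list(
      n = length(frn_g), voxel_stats = vs,
      areas = identify_areas(vs, alpha = config$alpha,
                             min_voxels = config$min_voxels))
  }
  # cross-group contrasts on area-mean correlations (reference areas)
  ref_areas <- setdiff(unique(source_res$HC$voxel_stats$area),
                       c("null1", "null2"))
  area_r <- function(g, a) {
    vs <- source_res[[g]]$voxel_stats
    mean(vs$r[vs$area == a], na.rm = TRUE)
  }
  contrasts <- do.call(rbind, lapply(ref_areas, function(a) {
    out <- lapply(list(c("HC", "PG"), c("HC", "CDI"), c("PG", "CDI")),
                  function(pair) {
      cc <- compare_correlations(area_r(pair[1], a),
                                 source_res[[pair[1]]]$n,
                                 area_r(pair[2], a),
                                 source_res[[pair[2]]]$n,
                                 n_comparisons = length(ref_areas))
      data.frame(area = a, contrast = paste(pair, collapse = " vs "),
                 z = cc$z, p_adjusted = cc$p_adjusted)
    })
    do.call(rbind, out)
  }))
  stage_log(verbose, "sources", "%d areas contrasted", length(ref_areas))

  # -- summary --------------------------------------------------------
  null_world <- config$cohort$severity_lapse_slope == 0 &&
    config$cohort$intensity_alpha_loss_slope == 0 &&
    config$cohort$intensity_latency_slope_ms == 0
  pg4 <- partials$PG[partials$PG$phase >= 2, ]
  cdi4 <- partials$CDI
  frn_means <- tapply(fcz$differential, fcz$group, mean)
  summary <- list(
    seed = seed,
    n_participants = nrow(manifest),
    expected_null = null_world,
    headline = list(
      intensity_reversal_cost_negative =
        mean(pg4$r_intensity_first_block) < 0,
      severity_asymptote_negative =
        mean(cdi4$r_severity_asymptote) < 0,
      hc_frn_larger_than_pg =
        unname(frn_means["HC"] > frn_means["PG"])),
    frn_group_p = frn_anova$p[frn_anova$effect == "group"],
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))

  result <- list(manifest = manifest, trial_log = trial_log,
                 metrics = metrics, behavior_anova = behavior_anova,
                 ancova = ancova, partial_correlations = partials,
                 frn_scores = frn_scores, frn_anova = frn_anova,
                 frn_posthoc = frn_posthoc, source = source_res,
                 source_contrasts = contrasts, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f) write.csv(x, file.path(out_dir, f),
                                     row.names = FALSE)
    wcsv(manifest, "cohort_manifest.csv")
    wcsv(trial_log, "trial_log.csv")
    wcsv(metrics, "metrics.csv")
    wcsv(as.data.frame(behavior_anova), "behavior_anova.csv")
    wcsv(frn_scores, "frn_scores.csv")
    wcsv(as.data.frame(frn_anova), "frn_anova.csv")
    for (g in names(source_res)) {
      wcsv(source_res[[g]]$voxel_stats,
           sprintf("voxel_correlations_%s.csv", g))
      wcsv(source_res[[g]]$areas, sprintf("areas_%s.csv", g))
    }
    wcsv(contrasts, "source_contrasts.csv")
    # timing is session metadata, not part of the reproducible bundle
    jsonlite::write_json(summary[setdiff(names(summary), "elapsed_s")],
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log(verbose, "report", "written to %s", out_dir)
  }
  invisible(result)
}

#' Command-line entry point
#'
#' Thin dispatcher for scripted use:
#' `Rscript -e 'prlterp::prlt_cli()' run-study --seed 1 --out results/`.
#' Subcommands: `run-study` (full pipeline), `simulate-cohort` (manifest
#' only), `score-erp --epochs <stem> --out <dir>` (score a stored epoch
#' container), `map-sources --density <csv> --frn <csv> --out <dir>`.
#'
#' @param args Character vector of arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the subcommand result.
#' @export
prlt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    stop("usage: prlt_cli <run-study|simulate-cohort|score-erp|",
         "map-sources> [--seed N] [--out DIR] ...")
  }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 1L && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("seed", "1"))
  out <- opt("out")
  switch(cmd,
    "run-study" = {
      res <- run_study(study_config(seed = seed), out_dir = out,
                       verbose = !is.null(opt("verbose", NULL)) ||
                         "--verbose" %in% args)
      invisible(res)
    },
    "simulate-cohort" = {
      man <- as.data.frame(make_cohort(cohort_config(), seed = seed))
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write.csv(man, file.path(out, "cohort_manifest.csv"),
                  row.names = FALSE)
      }
      invisible(man)
    },
    "score-erp" = {
      stem <- opt("epochs")
      if (is.null(stem)) stop("score-erp requires --epochs <stem>")
      sc <- score_participant(read_epoch_set(stem), scoring_config())
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write.csv(sc$frn, file.path(out, "frn_scores.csv"),
                  row.names = FALSE)
        write.csv(sc$p3, file.path(out, "p3_scores.csv"),
                  row.names = FALSE)
        jsonlite::write_json(sc$rejection,
                             file.path(out, "rejection_report.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      invisible(sc)
    },
    "map-sources" = {
      dpath <- opt("density"); fpath <- opt("frn")
      if (is.null(dpath) || is.null(fpath)) {
        stop("map-sources requires --density <csv> and --frn <csv>")
      }
      map <- read_density_map(dpath)
      frn_df <- read.csv(fpath, stringsAsFactors = FALSE)
      frn <- setNames(frn_df$differential, frn_df$participant_id)
      frn <- frn[rownames(map$densities)]
      vs <- voxel_frn_correlations(map, frn)
      ar <- identify_areas(vs,
                           alpha = as.numeric(opt("alpha", "0.05")),
                           min_voxels = as.integer(opt("min-voxels",
                                                       "10")))
      if (!is.null(out)) {
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write.csv(vs, file.path(out, "voxel_correlations.csv"),
                  row.names = FALSE)
        write.csv(ar, file.path(out, "areas.csv"), row.names = FALSE)
      }
      invisible(list(voxel_stats = vs, areas = ar))
    },
    stop("unknown subcommand: ", cmd))
}
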