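#' End-to-end experiment configuration
#'
#' One object holding everything [run_experiment()] needs: which group
#' presets to simulate (with optional overrides), the resampling and
#' significance settings, the analysis windows, and the master seed all
#' randomness flows from.
#'
#' @param groups Character vector of preset names (see [preset_truth()]).
#' @param overrides Named list (by group) of lists of [preset_truth()]
#'   overrides, e.g. `list(lesioned_noshift = list(sigma_bird = 0))`.
#' @param n_resamples Bootstrap resamples per estimate.
#' @param alpha Two-way significance level.
#' @param m_base,m_win,m_ref Equalized iteration counts for the bootstrap.
#' @param end_shift_days,washout_last_n Analysis windows.
#' @param od_sections_per_bird Sections per bird for the synthetic OD table.
#' @param od_target_fraction Calibration target for the OD generator (the
#'   study's reported below-threshold fraction).
#' @param seed Master seed; per-group and per-stage streams are derived from
#'   it deterministically.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(groups = names(PRESETS), overrides = list(),
                              n_resamples = 10000L, alpha = 0.05,
                              m_base = 50L, m_win = 50L, m_ref = 50L,
                              end_shift_days = 12:14, washout_last_n = 2L,
                              od_sections_per_bird = 30L,
                              od_target_fraction = 0.375, seed = 1L) {
  stopifnot(all(groups %in% names(PRESETS)), n_resamples >= 2L,
            alpha > 0, alpha < 1)
  structure(list(groups = groups, overrides = overrides,
                 n_resamples = as.integer(n_resamples), alpha = alpha,
                 m_base = as.integer(m_base), m_win = as.integer(m_win),
                 m_ref = as.integer(m_ref),
                 end_shift_days = as.integer(end_shift_days),
                 washout_last_n = as.integer(washout_last_n),
                 od_sections_per_bird = as.integer(od_sections_per_bird),
                 od_target_fraction = od_target_fraction,
                 seed = as.integer(seed)), class = "experiment_config")
}

stage_seed <- function(seed, stage, item = 0L) {
  as.integer((as.numeric(seed) * 2971 + stage * 7919 + item * 104729) %%
               2147483647)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) one dataset per group, then runs every stage:
#' daily trajectories, end-of-shift hierarchical bootstraps, washout deltas
#' and washout bootstraps, the statistical-test table for the lesioned
#' groups, mixed-model validation, and the synthetic lesion-extent analysis
#' with lesion-behavior correlations. Deterministic given `(config, seed)`.
#'
#' @param config An [experiment_config()].
#' @param datasets Optional named list of [pitch_dataset()] objects to use in
#'   place of generated ones (e.g. read from CSV); names must match
#'   `config$groups`. Missing groups are generated.
#' @param out_dir Optional directory; when given, CSV/JSON artifacts are
#'   written under it.
#' @return A list of class `results_bundle` with elements `datasets`,
#'   `trajectories`, `end_shift_boot`, `washout_delta_tables`,
#'   `washout_boot`, `table1`, `lmm`, `lesion`, `provenance`.
#' @export
run_experiment <- function(config = experiment_config(), datasets = NULL,
                           out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  groups <- config$groups
  truths <- setNames(lapply(seq_along(groups), function(i) {
    ov <- config$overrides[[groups[i]]]
    do.call(preset_truth, c(list(name = groups[i],
                                 seed = stage_seed(config$seed, 1L, i)), ov))
  }), groups)
  data_l <- setNames(lapply(groups, function(g) {
    if (!is.null(datasets[[g]])) datasets[[g]]
    else stage(paste0("generate:", g), generate_experiment(truths[[g]]))
  }), groups)

  traj <- lapply(data_l, function(d) stage("trajectory", daily_trajectory(d)))

  boots <- setNames(lapply(seq_along(groups), function(i) {
    stage(paste0("bootstrap:", groups[i]),
          hb_bootstrap(data_l[[i]], days = config$end_shift_days,
                       n_resamples = config$n_resamples,
                       m_base = config$m_base, m_win = config$m_win,
                       seed = stage_seed(config$seed, 2L, i)))
  }), groups)

  wash_groups <- groups[vapply(data_l, function(d)
    nrow(select_window(d, "washout")) > 0, logical(1))]
  wash_tabs <- setNames(lapply(wash_groups, function(g)
    stage(paste0("washout:", g), washout_delta(data_l[[g]]))), wash_groups)
  wash_boots <- setNames(lapply(wash_groups, function(g) {
    d <- data_l[[g]]
    stage(paste0("washout_boot:", g),
          hb_bootstrap_washout(
            d, days = end_of_washout_days(d, config$washout_last_n),
            n_resamples = config$n_resamples, m_base = config$m_base,
            m_win = config$m_win, m_ref = config$m_ref,
            seed = stage_seed(config$seed, 3L, match(g, groups))))
  }), wash_groups)

  lesioned_trio <- c("lesioned_noshift", "lesioned_plus1", "lesioned_minus1")
  table1 <- if (all(lesioned_trio %in% groups))
    stage("table1", make_table1(boots[lesioned_trio], alpha = config$alpha))
  else NULL

  lmm <- list()
  if (all(lesioned_trio %in% groups)) {
    lm_dat <- pitch_lmm_data(data_l[lesioned_trio], c(0, 1, -1),
                             days = config$end_shift_days)
    lmm$lesioned_direction <- stage("lmm", fit_pitch_lmm(lm_dat))
    lm_pool <- copy(lm_dat)[, x := as.numeric(x != 0)]
    lmm$lesioned_pooled_shift <- stage("lmm", fit_pitch_lmm(lm_pool))
  }
  unl <- c("unlesioned_plus1", "unlesioned_minus1")
  if (all(unl %in% groups))
    lmm$unlesioned_direction <- stage("lmm", fit_pitch_lmm(
      pitch_lmm_data(data_l[unl], c(1, -1), days = config$end_shift_days)))

  lesioned_birds <- unlist(lapply(data_l[grep("^lesioned", groups, value = TRUE)],
                                  function(d) unique(d$records$bird_id)),
                           use.names = FALSE)
  lesion <- NULL
  if (length(lesioned_birds) >= 3L) {
    od_truth <- od_generator_truth(
      n_lesion_birds = length(lesioned_birds),
      sections_per_bird = config$od_sections_per_bird,
      target_below_threshold_fraction = config$od_target_fraction,
      lesion_bird_ids = lesioned_birds, seed = stage_seed(config$seed, 4L))
    od_tab <- stage("od_generate", generate_od_sections(od_truth))
    lsum <- stage("lesion_summary", lesion_summary(od_tab))
    lesioned_data <- do.call(rbind, lapply(
      data_l[grep("^lesioned", groups, value = TRUE)],
      function(d) d$records))
    metrics <- stage("song_metrics", bird_song_metrics(
      pitch_dataset(lesioned_data, data_l[[grep("^lesioned", groups)[1]]]$timeline,
                    "lesioned_combined"),
      end_days = config$end_shift_days))
    corr <- stage("lesion_correlation",
                  lesion_behavior_correlation(lsum$per_bird_extent, metrics))
    lesion <- list(od_truth = od_truth, od_table = od_tab, summary = lsum,
                   correlations = corr)
  }

  bundle <- structure(list(
    datasets = data_l, truths = truths, trajectories = traj,
    end_shift_boot = boots, washout_delta_tables = wash_tabs,
    washout_boot = wash_boots, table1 = table1, lmm = lmm, lesion = lesion,
    provenance = list(config = config, seed = config$seed,
                      package_version = as.character(utils::packageVersion("songshift")),
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "results_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Statistical-test table for the lesioned groups
#'
#' The group-vs-zero and group-vs-group posterior-probability matrix for the
#' three lesioned groups (no shift, +1, -1 semitone shift): each row reports
#' P(row group >= column heading). Cells that do not make sense, or that
#' duplicate a comparison reported on another row, are explicit `NA`s.
#' Group-vs-zero tests are single comparisons; the three pairwise
#' group-vs-group tests share a Bonferroni correction (m = 3).
#'
#' @param boots Named list of three `hb_boot` objects:
#'   `lesioned_noshift`, `lesioned_plus1`, `lesioned_minus1`.
#' @param alpha Two-way significance level.
#' @return A data.table in the row/column layout of the study's test summary,
#'   with an attached `comparisons` attribute holding the full
#'   `hb_comparison` objects.
#' @export
make_table1 <- function(boots, alpha = 0.05) {
  need <- c("lesioned_noshift", "lesioned_plus1", "lesioned_minus1")
  miss <- setdiff(need, names(boots))
  if (length(miss)) stop("missing group(s): ", paste(miss, collapse = ", "))
  m_pair <- 3L
  cmp <- list(
    noshift_vs_zero = prob_ge_constant(boots$lesioned_noshift, 0, alpha,
                                       label = "lesioned 0 shift >= 0"),
    plus1_vs_zero = prob_ge_constant(boots$lesioned_plus1, 0, alpha,
                                     label = "lesioned +1 shift >= 0"),
    minus1_vs_zero = prob_ge_constant(boots$lesioned_minus1, 0, alpha,
                                      label = "lesioned -1 shift >= 0"),
    noshift_vs_plus1 = prob_group_ge(boots$lesioned_noshift,
                                     boots$lesioned_plus1, alpha, m_pair,
                                     label = "lesioned 0 shift >= lesioned +1"),
    noshift_vs_minus1 = prob_group_ge(boots$lesioned_noshift,
                                      boots$lesioned_minus1, alpha, m_pair,
                                      label = "lesioned 0 shift >= lesioned -1"),
    plus1_vs_minus1 = prob_group_ge(boots$lesioned_plus1,
                                    boots$lesioned_minus1, alpha, m_pair,
                                    label = "lesioned +1 >= lesioned -1"))
  p <- function(x) x$probability
  tab <- data.table(
    group = c("Lesioned 0 shift", "Lesioned +1 semitone shift",
              "Lesioned -1 semitone shift"),
    zero = c(p(cmp$noshift_vs_zero), p(cmp$plus1_vs_zero),
             p(cmp$minus1_vs_zero)),
    lesioned_plus1 = c(p(cmp$noshift_vs_plus1), NA_real_, NA_real_),
    lesioned_minus1 = c(p(cmp$noshift_vs_minus1), p(cmp$plus1_vs_minus1),
                        NA_real_))
  setattr(tab, "comparisons", cmp)
  tab[]
}

#' Write a results bundle to disk
#'
#' CSV for tables and trajectories, JSON for bootstrap/LMM/lesion summaries
#' and provenance.
#'
#' @param bundle A `results_bundle`.
#' @param out_dir Output directory (created if needed).
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  for (g in names(bundle$datasets)) {
    write_pitch_csv(bundle$datasets[[g]], fp(paste0("pitch_", g, ".csv")))
    if (!is.null(bundle$truths[[g]]))
      write_truth_yaml(bundle$truths[[g]], fp(paste0("truth_", g, ".yaml")))
    fwrite(bundle$trajectories[[g]], fp(paste0("trajectory_", g, ".csv")))
    write_boot_json(bundle$end_shift_boot[[g]], fp(paste0("boot_endshift_", g, ".json")))
  }
  for (g in names(bundle$washout_boot))
    write_boot_json(bundle$washout_boot[[g]], fp(paste0("boot_washout_", g, ".json")))
  if (!is.null(bundle$table1)) {
    fwrite(bundle$table1, fp("table1_probabilities.csv"))
    fwrite(comparison_table(attr(bundle$table1, "comparisons")),
           fp("table1_decisions.csv"))
  }
  for (nm in names(bundle$lmm))
    write_lmm_json(bundle$lmm[[nm]], fp(paste0("lmm_", nm, ".json")))
  if (!is.null(bundle$lesion)) {
    write_od_csv(bundle$lesion$od_table, fp("od_sections.csv"))
    s <- bundle$lesion$summary
    jsonlite::write_json(
      list(threshold = s$threshold,
           population_fraction_below = s$population_fraction_below,
           per_bird_extent = as.list(s$per_bird_extent),
           ks_statistic = s$ks_statistic, ks_p = s$ks_p,
           percentile_convention = s$percentile_convention),
      fp("lesion_summary.json"), auto_unbox = TRUE, digits = NA)
    fwrite(bundle$lesion$correlations, fp("table2_correlations.csv"))
  }
  jsonlite::write_json(
    list(seed = bundle$provenance$seed,
         package_version = bundle$provenance$package_version,
         groups = bundle$provenance$config$groups,
         n_resamples = bundle$provenance$config$n_resamples,
         alpha = bundle$provenance$config$alpha),
    fp("provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
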