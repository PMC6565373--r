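#' Ground truth for the synthetic cohort generator
#'
#' The latent parameters a synthetic pitch dataset is built from. The latent
#' mean semitone trajectory of syllable j in bird k is
#'
#'   mu_jk(d) = drift_asymptote * (1 - exp(-d_total / drift_timescale))
#'            + adapt_asymptote * (1 - exp(-d_shift / adapt_timescale))
#'            + (bird_k + syll_jk) * ramp(d)
#'
#' where `d_total` counts days from the start of the experiment (so
#' lesion-induced drift already evolves during baseline), `d_shift` counts
#' days from shift onset, and `bird_k ~ N(0, sigma_bird)`,
#' `syll_jk ~ N(0, sigma_syllable)` are idiosyncratic response deviations that
#' enter scaled by the adaptation ramp (they describe how much each bird and
#' syllable responds, so they survive baseline referencing). Iteration noise
#' `N(0, sigma_iteration)` is added per rendition and each pitch is realized
#' in Hz as `f0 * 2^((mu + eps) / 12)`.
#'
#' During washout the group-level trajectory either reverts (the adaptive
#' component decays exponentially toward zero, or approaches a calibrated
#' rebound `washout_delta_target`) or continues drifting; individual response
#' deviations are held at their end-of-shift values.
#'
#' @param group_label Group tag.
#' @param n_birds Number of birds in the cohort.
#' @param shift Imposed feedback shift in semitones (-1, 0 or +1); metadata.
#' @param drift_asymptote Lesion-induced pitch drop at plateau, semitones.
#' @param drift_timescale,adapt_timescale,washout_timescale First-order
#'   timescales in days.
#' @param adapt_asymptote Adaptive compensation at plateau, semitones (sign
#'   opposite the imposed shift for unlesioned groups, 0 for lesioned).
#' @param washout_mode `"revert"` or `"continue-drift"`.
#' @param washout_delta_target If non-`NULL`, the expected measured washout
#'   change (last 2 washout days relative to the last shift day), semitones;
#'   the rebound asymptote is solved so the expectation matches.
#' @param sigma_bird,sigma_syllable,sigma_iteration Variance components, in
#'   semitones, of the three levels of the hierarchy.
#' @param syllables_per_bird_range,iterations_per_day_range Integer intervals
#'   the per-bird syllable counts and per-syllable-per-day iteration counts
#'   are drawn uniformly from.
#' @param baseline_f0_range Interval in Hz the per-syllable base frequencies
#'   are drawn log-uniformly from.
#' @param timeline A [pitch_timeline()].
#' @param n_washout_birds Number of birds (the first so many) with washout
#'   recordings; headphones failures truncated washout in the real cohorts.
#' @param seed Master seed; each bird gets an independently derived stream.
#' @return An object of class `generator_truth`.
#' @export
generator_truth <- function(group_label = "custom", n_birds = 4L, shift = 0,
                            drift_asymptote = 0, drift_timescale = 6,
                            adapt_asymptote = 0, adapt_timescale = 5,
                            washout_mode = c("revert", "continue-drift"),
                            washout_timescale = 5, washout_delta_target = NULL,
                            sigma_bird = 0.10, sigma_syllable = 0.15,
                            sigma_iteration = 0.50,
                            syllables_per_bird_range = c(4L, 12L),
                            iterations_per_day_range = c(40L, 600L),
                            baseline_f0_range = c(1000, 6000),
                            timeline = pitch_timeline(),
                            n_washout_birds = n_birds, seed = 1L) {
  washout_mode <- match.arg(washout_mode)
  chk_range <- function(r, name, positive = TRUE) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        (positive && r[1] <= 0))
      stop("degenerate range for ", name)
    r
  }
  if (n_birds < 1L) stop("n_birds must be >= 1")
  if (any(c(sigma_bird, sigma_syllable, sigma_iteration) < 0))
    stop("variance components must be >= 0")
  if (any(c(drift_timescale, adapt_timescale, washout_timescale) <= 0))
    stop("timescales must be > 0")
  structure(list(
    group_label = group_label, n_birds = as.integer(n_birds), shift = shift,
    drift_asymptote = drift_asymptote, drift_timescale = drift_timescale,
    adapt_asymptote = adapt_asymptote, adapt_timescale = adapt_timescale,
    washout_mode = washout_mode, washout_timescale = washout_timescale,
    washout_delta_target = washout_delta_target,
    sigma_bird = sigma_bird, sigma_syllable = sigma_syllable,
    sigma_iteration = sigma_iteration,
    syllables_per_bird_range =
      as.integer(chk_range(syllables_per_bird_range, "syllables_per_bird_range")),
    iterations_per_day_range =
      as.integer(chk_range(iterations_per_day_range, "iterations_per_day_range")),
    baseline_f0_range = chk_range(baseline_f0_range, "baseline_f0_range"),
    timeline = timeline,
    n_washout_birds = as.integer(min(n_washout_birds, n_birds)),
    seed = as.integer(seed)), class = "generator_truth")
}

#' @export
print.generator_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<generator_truth> %s: %d birds (shift %+g st)\n",
    "  drift %.3f st (tau %g d), adaptation %.3f st (tau %g d), washout %s\n",
    "  sigmas bird/syllable/iteration: %.2f / %.2f / %.2f st, seed %d\n"),
    x$group_label, x$n_birds, x$shift, x$drift_asymptote, x$drift_timescale,
    x$adapt_asymptote, x$adapt_timescale, x$washout_mode,
    x$sigma_bird, x$sigma_syllable, x$sigma_iteration, x$seed))
  invisible(x)
}

# Measured semitone values are log2 of an arithmetic Hz mean of the baseline
# (and, for washout, the reference day); with lognormal iteration noise the
# arithmetic mean overshoots the geometric one, biasing every measured value
# by -sigma_iteration^2 * ln(2) / 24 semitones. Calibration and the true_*
# helpers account for it so expectations line up with what the metrics report.
convexity_st <- function(truth) truth$sigma_iteration^2 * log(2) / 24

g_drift <- function(truth, d_total) 1 - exp(-d_total / truth$drift_timescale)
g_adapt <- function(truth, d_shift) 1 - exp(-d_shift / truth$adapt_timescale)

# Group-level latent trajectory by epoch/day (excludes response deviations).
latent_mean <- function(truth, epoch, day) {
  tl <- truth$timeline
  drift_end <- g_drift(truth, tl$baseline + tl$shift)
  adapt_end <- g_adapt(truth, tl$shift)
  vapply(seq_along(epoch), function(i) {
    d <- day[i]
    switch(epoch[i],
      baseline = truth$drift_asymptote * g_drift(truth, d),
      shift = truth$drift_asymptote * g_drift(truth, tl$baseline + d) +
        truth$adapt_asymptote * g_adapt(truth, d),
      washout = {
        end <- truth$drift_asymptote * drift_end +
          truth$adapt_asymptote * adapt_end
        end + washout_change(truth, d)
      })
  }, numeric(1))
}

# Latent change during washout day w relative to the end-of-shift value.
washout_change <- function(truth, w) {
  tl <- truth$timeline
  if (!is.null(truth$washout_delta_target)) {
    ramp <- 1 - exp(-w / truth$washout_timescale)
    last2 <- seq.int(tl$washout - 1L, tl$washout)
    fac <- mean(1 - exp(-last2 / truth$washout_timescale))
    (truth$washout_delta_target + convexity_st(truth)) / fac * ramp
  } else if (truth$washout_mode == "revert") {
    truth$adapt_asymptote * g_adapt(truth, tl$shift) *
      (exp(-w / truth$washout_timescale) - 1)
  } else {
    d0 <- tl$baseline + tl$shift
    truth$drift_asymptote * (g_drift(truth, d0 + w) - g_drift(truth, d0))
  }
}

# Deviation ramp: how strongly bird/syllable response deviations express on a
# given day. Zero in baseline, adaptation-shaped during shift, frozen at the
# end-of-shift value through washout.
deviation_ramp <- function(truth, epoch, day) {
  tl <- truth$timeline
  ifelse(epoch == "baseline", 0,
         ifelse(epoch == "shift", g_adapt(truth, day),
                g_adapt(truth, tl$shift)))
}

#' Expected measured group effects of a generator truth
#'
#' `true_plateau()` is the expectation of [weighted_group_mean()] over the
#' given shift-day window (default: end of shift, days 12--14) for data
#' generated from `truth`; `true_washout_delta()` the expectation of
#' [washout_group_mean()] over the final washout days. Both are estimands of
#' the measured pipeline, not bare latent values: baselines are arithmetic
#' means of Hz, so the reference is the log of the mean per-day Hz factor
#' (not the mean latent semitone) and carries the lognormal iteration-noise
#' convexity term.
#'
#' @param truth A [generator_truth()].
#' @param days Shift-day window for the plateau.
#' @return A semitone value.
#' @export
true_plateau <- function(truth, days = end_of_shift_days(truth$timeline)) {
  base_days <- baseline_days_of(truth$timeline)
  mu_base <- latent_mean(truth, rep("baseline", length(base_days)), base_days)
  baseline_ref <- 12 * log2(mean(2^(mu_base / 12)))
  mean(latent_mean(truth, rep("shift", length(days)), days)) -
    baseline_ref - convexity_st(truth)
}

#' @rdname true_plateau
#' @param n_days Number of final washout days averaged.
#' @export
true_washout_delta <- function(truth, n_days = 2L) {
  tl <- truth$timeline
  days <- seq.int(tl$washout - n_days + 1L, tl$washout)
  mean(vapply(days, function(w) washout_change(truth, w), numeric(1))) -
    convexity_st(truth)
}

bird_stream_seed <- function(seed, bird) {
  as.integer((as.numeric(seed) * 1009 + 7919 * bird) %% 2147483647)
}

draw_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

#' Generate a synthetic pitch-shift experiment
#'
#' Simulates a full cohort from a [generator_truth()]: per-bird syllable
#' counts, log-uniform base frequencies, bird- and syllable-level response
#' deviations, per-day iteration counts and lognormal (in Hz) iteration noise,
#' over the truth's baseline/shift/washout timeline. Fully reproducible from
#' `truth$seed`; each bird has an independently derived stream, so adding
#' birds does not perturb existing ones.
#'
#' @param truth A [generator_truth()].
#' @return A [pitch_dataset()] with the truth attached (`$truth`).
#' @export
generate_experiment <- function(truth) {
  stopifnot(inherits(truth, "generator_truth"))
  tl <- truth$timeline
  day_grid <- rbindlist(lapply(EPOCHS, function(ep) {
    if (tl[[ep]] < 1L) return(NULL)
    data.table(epoch = ep, day = seq_len(tl[[ep]]))
  }))
  day_grid[, mu_group := latent_mean(truth, epoch, day)]
  day_grid[, ramp := deviation_ramp(truth, epoch, day)]
  birds <- vector("list", truth$n_birds)
  for (k in seq_len(truth$n_birds)) {
    set.seed(bird_stream_seed(truth$seed, k))
    grid <- if (k <= truth$n_washout_birds) day_grid else
      day_grid[epoch != "washout"]
    n_syl <- draw_int(1L, truth$syllables_per_bird_range)
    f0 <- exp(runif(n_syl, log(truth$baseline_f0_range[1]),
                    log(truth$baseline_f0_range[2])))
    bird_eff <- rnorm(1L, 0, truth$sigma_bird)
    syl_eff <- rnorm(n_syl, 0, truth$sigma_syllable)
    nd <- nrow(grid)
    counts <- matrix(draw_int(n_syl * nd, truth$iterations_per_day_range),
                     nrow = n_syl)
    syl_idx <- rep(rep(seq_len(n_syl), nd), as.vector(counts))
    day_idx <- rep(rep(seq_len(nd), each = n_syl), as.vector(counts))
    dev <- bird_eff + syl_eff
    mu <- grid$mu_group[day_idx] + dev[syl_idx] * grid$ramp[day_idx]
    eps <- rnorm(length(mu), 0, truth$sigma_iteration)
    birds[[k]] <- data.table(
      bird_id = sprintf("%s_b%02d", truth$group_label, k),
      syllable_id = sprintf("s%02d", syl_idx),
      day = grid$day[day_idx], epoch = grid$epoch[day_idx],
      pitch_hz = f0[syl_idx] * 2^((mu + eps) / 12))
  }
  pitch_dataset(rbindlist(birds), timeline = tl,
                group_label = truth$group_label, truth = truth)
}

# name: (n_birds, shift, plateau, component, washout_target, washout_mode,
#        washout_days, n_washout)
PRESETS <- list(
  unlesioned_plus1  = list(3L, +1, -0.40, "adapt", +0.17, "revert",         6L, 3L),
  unlesioned_minus1 = list(3L, -1, +0.36, "adapt", -0.22, "revert",         6L, 3L),
  unlesioned_noshift= list(2L,  0,  0.00, "adapt",  NULL, "revert",         6L, 2L),
  lesioned_plus1    = list(4L, +1, -0.38, "drift", +0.24, "revert",         7L, 2L),
  lesioned_minus1   = list(4L, -1, -0.46, "drift", -0.28, "revert",         7L, 2L),
  lesioned_noshift  = list(8L,  0, -0.19, "drift",  NULL, "continue-drift", 7L, 5L)
)

#' Study-group presets for the generator
#'
#' Returns a [generator_truth()] whose expected measured plateau over shift
#' days 12--14 equals the group effect the study reports: -0.40 / +0.36
#' semitones for unlesioned birds under +1 / -1 semitone shifts (adaptive
#' compensation), -0.38 / -0.46 for lesioned birds under the same shifts and
#' -0.19 for lesioned birds with no shift (non-adaptive pitch drift), and
#' ~0 for unlesioned birds with no shift. Bird counts (3/3/2/4/4/8), washout
#' lengths (6 d unlesioned, 7 d lesioned) and the number of birds with washout
#' data (all unlesioned; 2 per lesioned shift group; 5 lesioned no-shift)
#' match the study cohorts. Shift presets also carry the reported washout
#' rebound over the last 2 washout days (+0.17 / -0.22 unlesioned,
#' +0.24 / -0.28 lesioned) as `washout_delta_target`.
#'
#' For unlesioned groups the plateau is carried by the adaptation component,
#' for lesioned groups by the drift component (lesioned birds do not adapt);
#' the asymptote is solved so the expectation of the measured, baseline-
#' referenced group mean hits the target under whatever timescales and
#' variance components are in force.
#'
#' @param name One of `unlesioned_plus1`, `unlesioned_minus1`,
#'   `unlesioned_noshift`, `lesioned_plus1`, `lesioned_minus1`,
#'   `lesioned_noshift`.
#' @param ... Overrides forwarded to [generator_truth()] (e.g. `seed`,
#'   variance components, timescales); the plateau calibration is re-solved
#'   under the overrides.
#' @return A [generator_truth()].
#' @export
preset_truth <- function(name, ...) {
  if (!name %in% names(PRESETS))
    stop("unknown preset '", name, "'; available: ",
         paste(names(PRESETS), collapse = ", "))
  p <- PRESETS[[name]]
  args <- list(group_label = name, n_birds = p[[1]], shift = p[[2]],
               washout_delta_target = p[[5]], washout_mode = p[[6]],
               timeline = pitch_timeline(3L, 14L, p[[7]]),
               n_washout_birds = p[[8]])
  user <- list(...)
  args[names(user)] <- user
  truth <- do.call(generator_truth, args)
  # solve the asymptote so true_plateau(truth) equals the printed value
  target <- p[[3]]
  slot <- if (p[[4]] == "adapt") "adapt_asymptote" else "drift_asymptote"
  f <- function(A) {
    t2 <- truth
    t2[[slot]] <- A
    true_plateau(t2) - target
  }
  truth[[slot]] <- uniroot(f, interval = c(-60, 60), tol = 1e-12)$root
  truth
}

#' Write / read the generator truth echo
#'
#' The truth a synthetic dataset was generated from, serialized as YAML next
#' to the CSV so every synthetic table is auditable.
#'
#' @param truth A [generator_truth()].
#' @param path YAML file path.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "generator_truth"))
  x <- unclass(truth)
  x$timeline <- unclass(x$timeline)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  x$timeline <- do.call(pitch_timeline, x$timeline)
  do.call(generator_truth, x)
}
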