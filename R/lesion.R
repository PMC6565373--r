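#' Optical-density ratio of Area X to surrounding striatum
#'
#' Area X stains darker than surrounding striatum under TH immunolabeling, so
#' the ratio of its optical density to that of a representative striatal
#' region in the same section indexes dopaminergic innervation: low values
#' indicate denervation.
#'
#' @param od_areax Optical density of the Area X region (arbitrary units).
#' @param od_striatum Optical density of the striatal reference region
#'   (same units, > 0).
#' @return Dimensionless ratio(s).
#' @export
od_ratio <- function(od_areax, od_striatum) {
  if (any(!is.finite(od_striatum)) || any(od_striatum <= 0))
    stop("od_striatum must be positive and finite")
  od_areax / od_striatum
}

#' Lesion threshold from the saline OD-ratio distribution
#'
#' The 5th percentile of the saline-injected birds' section OD ratios, under
#' the linear-interpolation-between-closest-ranks convention
#' (`stats::quantile` type 7). The convention choice shifts the threshold
#' slightly at small n and is recorded in output metadata.
#'
#' @param saline_ratios Numeric vector of OD ratios from saline birds
#'   (length >= 2).
#' @param probs Percentile, as a probability.
#' @return The threshold OD ratio.
#' @export
lesion_threshold <- function(saline_ratios, probs = 0.05) {
  if (length(saline_ratios) < 2L)
    stop("need at least 2 saline OD ratios to define a threshold")
  unname(quantile(saline_ratios, probs, type = 7, names = FALSE))
}

#' Fraction of sections below the lesion threshold
#'
#' Strict "less than" comparison at the boundary. Returns the overall
#' population fraction and, when bird ids are supplied, the per-bird lesion
#' extents; per-bird extents weighted by section counts average back to the
#' population fraction exactly.
#'
#' @param ratios Numeric vector of section OD ratios.
#' @param threshold Threshold from [lesion_threshold()].
#' @param bird_id Optional bird id per section.
#' @return A list with `population_fraction` and (if ids given)
#'   `per_bird_extent` (named numeric) and `per_bird_n`.
#' @export
lesion_extent <- function(ratios, threshold, bird_id = NULL) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  below <- ratios < threshold
  out <- list(population_fraction = mean(below))
  if (!is.null(bird_id)) {
    out$per_bird_extent <- vapply(split(below, bird_id), mean, numeric(1))
    out$per_bird_n <- vapply(split(below, bird_id), length, integer(1))
  }
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of OD-ratio populations
#'
#' Tests whether the lesioned and saline section populations were drawn from
#' separate distributions. The statistic is the supremum of the ECDF
#' difference; the p-value is asymptotic for larger samples and exact below
#' a configurable total size (ties disable the exact computation, as usual).
#'
#' @param saline_ratios,lesion_ratios Numeric vectors of OD ratios.
#' @param exact_below Total sample size under which the exact p-value is
#'   requested.
#' @return A list with `ks_statistic` and `ks_p`.
#' @export
ks_compare <- function(saline_ratios, lesion_ratios, exact_below = 50L) {
  if (!length(saline_ratios) || !length(lesion_ratios))
    stop("both OD-ratio samples must be non-empty")
  exact <- (length(saline_ratios) + length(lesion_ratios)) < exact_below
  kt <- suppressWarnings(ks.test(lesion_ratios, saline_ratios, exact = exact))
  list(ks_statistic = unname(kt$statistic), ks_p = kt$p.value)
}

#' Summarize lesion extent from a per-section OD table
#'
#' Computes OD ratios, the saline 5th-percentile threshold, the overall and
#' per-bird fractions of lesioned-bird sections below it, and the KS
#' comparison of the two populations.
#'
#' @param od_table A table as produced by [generate_od_sections()] /
#'   [read_od_csv()]: columns `bird_id`, `group` (saline/lesioned),
#'   `od_areax`, `od_striatum`.
#' @return A list of class `lesion_summary`: `threshold`,
#'   `population_fraction_below`, `per_bird_extent`, `ks_statistic`, `ks_p`,
#'   plus `percentile_convention` metadata.
#' @export
lesion_summary <- function(od_table) {
  od_table <- as.data.table(od_table)
  stopifnot(all(c("bird_id", "group", "od_areax", "od_striatum") %in%
                  names(od_table)))
  od_table[, ratio := od_ratio(od_areax, od_striatum)]
  sal <- od_table[group == "saline"]
  les <- od_table[group == "lesioned"]
  if (!nrow(sal) || !nrow(les))
    stop("od_table must contain both saline and lesioned sections")
  thr <- lesion_threshold(sal$ratio)
  ext <- lesion_extent(les$ratio, thr, les$bird_id)
  ks <- ks_compare(sal$ratio, les$ratio)
  structure(list(
    threshold = thr,
    population_fraction_below = ext$population_fraction,
    per_bird_extent = ext$per_bird_extent,
    per_bird_n = ext$per_bird_n,
    ks_statistic = ks$ks_statistic, ks_p = ks$ks_p,
    n_saline_sections = nrow(sal), n_lesion_sections = nrow(les),
    percentile_convention = "linear interpolation (quantile type 7), strict '<' at boundary"),
    class = "lesion_summary")
}

#' @export
print.lesion_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<lesion_summary> threshold (saline 5th pct) = %.4f\n",
    "  %.1f%% of %d lesioned sections below threshold (%d birds)\n",
    "  two-sample KS: K = %.4f, p = %.3g\n"),
    x$threshold, 100 * x$population_fraction_below, x$n_lesion_sections,
    length(x$per_bird_extent), x$ks_statistic, x$ks_p))
  invisible(x)
}

#' Correlate per-bird lesion extent with song metrics
#'
#' Pearson correlation (and its two-sided p-value) between per-bird lesion
#' extents and one or more per-bird behavioral metrics -- final pitch change,
#' baseline variance, final variance, percent increase in variance.
#'
#' @param per_bird_extent Named numeric vector of lesion extents (bird ids as
#'   names).
#' @param per_bird_metrics A data.frame with a `bird_id` column and one
#'   column per metric, or a single named numeric vector.
#' @return A data.table with columns `metric`, `r`, `p`, `n`.
#' @export
lesion_behavior_correlation <- function(per_bird_extent, per_bird_metrics) {
  if (is.numeric(per_bird_metrics)) {
    per_bird_metrics <- data.table(bird_id = names(per_bird_metrics),
                                   metric = unname(per_bird_metrics))
  }
  m <- as.data.table(per_bird_metrics)
  stopifnot("bird_id" %in% names(m))
  m <- m[bird_id %in% names(per_bird_extent)]
  if (nrow(m) < 3L) stop("need >= 3 birds with both lesion extent and metrics")
  ext <- per_bird_extent[m$bird_id]
  cols <- setdiff(names(m), "bird_id")
  rbindlist(lapply(cols, function(cn) {
    y <- m[[cn]]
    ok <- is.finite(y) & is.finite(ext)
    if (sum(ok) < 3L) stop("need >= 3 finite pairs for metric ", cn)
    if (var(y[ok]) == 0 || var(ext[ok]) == 0)
      stop("zero-variance input: correlation undefined for metric ", cn)
    ct <- cor.test(ext[ok], y[ok], method = "pearson")
    data.table(metric = cn, r = unname(ct$estimate), p = ct$p.value,
               n = as.integer(sum(ok)))
  }))
}

#' Per-bird song metrics for lesion-behavior correlations
#'
#' For each bird: the final pitch change (pooled mean semitones over shift
#' days 12--14), the variance of semitone values across the 3 baseline days,
#' the variance across the final 3 shift days, and the percent increase in
#' variance from baseline to end of shift.
#'
#' @param x A [pitch_dataset()] (typically a combined lesioned cohort).
#' @param end_days Shift-day window for the "final" metrics.
#' @return A data.table with one row per bird.
#' @export
bird_song_metrics <- function(x, end_days = end_of_shift_days(x)) {
  base <- compute_baseline(x)
  fin <- semitone_records(x, "shift", end_days, base)
  bl <- semitone_records(x, "baseline", baseline_days_of(x$timeline), base)
  f <- fin[, .(final_pitch_change = mean(st), final_variance = var(st)),
           by = bird_id]
  b <- bl[, .(baseline_variance = var(st)), by = bird_id]
  out <- b[f, on = "bird_id"]
  out[, percent_increase_variance :=
        100 * (final_variance - baseline_variance) / baseline_variance]
  out[]
}
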