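#' Prepare a dataset for the hierarchical bootstrap
#'
#' Collects, per syllable, the raw-Hz iteration pools the resampler draws
#' from: the baseline pool (last 3 baseline days), the analysis-window pool,
#' and -- for the washout variant -- the reference pool from the syllable's
#' last shift day with records. Only syllables with records in the window are
#' kept; in washout mode, only birds with washout-window records enter.
#'
#' @param x A [pitch_dataset()].
#' @param epoch Epoch of the analysis window.
#' @param days Days within the epoch (`NULL` = whole epoch).
#' @param washout Logical: prepare the washout (reference-subtracting)
#'   variant? Requires `epoch = "washout"`.
#' @return A list of pools and nesting indices, class `hb_prep`.
#' @export
hb_prepare <- function(x, epoch = "shift", days = NULL, washout = FALSE) {
  stopifnot(inherits(x, "pitch_dataset"))
  if (washout && epoch != "washout")
    stop("washout preparation requires epoch = 'washout'")
  w <- select_window(x, epoch, days)
  if (!nrow(w)) stop(sprintf("no records in epoch '%s' for the given days", epoch))
  syls <- unique(w[, .(bird_id, syllable_id)])
  setkey(syls, bird_id, syllable_id)
  base_days <- baseline_days_of(x$timeline)
  br <- x$records[epoch == "baseline" & day %in% base_days]
  base_pool <- br[syls, on = c("bird_id", "syllable_id"),
                  .(bird_id, syllable_id, pitch_hz)]
  if (anyNA(base_pool$pitch_hz))
    stop("window syllable(s) lack baseline records")
  key <- function(d) paste(d$bird_id, d$syllable_id, sep = "\r")
  syl_keys <- key(syls)
  base <- split(base_pool$pitch_hz, factor(key(base_pool), levels = syl_keys))
  winp <- split(w$pitch_hz, factor(key(w), levels = syl_keys))
  ref <- NULL
  if (washout) {
    sh <- x$records[epoch == "shift"][syls, on = c("bird_id", "syllable_id")]
    if (anyNA(sh$pitch_hz))
      stop("washout syllable(s) have no shift-epoch records")
    refp <- sh[, .SD[day == max(day), .(pitch_hz)], by = .(bird_id, syllable_id)]
    ref <- split(refp$pitch_hz, factor(key(refp), levels = syl_keys))
  }
  birds <- unique(syls$bird_id)
  syl_bird <- match(syls$bird_id, birds)
  ord <- order(syl_bird)
  structure(list(
    birds = birds,
    syllables = syls,
    base = base, win = winp, ref = ref,
    # CSR-style layout: syllable indices (0-based) grouped by bird
    bird_syls_ptr = c(0L, cumsum(tabulate(syl_bird, length(birds)))),
    syl_of_bird = as.integer(ord - 1L)),
    class = "hb_prep")
}

#' One hierarchical resample
#'
#' Draws a single subsample by resampling birds, then syllables within each
#' drawn bird, then iterations within each drawn syllable, with per-syllable
#' iteration counts fixed at `m_base`/`m_win` (and `m_ref` in washout mode)
#' independent of how often the syllable was actually sung -- each syllable is
#' treated as equally likely in a hypothetical new bird. Baselines are
#' recomputed from the resampled baseline iterations and Hz values are
#' converted to semitones only when the subsample mean is taken. Consumes the
#' current RNG stream; pure R, draw-for-draw identical to the compiled engine
#' used by [hb_bootstrap()].
#'
#' @param x A [pitch_dataset()] or a prepared [hb_prepare()] object.
#' @inheritParams hb_prepare
#' @param m_base,m_win,m_ref Equalized iteration counts per drawn syllable.
#' @return The subsample mean, in semitones.
#' @export
hb_resample_once <- function(x, epoch = "shift", days = NULL,
                             m_base = 50L, m_win = 50L, m_ref = 50L,
                             washout = FALSE) {
  prep <- if (inherits(x, "hb_prep")) x else hb_prepare(x, epoch, days, washout)
  washout <- !is.null(prep$ref)
  n_birds <- length(prep$birds)
  draw <- function(pool, m) pool[floor(runif(m) * length(pool)) + 1L]
  tot <- 0; cnt <- 0L
  for (b in seq_len(n_birds)) {
    k <- floor(runif(1L) * n_birds) + 1L
    idx <- prep$syl_of_bird[(prep$bird_syls_ptr[k] + 1L):prep$bird_syls_ptr[k + 1L]] + 1L
    for (t in seq_along(idx)) {
      s <- idx[floor(runif(1L) * length(idx)) + 1L]
      bmean <- mean(draw(prep$base[[s]], m_base))
      ref_st <- if (washout)
        hz_to_semitones(mean(draw(prep$ref[[s]], m_ref)), bmean) else 0
      st <- hz_to_semitones(draw(prep$win[[s]], m_win), bmean) - ref_st
      tot <- tot + sum(st)
      cnt <- cnt + length(st)
    }
  }
  tot / cnt
}

new_hb_boot <- function(resampled, point_estimate, seed, statistic, window) {
  structure(list(
    resampled_means = resampled,
    n_resamples = length(resampled),
    point_estimate = point_estimate,
    sem = sd(resampled),
    ci67 = unname(quantile(resampled, c(0.165, 0.835))),
    seed = seed, statistic = statistic, window = window),
    class = "hb_boot")
}

#' @export
print.hb_boot <- function(x, ...) {
  cat(sprintf(
    "<hb_boot> %s (%s): %.4f st, hierarchical SEM %.4f, 67%% CI [%.4f, %.4f] (N = %d)\n",
    x$statistic, x$window, x$point_estimate, x$sem, x$ci67[1], x$ci67[2],
    x$n_resamples))
  invisible(x)
}

#' Hierarchical bootstrap of a group mean pitch change
#'
#' Generates `n_resamples` subsample means via the three-level resampling
#' scheme of [hb_resample_once()]. The standard deviation of the resampled
#' means estimates the standard error of the group mean with uncertainty
#' propagated from all three levels of the hierarchy; the central 67%
#' interval of the resampled means is reported alongside as the uncertainty
#' interval (comparable to +/- 1 SEM). The point estimate is the
#' frequency-weighted group mean of the actual data, not a bootstrap
#' quantity -- resampling only informs the uncertainty.
#'
#' @param x A [pitch_dataset()].
#' @param epoch,days Analysis window (default: end of shift, days 12--14).
#' @param n_resamples Number of resamples (10^4 by default).
#' @param m_base,m_win Equalized per-syllable iteration counts.
#' @param seed RNG seed for the resampling stream.
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; identical draws, much slower).
#' @return An object of class `hb_boot` with elements `resampled_means`,
#'   `n_resamples`, `point_estimate`, `sem`, `ci67`, `seed`.
#' @export
hb_bootstrap <- function(x, epoch = "shift", days = end_of_shift_days(x),
                         n_resamples = 10000L, m_base = 50L, m_win = 50L,
                         seed = 1L, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (n_resamples < 2L) stop("n_resamples must be >= 2")
  prep <- hb_prepare(x, epoch, days, washout = FALSE)
  point <- weighted_group_mean(x, epoch, days)
  set.seed(seed)
  res <- if (engine == "cpp")
    .hb_engine(prep$base, prep$win, list(), prep$bird_syls_ptr,
               prep$syl_of_bird, as.integer(n_resamples),
               as.integer(m_base), as.integer(m_win), 0L, FALSE)
  else
    vapply(seq_len(n_resamples), function(i)
      hb_resample_once(prep, m_base = m_base, m_win = m_win), numeric(1))
  new_hb_boot(res, point, seed, "group mean pitch change",
              sprintf("%s days %s", epoch, paste(range(days), collapse = "-")))
}

#' Hierarchical bootstrap of the washout pitch change
#'
#' As [hb_bootstrap()], over a washout-day window, but each subsample
#' additionally resamples `m_ref` iterations of the syllable's last shift day
#' with records, recomputes that reference mean within the subsample, and
#' returns mean(washout semitones) minus the reference mean in semitones --
#' so the uncertainty of the reference-day mean propagates into the washout
#' estimate. The point estimate is the [washout_group_mean()] of the actual
#' data. Only birds with washout records in the window enter.
#'
#' @inheritParams hb_bootstrap
#' @param days Washout days (default: last 2).
#' @param m_ref Equalized reference-day iteration count.
#' @return An `hb_boot` object.
#' @export
hb_bootstrap_washout <- function(x, days = end_of_washout_days(x),
                                 n_resamples = 10000L, m_base = 50L,
                                 m_win = 50L, m_ref = 50L, seed = 1L,
                                 engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (n_resamples < 2L) stop("n_resamples must be >= 2")
  prep <- hb_prepare(x, "washout", days, washout = TRUE)
  deltas <- washout_delta(x)
  point <- washout_group_mean(deltas, days)
  set.seed(seed)
  res <- if (engine == "cpp")
    .hb_engine(prep$base, prep$win, prep$ref, prep$bird_syls_ptr,
               prep$syl_of_bird, as.integer(n_resamples),
               as.integer(m_base), as.integer(m_win), as.integer(m_ref), TRUE)
  else
    vapply(seq_len(n_resamples), function(i)
      hb_resample_once(prep, m_base = m_base, m_win = m_win, m_ref = m_ref),
      numeric(1))
  new_hb_boot(res, point, seed, "washout pitch change",
              sprintf("washout days %s", paste(range(days), collapse = "-")))
}

#' Naive pooled standard error of the mean
#'
#' `sd / sqrt(n)` over all semitone records pooled, ignoring the nesting --
#' the estimator the hierarchical bootstrap exists to correct. Exposed for
#' comparison and for the hierarchy-sensitivity diagnostics.
#'
#' @inheritParams hb_bootstrap
#' @return A single value, semitones.
#' @export
naive_pooled_sem <- function(x, epoch = "shift", days = end_of_shift_days(x)) {
  w <- semitone_records(x, epoch, days)
  sd(w$st) / sqrt(nrow(w))
}

#' Serialize a bootstrap result
#'
#' Writes point estimate, SEM, 67% CI, resample count and seed as JSON; the
#' full resampled-means vector can be written alongside as CSV for audit.
#'
#' @param x An `hb_boot`.
#' @param path JSON path.
#' @param means_csv Optional CSV path for the resampled means.
#' @export
write_boot_json <- function(x, path, means_csv = NULL) {
  stopifnot(inherits(x, "hb_boot"))
  jsonlite::write_json(
    list(statistic = x$statistic, window = x$window,
         point_estimate = x$point_estimate, sem = x$sem,
         ci67 = x$ci67, n_resamples = x$n_resamples, seed = x$seed),
    path, auto_unbox = TRUE, digits = NA)
  if (!is.null(means_csv))
    fwrite(data.table(resampled_mean = x$resampled_means), means_csv)
  invisible(path)
}
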