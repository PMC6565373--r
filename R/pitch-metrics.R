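#' Convert frequency to semitones relative to a baseline
#'
#' The semitone change is `12 * log2(pitch_hz / baseline_hz)`: a dimensionless
#' log-frequency measure that makes syllables with very different base
#' frequencies comparable (12 semitones per octave).
#'
#' @param pitch_hz Observed pitch in Hz (> 0).
#' @param baseline_hz Reference pitch in Hz (> 0). Recycled against `pitch_hz`.
#' @return Numeric vector of semitone values.
#' @export
hz_to_semitones <- function(pitch_hz, baseline_hz) {
  if (any(!is.finite(pitch_hz)) || any(pitch_hz <= 0))
    stop("pitch_hz must be positive and finite")
  if (any(!is.finite(baseline_hz)) || any(baseline_hz <= 0))
    stop("baseline_hz must be positive and finite")
  12 * log2(pitch_hz / baseline_hz)
}

baseline_days_of <- function(timeline) {
  seq.int(timeline$baseline - 2L, timeline$baseline)
}

#' Per-syllable baseline pitch
#'
#' The baseline of a syllable is the arithmetic mean of its pitch (in Hz) over
#' the last 3 days of the baseline epoch. Datasets with longer baseline epochs
#' (one bird had 6 baseline days) use only the final 3 days, treated as
#' equivalent to days 1--3 of a standard baseline.
#'
#' @param x A [pitch_dataset()].
#' @return A data.table with columns `bird_id`, `syllable_id`, `baseline_hz`.
#' @export
compute_baseline <- function(x) {
  stopifnot(inherits(x, "pitch_dataset"))
  days <- baseline_days_of(x$timeline)
  r <- x$records
  base <- r[epoch == "baseline" & day %in% days,
            .(baseline_hz = mean(pitch_hz)), by = .(bird_id, syllable_id)]
  later <- unique(r[epoch != "baseline", .(bird_id, syllable_id)])
  miss <- later[!base, on = c("bird_id", "syllable_id")]
  if (nrow(miss))
    stop("no baseline records (last 3 baseline days) for syllable(s): ",
         paste(sprintf("%s/%s", miss$bird_id, miss$syllable_id), collapse = ", "))
  setkey(base, bird_id, syllable_id)
  base[]
}

# Records in a window joined with their syllable baselines, plus semitones.
semitone_records <- function(x, epoch = "shift", days = NULL, baseline = NULL) {
  if (is.null(baseline)) baseline <- compute_baseline(x)
  w <- select_window(x, epoch, days)
  w <- baseline[w, on = c("bird_id", "syllable_id")]
  if (anyNA(w$baseline_hz))
    stop("window contains syllables without a computable baseline")
  w[, st := hz_to_semitones(pitch_hz, baseline_hz)]
  w[]
}

#' Frequency-weighted group mean pitch change
#'
#' Converts each record in the window to semitones against its syllable
#' baseline and averages. The default pools all records across birds, which
#' weights every syllable by the proportion of times it was sung -- syllables
#' sung more often were exposed more often to the shifted feedback.
#' `method = "per_bird"` instead averages per-bird means (each bird weighted
#' equally), retained as an alternative convention.
#'
#' @param x A [pitch_dataset()].
#' @param epoch Epoch of the analysis window.
#' @param days Days within the epoch; defaults to the whole epoch.
#' @param method `"pooled"` (frequency-weighted, default) or `"per_bird"`.
#' @param baseline Optional precomputed [compute_baseline()] table.
#' @return A single semitone value.
#' @export
weighted_group_mean <- function(x, epoch = "shift", days = NULL,
                                method = c("pooled", "per_bird"),
                                baseline = NULL) {
  method <- match.arg(method)
  w <- semitone_records(x, epoch, days, baseline)
  if (!nrow(w))
    stop(sprintf("no records in epoch '%s' for the requested days", epoch))
  if (method == "pooled") mean(w$st)
  else mean(w[, .(m = mean(st)), by = bird_id]$m)
}

#' Daily mean pitch-change trajectory
#'
#' [weighted_group_mean()] evaluated for every day of the timeline, in epoch
#' order. Days on which no records exist (a bird may not sing at all on a
#' given day) are emitted as `NA`.
#'
#' @inheritParams weighted_group_mean
#' @return A data.table with columns `epoch`, `day`, `mean_st`, `n_records`.
#' @export
daily_trajectory <- function(x, method = c("pooled", "per_bird")) {
  method <- match.arg(method)
  base <- compute_baseline(x)
  grid <- rbindlist(lapply(EPOCHS, function(ep) {
    if (x$timeline[[ep]] < 1L) return(NULL)
    data.table(epoch = ep, day = seq_len(x$timeline[[ep]]))
  }))
  grid[, `:=`(mean_st = NA_real_, n_records = 0L)]
  for (i in seq_len(nrow(grid))) {
    w <- select_window(x, grid$epoch[i], grid$day[i])
    if (nrow(w) == 0L) next
    set(grid, i, "n_records", nrow(w))
    set(grid, i, "mean_st",
        weighted_group_mean(x, grid$epoch[i], grid$day[i], method, base))
  }
  grid[]
}

#' Pitch change during washout relative to the end of shift
#'
#' Re-expresses every washout record as the semitone deviation from its own
#' syllable's mean pitch on the last day of the shift epoch. A syllable with
#' no records on the final shift day falls back to its most recent shift day
#' with records (birds occasionally skip singing for a day).
#'
#' @param x A [pitch_dataset()] with washout records.
#' @return A data.table of class `washout_delta` with columns `bird_id`,
#'   `syllable_id`, `day` (washout day), `delta_st`, `ref_day` (the shift day
#'   used as reference) and `pitch_hz`.
#' @export
washout_delta <- function(x) {
  stopifnot(inherits(x, "pitch_dataset"))
  wash <- select_window(x, "washout")
  if (!nrow(wash)) stop("dataset has no washout records")
  shift <- select_window(x, "shift")
  syls <- unique(wash[, .(bird_id, syllable_id)])
  miss <- syls[!unique(shift[, .(bird_id, syllable_id)]),
               on = c("bird_id", "syllable_id")]
  if (nrow(miss))
    stop("no shift-epoch records for washout syllable(s): ",
         paste(sprintf("%s/%s", miss$bird_id, miss$syllable_id), collapse = ", "))
  ref <- shift[syls, on = c("bird_id", "syllable_id")][
    , .SD[day == max(day), .(ref_hz = mean(pitch_hz), ref_day = day[1L])],
    by = .(bird_id, syllable_id)]
  out <- ref[wash, on = c("bird_id", "syllable_id")]
  out[, delta_st := hz_to_semitones(pitch_hz, ref_hz)]
  out <- out[, .(bird_id, syllable_id, day, delta_st, ref_day, pitch_hz)]
  setattr(out, "timeline", x$timeline)
  setattr(out, "class", c("washout_delta", class(out)))
  out[]
}

#' Group mean washout change
#'
#' Pooled mean of [washout_delta()] values over a washout-day window
#' (default: the last 2 washout days).
#'
#' @param x A [pitch_dataset()] or a [washout_delta()] table.
#' @param days Washout days to average over; defaults to the final 2 days.
#' @return A single semitone value.
#' @export
washout_group_mean <- function(x, days = NULL) {
  d <- if (inherits(x, "washout_delta")) x else washout_delta(x)
  if (is.null(days)) {
    tl <- attr(d, "timeline")
    days <- seq.int(tl$washout - 1L, tl$washout)
  }
  v <- d$delta_st[d$day %in% as.integer(days)]
  if (!length(v)) stop("no washout records in the requested days")
  mean(v)
}
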