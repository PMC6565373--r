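#' Experiment timeline
#'
#' Epoch lengths, in days, of a headphones pitch-shift experiment. Days are
#' 1-based within each epoch.
#'
#' @param baseline,shift,washout Number of days in each epoch.
#' @return A list of class `pitch_timeline`.
#' @export
pitch_timeline <- function(baseline = 3L, shift = 14L, washout = 6L) {
  tl <- list(baseline = as.integer(baseline), shift = as.integer(shift),
             washout = as.integer(washout))
  if (tl$baseline < 3L)
    stop("baseline epoch must span at least 3 days (the baseline window)")
  if (tl$shift < 1L || tl$washout < 0L)
    stop("invalid timeline: shift >= 1 and washout >= 0 days required")
  structure(tl, class = "pitch_timeline")
}

EPOCHS <- c("baseline", "shift", "washout")

#' Nested pitch dataset
#'
#' One row per syllable iteration, with full nesting labels. This is the
#' universal input table: every metric and every resampling scheme in the
#' package consumes it. Pitches are stored in Hz and converted to semitones
#' lazily, never destructively, because the hierarchical bootstrap must
#' resample raw Hz values and recompute baselines per subsample.
#'
#' @param records A data.frame with columns `bird_id`, `syllable_id`, `day`
#'   (1-based within epoch), `epoch` (one of baseline/shift/washout) and
#'   `pitch_hz` (> 0).
#' @param timeline A [pitch_timeline()].
#' @param group_label Experimental group tag, e.g. `"unlesioned_plus1"`.
#' @param truth Optional generator ground truth ([generator_truth()]) the
#'   records were simulated from; carried along for parameter-recovery tests.
#' @return An object of class `pitch_dataset`.
#' @export
pitch_dataset <- function(records, timeline = pitch_timeline(),
                          group_label = NA_character_, truth = NULL) {
  records <- as.data.table(records)
  need <- c("bird_id", "syllable_id", "day", "epoch", "pitch_hz")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records lack required columns: ", paste(miss, collapse = ", "))
  records <- records[, need, with = FALSE]
  records[, `:=`(bird_id = as.character(bird_id),
                 syllable_id = as.character(syllable_id),
                 day = as.integer(day),
                 epoch = as.character(epoch),
                 pitch_hz = as.numeric(pitch_hz))]
  x <- structure(list(records = records, timeline = timeline,
                      group_label = group_label, truth = truth),
                 class = "pitch_dataset")
  validate_pitch_dataset(x)
  x
}

validate_pitch_dataset <- function(x) {
  r <- x$records
  if (any(!is.finite(r$pitch_hz)) || any(r$pitch_hz <= 0))
    stop("pitch_hz must be positive and finite")
  bad <- setdiff(unique(r$epoch), EPOCHS)
  if (length(bad))
    stop("unknown epoch label(s): ", paste(bad, collapse = ", "))
  for (ep in EPOCHS) {
    d <- r$day[r$epoch == ep]
    if (length(d) && (min(d) < 1L || max(d) > x$timeline[[ep]]))
      stop(sprintf("days in epoch '%s' outside 1..%d", ep, x$timeline[[ep]]))
  }
  invisible(x)
}

#' @export
print.pitch_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<pitch_dataset> group=%s: %d records, %d birds, %d syllables\n",
              x$group_label, nrow(r), uniqueN(r$bird_id),
              uniqueN(r[, .(bird_id, syllable_id)])))
  cat(sprintf("  timeline: %d d baseline / %d d shift / %d d washout\n",
              x$timeline$baseline, x$timeline$shift, x$timeline$washout))
  invisible(x)
}

#' Subset records to a day window within an epoch
#'
#' @param x A [pitch_dataset()].
#' @param epoch Epoch name.
#' @param days Integer days within the epoch; `NULL` keeps the whole epoch.
#' @return A data.table of the matching records.
#' @export
select_window <- function(x, epoch = "shift", days = NULL) {
  stopifnot(inherits(x, "pitch_dataset"), epoch %in% EPOCHS)
  keep <- x$records$epoch == epoch
  if (!is.null(days)) keep <- keep & x$records$day %in% as.integer(days)
  x$records[which(keep)]
}

#' Conventional analysis windows
#'
#' "End of shift" means shift days 12--14 and "end of washout" the final two
#' washout days; both follow the reporting convention of the study design and
#' are relative to the dataset's own timeline (so a 14-day shift yields days
#' 12:14, and a 7-day washout days 6:7).
#'
#' @param x A [pitch_dataset()] (or a [pitch_timeline()]).
#' @param n_days Width of the window in days.
#' @return Integer vector of days within the epoch.
#' @export
end_of_shift_days <- function(x, n_days = 3L) {
  tl <- if (inherits(x, "pitch_timeline")) x else x$timeline
  seq.int(tl$shift - n_days + 1L, tl$shift)
}

#' @rdname end_of_shift_days
#' @export
end_of_washout_days <- function(x, n_days = 2L) {
  tl <- if (inherits(x, "pitch_timeline")) x else x$timeline
  seq.int(tl$washout - n_days + 1L, tl$washout)
}

#' Read / write pitch tables
#'
#' CSV with header `bird_id,syllable_id,day,epoch,pitch_hz`; days are 1-based
#' within epoch, UTF-8, no index column. The timeline is inferred from the
#' maximum day per epoch unless supplied.
#'
#' @param path File path.
#' @param timeline Optional [pitch_timeline()]; inferred from the data if `NULL`.
#' @param group_label Group tag attached to the returned dataset.
#' @return `read_pitch_csv()` a [pitch_dataset()]; `write_pitch_csv()` the path,
#'   invisibly.
#' @export
read_pitch_csv <- function(path, timeline = NULL, group_label = NA_character_) {
  r <- fread(path, colClasses = list(character = c("bird_id", "syllable_id", "epoch")))
  if (is.null(timeline)) {
    mx <- function(ep) if (any(r$epoch == ep)) max(r$day[r$epoch == ep]) else 0L
    timeline <- pitch_timeline(max(3L, mx("baseline")), max(1L, mx("shift")), mx("washout"))
  }
  pitch_dataset(r, timeline, group_label = group_label)
}

#' @rdname read_pitch_csv
#' @param x A [pitch_dataset()].
#' @export
write_pitch_csv <- function(x, path) {
  stopifnot(inherits(x, "pitch_dataset"))
  fwrite(x$records, path)
  invisible(path)
}
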