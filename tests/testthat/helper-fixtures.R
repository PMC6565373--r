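# Hand-built datasets and small-cohort truths used across tests.

# Build a pitch_dataset from compact row specs:
# rows = list(list(bird, syl, epoch, day, hz, n = 1), ...)
make_dataset <- function(rows, timeline = pitch_timeline(3L, 14L, 6L),
                         group_label = "test") {
  rec <- data.table::rbindlist(lapply(rows, function(r) {
    n <- if (length(r) >= 6L) r[[6]] else 1L
    data.table::data.table(bird_id = r[[1]], syllable_id = r[[2]],
                           epoch = r[[3]], day = as.integer(r[[4]]),
                           pitch_hz = rep(as.numeric(r[[5]]), length.out = max(n, length(r[[5]]))))
  }))
  pitch_dataset(rec, timeline, group_label)
}

# A constant-pitch dataset: every record of every syllable at its baseline.
constant_dataset <- function(n_birds = 2L, n_syl = 2L, hz = c(1000, 2000, 3000, 4000),
                             timeline = pitch_timeline(3L, 14L, 6L), n_per_day = 5L) {
  rows <- list()
  for (b in seq_len(n_birds)) for (s in seq_len(n_syl)) {
    f0 <- hz[(b - 1L) * n_syl + s]
    for (ep in c("baseline", "shift", "washout")) {
      nd <- timeline[[ep]]
      if (nd < 1L) next
      for (d in seq_len(nd))
        rows[[length(rows) + 1L]] <-
          list(paste0("b", b), paste0("s", s), ep, d, f0, n_per_day)
    }
  }
  make_dataset(rows, timeline)
}

# Small fast cohort truth for property loops.
small_truth <- function(seed, n_birds = 4L, plateau_drift = -0.28, ...) {
  generator_truth(group_label = "small", n_birds = n_birds,
                  drift_asymptote = plateau_drift,
                  syllables_per_bird_range = c(3L, 5L),
                  iterations_per_day_range = c(20L, 40L),
                  seed = seed, ...)
}

semitone_ratio <- function(st) 2^(st / 12)
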