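test_that("syllable baselines are arithmetic means over the last 3 baseline days", {
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100),
    list("b1", "s1", "baseline", 2, 110),
    list("b1", "s1", "baseline", 3, 120),
    list("b1", "s2", "baseline", 1, 2500, 4),
    list("b1", "s2", "baseline", 3, 2500, 2)))
  base <- compute_baseline(d)
  expect_equal(base[syllable_id == "s1", baseline_hz], 110)
  expect_equal(base[syllable_id == "s2", baseline_hz], 2500)
})

test_that("extended baselines use only the final 3 days", {
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100), list("b1", "s1", "baseline", 2, 100),
    list("b1", "s1", "baseline", 3, 100), list("b1", "s1", "baseline", 4, 200),
    list("b1", "s1", "baseline", 5, 200), list("b1", "s1", "baseline", 6, 200)),
    timeline = pitch_timeline(6L, 14L, 6L))
  expect_equal(compute_baseline(d)$baseline_hz, 200)
})

test_that("a syllable appearing after baseline without baseline records is a hard error", {
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 3, 100),
    list("b1", "s1", "shift", 1, 100),
    list("b1", "s9", "shift", 1, 500)))
  expect_error(compute_baseline(d), "s9")
})

test_that("semitone conversion follows 12*log2(pitch/baseline)", {
  expect_identical(hz_to_semitones(440, 440), 0)
  expect_equal(hz_to_semitones(220 * 2^(1 / 12), 220), 1.0, tolerance = 1e-12)
  expect_equal(hz_to_semitones(220, 110), 12.0, tolerance = 1e-12)
  expect_error(hz_to_semitones(0, 100), "positive")
  expect_error(hz_to_semitones(100, -1), "positive")
})

test_that("semitone conversion is antisymmetric and additive over chained ratios", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(1, 50, 5000); b <- runif(1, 0.25, 4)
    expect_equal(hz_to_semitones(a * b, a) + hz_to_semitones(a, a * b), 0,
                 tolerance = 1e-9)
    p <- runif(3, 100, 8000)
    expect_equal(hz_to_semitones(p[1], p[2]) + hz_to_semitones(p[2], p[3]),
                 hz_to_semitones(p[1], p[3]), tolerance = 1e-9)
  }
})

test_that("group means pool records, weighting syllables by how often they are sung", {
  # one bird, two syllables: 10 records at +1 st, 30 records at -1 st -> -0.5
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100, 5),
    list("b1", "s2", "baseline", 1, 200, 5),
    list("b1", "s1", "shift", 12, 100 * semitone_ratio(1), 10),
    list("b1", "s2", "shift", 12, 200 * semitone_ratio(-1), 30)))
  expect_equal(weighted_group_mean(d, "shift", 12), -0.5, tolerance = 1e-12)
  # per-bird alternative weights each bird equally instead
  d2 <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100, 5),
    list("b2", "s1", "baseline", 1, 200, 5),
    list("b1", "s1", "shift", 12, 100 * semitone_ratio(1), 90),
    list("b2", "s1", "shift", 12, 200 * semitone_ratio(-1), 10)))
  expect_equal(weighted_group_mean(d2, "shift", 12), 0.8, tolerance = 1e-12)
  expect_equal(weighted_group_mean(d2, "shift", 12, method = "per_bird"), 0,
               tolerance = 1e-12)
  expect_error(weighted_group_mean(d2, "shift", 9), "no records")
})

test_that("records at their syllable baselines give exactly zero group mean", {
  d <- constant_dataset()
  expect_identical(weighted_group_mean(d, "shift", 12:14), 0)
  tr <- daily_trajectory(d)
  expect_true(all(tr$mean_st == 0))
})

test_that("daily trajectories mark silent days as missing and track a noiseless ramp", {
  d <- constant_dataset(timeline = pitch_timeline(3L, 5L, 0L))
  d$records <- d$records[!(epoch == "shift" & day == 2L)]
  tr <- daily_trajectory(d)
  expect_true(is.na(tr[epoch == "shift" & day == 2L, mean_st]))
  expect_equal(tr[epoch == "shift" & day == 2L, n_records], 0L)
  # noiseless adaptation ramp: trajectory equals the latent curve
  truth <- generator_truth(n_birds = 2L, adapt_asymptote = 1, adapt_timescale = 5,
                           sigma_bird = 0, sigma_syllable = 0, sigma_iteration = 0,
                           syllables_per_bird_range = c(2L, 2L),
                           iterations_per_day_range = c(10L, 10L), seed = 7L)
  tr2 <- daily_trajectory(generate_experiment(truth))
  ramp <- 1 - exp(-(1:14) / 5)
  expect_equal(tr2[epoch == "shift", mean_st], ramp, tolerance = 1e-9)
  expect_true(all(diff(tr2[epoch == "shift", mean_st]) > 0))
})

test_that("washout deltas subtract each syllable's last-shift-day mean", {
  base <- list(list("b1", "s1", "baseline", 1, 100, 3),
               list("b1", "s2", "baseline", 1, 200, 3))
  # washout identical to the last shift day -> all zeros
  d0 <- make_dataset(c(base, list(
    list("b1", "s1", "shift", 14, 150, 4),
    list("b1", "s1", "washout", 1, 150, 4),
    list("b1", "s1", "washout", 6, 150, 4))))
  expect_true(all(washout_delta(d0)$delta_st == 0))
  # +1 st reference, washout at baseline -> delta -1; second syllable distinct
  d1 <- make_dataset(c(base, list(
    list("b1", "s1", "shift", 14, 100 * semitone_ratio(1), 4),
    list("b1", "s2", "shift", 14, 200 * semitone_ratio(0.5), 4),
    list("b1", "s1", "washout", 5, 100, 2),
    list("b1", "s2", "washout", 5, 200, 2))))
  w <- washout_delta(d1)
  expect_equal(w[syllable_id == "s1", unique(delta_st)], -1, tolerance = 1e-9)
  expect_equal(w[syllable_id == "s2", unique(delta_st)], -0.5, tolerance = 1e-9)
  expect_equal(washout_group_mean(d1, days = 5), -0.75, tolerance = 1e-9)
})

test_that("washout reference falls back to the most recent shift day with records", {
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100, 3),
    list("b1", "s1", "shift", 11, 100 * semitone_ratio(2), 4),
    list("b1", "s1", "washout", 1, 100 * semitone_ratio(2), 4)))
  w <- washout_delta(d)
  expect_equal(unique(w$ref_day), 11L)
  expect_true(all(w$delta_st == 0))
  d2 <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100, 3),
    list("b1", "s1", "washout", 1, 100, 4)))
  expect_error(washout_delta(d2), "no shift-epoch records")
})

test_that("pitch CSV round-trips with schema and values intact", {
  d <- generate_experiment(small_truth(11L, n_birds = 2L))
  f <- tempfile(fileext = ".csv")
  write_pitch_csv(d, f)
  hdr <- readLines(f, n = 1L)
  expect_identical(hdr, "bird_id,syllable_id,day,epoch,pitch_hz")
  d2 <- read_pitch_csv(f, timeline = d$timeline, group_label = d$group_label)
  expect_equal(as.data.frame(d2$records), as.data.frame(d$records))
  expect_equal(weighted_group_mean(d2, "shift", 12:14),
               weighted_group_mean(d, "shift", 12:14))
  unlink(f)
})
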