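test_that("generation is deterministic given truth and seed", {
  tr <- small_truth(42L)
  d1 <- generate_experiment(tr)
  d2 <- generate_experiment(tr)
  expect_identical(as.data.frame(d1$records), as.data.frame(d2$records))
  f1 <- tempfile(); f2 <- tempfile()
  write_pitch_csv(d1, f1); write_pitch_csv(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
  d3 <- generate_experiment(small_truth(43L))
  expect_false(identical(as.data.frame(d1$records), as.data.frame(d3$records)))
})

test_that("per-bird streams are independent: adding birds leaves earlier birds unchanged", {
  d3 <- generate_experiment(small_truth(7L, n_birds = 3L))
  d4 <- generate_experiment(small_truth(7L, n_birds = 4L))
  first3 <- d4$records[bird_id %in% unique(d3$records$bird_id)]
  expect_identical(as.data.frame(first3), as.data.frame(d3$records))
})

test_that("a silent truth produces records exactly at their syllable baselines", {
  tr <- generator_truth(n_birds = 2L, drift_asymptote = 0, adapt_asymptote = 0,
                        sigma_bird = 0, sigma_syllable = 0, sigma_iteration = 0,
                        syllables_per_bird_range = c(2L, 3L),
                        iterations_per_day_range = c(5L, 10L), seed = 3L)
  d <- generate_experiment(tr)
  tr_daily <- daily_trajectory(d)
  expect_true(all(abs(tr_daily$mean_st[!is.na(tr_daily$mean_st)]) < 1e-12))
  per_syl <- d$records[, .(n_hz = uniqueN(pitch_hz)), by = .(bird_id, syllable_id)]
  expect_true(all(per_syl$n_hz == 1L))
})

test_that("an instantaneous drift plateau lowers every pitch by exactly the asymptote", {
  args <- list(n_birds = 1L, drift_timescale = 1e-9, sigma_bird = 0,
               sigma_syllable = 0, sigma_iteration = 0,
               syllables_per_bird_range = c(2L, 2L),
               iterations_per_day_range = c(5L, 5L), seed = 1L)
  d0 <- generate_experiment(do.call(generator_truth, c(args, drift_asymptote = 0)))
  d1 <- generate_experiment(do.call(generator_truth, c(args, drift_asymptote = -1)))
  # same seed, so the cohorts differ only by the latent drift: every pitch
  # sits exactly 1 semitone lower from day 1 on
  expect_equal(hz_to_semitones(d1$records$pitch_hz, d0$records$pitch_hz),
               rep(-1, nrow(d0$records)), tolerance = 1e-9)
  # ...and baseline referencing therefore reads the plateau as zero change
  expect_lt(max(abs(daily_trajectory(d1)$mean_st), na.rm = TRUE), 1e-9)
})

test_that("generated nesting and counts respect the configured ranges", {
  tr <- preset_truth("lesioned_noshift", seed = 5L)
  d <- generate_experiment(tr)
  syl_per_bird <- d$records[, uniqueN(syllable_id), by = bird_id]$V1
  expect_true(all(syl_per_bird >= 4L & syl_per_bird <= 12L))
  counts <- d$records[, .N, by = .(bird_id, syllable_id, epoch, day)]$N
  expect_true(all(counts >= 40L & counts <= 600L))
  base <- compute_baseline(d)
  expect_true(all(base$baseline_hz > 900 & base$baseline_hz < 6600))
  # washout present only for the first n_washout_birds birds
  wb <- unique(d$records[epoch == "washout", bird_id])
  expect_length(wb, tr$n_washout_birds)
})

test_that("variance decomposes across the three levels as configured", {
  # no iteration noise -> within-syllable-day variance is exactly 0
  d0 <- generate_experiment(small_truth(8L, sigma_iteration = 0))
  wvar <- d0$records[, var(pitch_hz), by = .(bird_id, syllable_id, epoch, day)]$V1
  expect_true(all(wvar == 0))
  # no bird/syllable effects -> per-bird plateau means concentrate tightly
  d1 <- generate_experiment(generator_truth(
    n_birds = 6L, drift_asymptote = -0.3, sigma_bird = 0, sigma_syllable = 0,
    sigma_iteration = 0.5, syllables_per_bird_range = c(4L, 6L),
    iterations_per_day_range = c(200L, 400L), seed = 9L))
  base <- compute_baseline(d1)
  w <- base[select_window(d1, "shift", 12:14), on = c("bird_id", "syllable_id")]
  bird_means <- w[, mean(hz_to_semitones(pitch_hz, baseline_hz)), by = bird_id]$V1
  expect_lt(sd(bird_means), 0.02)
})

test_that("presets encode the study cohorts and their printed group effects", {
  plateaus <- c(unlesioned_plus1 = -0.40, unlesioned_minus1 = 0.36,
                unlesioned_noshift = 0, lesioned_plus1 = -0.38,
                lesioned_minus1 = -0.46, lesioned_noshift = -0.19)
  birds <- c(unlesioned_plus1 = 3L, unlesioned_minus1 = 3L,
             unlesioned_noshift = 2L, lesioned_plus1 = 4L,
             lesioned_minus1 = 4L, lesioned_noshift = 8L)
  for (nm in names(plateaus)) {
    tr <- preset_truth(nm, seed = 1L)
    expect_equal(true_plateau(tr), plateaus[[nm]], tolerance = 1e-9)
    expect_identical(tr$n_birds, birds[[nm]])
    if (startsWith(nm, "unlesioned")) {
      expect_identical(tr$drift_asymptote, 0)
      expect_identical(tr$timeline$washout, 6L)
    } else {
      expect_identical(tr$adapt_asymptote, 0)
      expect_identical(tr$timeline$washout, 7L)
    }
  }
  wash <- c(unlesioned_plus1 = 0.17, unlesioned_minus1 = -0.22,
            lesioned_plus1 = 0.24, lesioned_minus1 = -0.28)
  for (nm in names(wash))
    expect_equal(true_washout_delta(preset_truth(nm, seed = 1L)), wash[[nm]],
                 tolerance = 1e-9)
  expect_error(preset_truth("no_such_group"), "unknown preset")
})

test_that("noiseless preset cohorts reproduce their plateau and washout targets", {
  for (nm in c("lesioned_noshift", "unlesioned_plus1")) {
    tr <- preset_truth(nm, seed = 2L, sigma_bird = 0, sigma_syllable = 0,
                       sigma_iteration = 0,
                       iterations_per_day_range = c(30L, 30L))
    d <- generate_experiment(tr)
    expect_equal(weighted_group_mean(d, "shift", 12:14), true_plateau(tr),
                 tolerance = 1e-9)
  }
  trw <- preset_truth("lesioned_plus1", seed = 2L, sigma_bird = 0,
                      sigma_syllable = 0, sigma_iteration = 0,
                      iterations_per_day_range = c(30L, 30L))
  dw <- generate_experiment(trw)
  expect_equal(washout_group_mean(dw), true_washout_delta(trw), tolerance = 1e-9)
})

test_that("degenerate generator configurations are rejected", {
  expect_error(generator_truth(syllables_per_bird_range = c(5L, 2L)), "degenerate")
  expect_error(generator_truth(baseline_f0_range = c(-10, 100)), "degenerate")
  expect_error(generator_truth(sigma_bird = -1), "variance")
  expect_error(generator_truth(drift_timescale = 0), "timescales")
})

test_that("truth echoes round-trip through YAML", {
  tr <- preset_truth("unlesioned_minus1", seed = 13L)
  f <- tempfile(fileext = ".yaml")
  write_truth_yaml(tr, f)
  tr2 <- read_truth_yaml(f)
  unlink(f)
  expect_equal(true_plateau(tr2), true_plateau(tr), tolerance = 1e-12)
  # the echo keeps 15 significant digits, so regenerated pitches agree to
  # numerical precision rather than bit-for-bit
  expect_equal(as.data.frame(generate_experiment(tr2)$records),
               as.data.frame(generate_experiment(tr)$records),
               tolerance = 1e-12)
})
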