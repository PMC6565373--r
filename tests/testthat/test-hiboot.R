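test_that("a dataset at its baselines bootstraps to exactly zero spread", {
  d <- constant_dataset()
  b <- hb_bootstrap(d, n_resamples = 200L, seed = 1L)
  expect_identical(unique(b$resampled_means), 0)
  expect_identical(b$sem, 0)
  expect_equal(b$ci67, c(0, 0))
  expect_identical(b$point_estimate, 0)
})

test_that("degenerate single-syllable resampling returns the exact semitone offset", {
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100, 20),
    list("b1", "s1", "shift", 12, 100 * semitone_ratio(1), 20)))
  b <- hb_bootstrap(d, days = 12, n_resamples = 100L, seed = 2L)
  expect_equal(unique(b$resampled_means), 1.0, tolerance = 1e-12)
})

test_that("bootstrap results are reproducible from the seed", {
  d <- generate_experiment(small_truth(21L))
  b1 <- hb_bootstrap(d, n_resamples = 300L, seed = 5L)
  b2 <- hb_bootstrap(d, n_resamples = 300L, seed = 5L)
  expect_identical(b1$resampled_means, b2$resampled_means)
  b3 <- hb_bootstrap(d, n_resamples = 300L, seed = 6L)
  expect_false(identical(b1$resampled_means, b3$resampled_means))
  # invariants of the result object
  expect_length(b1$resampled_means, 300L)
  expect_gte(b1$sem, 0)
  med <- median(b1$resampled_means)
  expect_lte(b1$ci67[1], med)
  expect_lte(med, b1$ci67[2])
})

test_that("the compiled engine matches the pure-R resampler draw for draw", {
  d <- generate_experiment(small_truth(22L, n_birds = 3L))
  bc <- hb_bootstrap(d, n_resamples = 60L, seed = 9L, engine = "cpp")
  br <- hb_bootstrap(d, n_resamples = 60L, seed = 9L, engine = "r")
  expect_equal(bc$resampled_means, br$resampled_means, tolerance = 1e-12)
  # and a single exported resample continues the same stream
  prep <- hb_prepare(d, "shift", end_of_shift_days(d))
  set.seed(9L)
  expect_equal(hb_resample_once(prep), bc$resampled_means[1], tolerance = 1e-12)
  # washout variant too
  wc <- hb_bootstrap_washout(d, n_resamples = 40L, seed = 9L, engine = "cpp")
  wr <- hb_bootstrap_washout(d, n_resamples = 40L, seed = 9L, engine = "r")
  expect_equal(wc$resampled_means, wr$resampled_means, tolerance = 1e-12)
})

test_that("resampling equalizes syllable frequencies instead of weighting by them", {
  # two syllables at +1 / -1 st with 10 vs 1000 iterations: the weighted mean
  # sits near -1, but equalized subsample means are centered at 0
  d <- make_dataset(list(
    list("b1", "s1", "baseline", 1, 100, 30),
    list("b1", "s2", "baseline", 1, 200, 30),
    list("b1", "s1", "shift", 12, 100 * semitone_ratio(1), 10),
    list("b1", "s2", "shift", 12, 200 * semitone_ratio(-1), 1000)))
  expect_equal(weighted_group_mean(d, "shift", 12), (10 - 1000) / 1010,
               tolerance = 1e-9)
  b <- hb_bootstrap(d, days = 12, n_resamples = 2000L, seed = 3L)
  expect_lt(abs(mean(b$resampled_means)), 0.05)
  expect_equal(b$point_estimate, (10 - 1000) / 1010, tolerance = 1e-9)
})

test_that("for one bird and one syllable the sem matches a flat bootstrap oracle", {
  set.seed(31)
  base_hz <- 2000 * semitone_ratio(rnorm(300, 0, 0.5))
  win_hz <- 2000 * semitone_ratio(rnorm(300, 0.3, 0.5))
  d <- pitch_dataset(data.table::data.table(
    bird_id = "b1", syllable_id = "s1",
    day = c(rep(3L, 300), rep(12L, 300)),
    epoch = rep(c("baseline", "shift"), each = 300),
    pitch_hz = c(base_hz, win_hz)))
  b <- hb_bootstrap(d, days = 12, n_resamples = 4000L, seed = 4L)
  # independent oracle: plain one-level bootstrap of the same statistic
  set.seed(400)
  oracle <- replicate(4000, {
    bs <- sample(base_hz, 50, replace = TRUE)
    ws <- sample(win_hz, 50, replace = TRUE)
    mean(12 * log2(ws / mean(bs)))
  })
  expect_lt(abs(b$sem - sd(oracle)) / sd(oracle), 0.10)
  expect_lt(abs(mean(b$resampled_means) - mean(oracle)), 0.02)
})

test_that("hierarchical sem exceeds the naive pooled SEM when birds truly differ", {
  for (s in 1:20) {
    d <- generate_experiment(small_truth(1000L + s))
    b <- hb_bootstrap(d, n_resamples = 250L, seed = s)
    expect_gt(b$sem, naive_pooled_sem(d))
  }
})

test_that("washout resampling reproduces exact offsets in noiseless data", {
  base <- list(list("b1", "s1", "baseline", 1, 100, 20),
               list("b2", "s1", "baseline", 1, 300, 20))
  d0 <- make_dataset(c(base, list(
    list("b1", "s1", "shift", 14, 150, 20),
    list("b2", "s1", "shift", 14, 330, 20),
    list("b1", "s1", "washout", 5, 150, 10),
    list("b1", "s1", "washout", 6, 150, 10),
    list("b2", "s1", "washout", 5, 330, 10),
    list("b2", "s1", "washout", 6, 330, 10))))
  b0 <- hb_bootstrap_washout(d0, n_resamples = 100L, seed = 1L)
  expect_identical(unique(b0$resampled_means), 0)
  d5 <- make_dataset(c(base, list(
    list("b1", "s1", "shift", 14, 150, 20),
    list("b1", "s1", "washout", 5, 150 * semitone_ratio(0.5), 10),
    list("b1", "s1", "washout", 6, 150 * semitone_ratio(0.5), 10))))
  b5 <- hb_bootstrap_washout(d5, n_resamples = 100L, seed = 1L)
  expect_equal(unique(b5$resampled_means), 0.5, tolerance = 1e-12)
})

test_that("reference-day noise propagates into the washout sem", {
  set.seed(55)
  tr <- small_truth(61L, n_birds = 3L)
  d <- generate_experiment(tr)
  b_noisy <- hb_bootstrap_washout(d, n_resamples = 1500L, seed = 7L)
  # collapse the last shift day of each syllable to its mean: a noiseless
  # reference; everything else identical
  r <- data.table::copy(d$records)
  last <- r[epoch == "shift", .(day = max(day)), by = .(bird_id, syllable_id)]
  for (i in seq_len(nrow(last))) {
    sel <- r$epoch == "shift" & r$bird_id == last$bird_id[i] &
      r$syllable_id == last$syllable_id[i] & r$day == last$day[i]
    r$pitch_hz[sel] <- mean(r$pitch_hz[sel])
  }
  d_fixed <- pitch_dataset(r, d$timeline, d$group_label)
  b_fixed <- hb_bootstrap_washout(d_fixed, n_resamples = 1500L, seed = 7L)
  expect_gt(b_noisy$sem, b_fixed$sem)
})

test_that("bootstrap results serialize to JSON with their provenance", {
  d <- constant_dataset()
  b <- hb_bootstrap(d, n_resamples = 50L, seed = 12L)
  f <- tempfile(fileext = ".json"); fc <- tempfile(fileext = ".csv")
  write_boot_json(b, f, means_csv = fc)
  j <- jsonlite::read_json(f)
  expect_equal(j$point_estimate, 0)
  expect_equal(j$n_resamples, 50L)
  expect_equal(j$seed, 12L)
  expect_equal(nrow(data.table::fread(fc)), 50L)
  unlink(c(f, fc))
})
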