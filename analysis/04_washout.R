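#!/usr/bin/env Rscript
# Washout dynamics: per-syllable pitch change relative to the last shift
# day, averaged over the final two washout days, with reference-resampling
# hierarchical bootstrap. Writes results/washout_summary.csv.

suppressPackageStartupMessages({
  library(songshift)
  library(data.table)
})

seed <- 20260924L
groups <- c("unlesioned_plus1", "unlesioned_minus1", "lesioned_plus1",
            "lesioned_minus1", "lesioned_noshift")
dir.create("results", showWarnings = FALSE)

rows <- list()
for (i in seq_along(groups)) {
  g <- groups[i]
  d <- read_pitch_csv(file.path("results/data", paste0("pitch_", g, ".csv")),
                      group_label = g)
  tr <- read_truth_yaml(file.path("results/data", paste0("truth_", g, ".yaml")))
  b <- hb_bootstrap_washout(d, n_resamples = 10000L, seed = seed + 300L + i)
  pz <- prob_ge_constant(b, 0)
  rows[[g]] <- data.table(
    group = g, washout_delta_st = b$point_estimate,
    truth_st = true_washout_delta(tr), sem = b$sem,
    ci67_lo = b$ci67[1], ci67_hi = b$ci67[2],
    p_ge_zero = pz$probability, rendered = pz$probability_label,
    significant = pz$significant)
  message(sprintf("%-18s washout delta %+0.3f st (SEM %0.3f, truth %+0.2f) %s",
                  g, b$point_estimate, b$sem, true_washout_delta(tr),
                  pz$probability_label))
}
fwrite(rbindlist(rows), "results/washout_summary.csv")
message("wrote results/washout_summary.csv")
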