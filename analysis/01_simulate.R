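#!/usr/bin/env Rscript
# Simulate the six study cohorts at their preset group effects, plus the
# per-section optical-density table, and write everything (with truth
# echoes) under results/data/.

suppressPackageStartupMessages(library(songshift))

seed <- 20260924L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

groups <- c("unlesioned_plus1", "unlesioned_minus1", "unlesioned_noshift",
            "lesioned_plus1", "lesioned_minus1", "lesioned_noshift")

lesioned_birds <- character()
for (i in seq_along(groups)) {
  tr <- preset_truth(groups[i], seed = seed + i)
  d <- generate_experiment(tr)
  write_pitch_csv(d, file.path(out, paste0("pitch_", groups[i], ".csv")))
  write_truth_yaml(tr, file.path(out, paste0("truth_", groups[i], ".yaml")))
  if (startsWith(groups[i], "lesioned"))
    lesioned_birds <- c(lesioned_birds, unique(d$records$bird_id))
  message(sprintf("%-18s %d birds, %6d records, true plateau %+0.2f st",
                  groups[i], tr$n_birds, nrow(d$records), true_plateau(tr)))
}

od_truth <- od_generator_truth(n_lesion_birds = length(lesioned_birds),
                               sections_per_bird = 30L,
                               target_below_threshold_fraction = 0.375,
                               lesion_bird_ids = lesioned_birds,
                               seed = seed + 100L)
od <- generate_od_sections(od_truth)
write_od_csv(od, file.path(out, "od_sections.csv"))
message(sprintf("OD table: %d sections (%d saline + %d lesioned birds)",
                nrow(od), od_truth$n_saline_birds, od_truth$n_lesion_birds))
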