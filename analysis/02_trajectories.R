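#!/usr/bin/env Rscript
# Daily mean pitch-change trajectories per cohort (the daily-trace view of
# the experiment), written to results/trajectories.csv; optional plot if
# ggplot2 is available.

suppressPackageStartupMessages({
  library(songshift)
  library(data.table)
})

groups <- c("unlesioned_plus1", "unlesioned_minus1", "unlesioned_noshift",
            "lesioned_plus1", "lesioned_minus1", "lesioned_noshift")
dir.create("results", showWarnings = FALSE)

traj <- rbindlist(lapply(groups, function(g) {
  d <- read_pitch_csv(file.path("results/data", paste0("pitch_", g, ".csv")),
                      group_label = g)
  cbind(group = g, daily_trajectory(d))
}))
fwrite(traj, "results/trajectories.csv")
message("wrote results/trajectories.csv (", nrow(traj), " group-days)")

end_shift <- traj[epoch == "shift" & day >= 12, .(end_shift_mean = mean(mean_st, na.rm = TRUE)),
                  by = group]
print(end_shift)

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  traj[, t := day + c(baseline = 0L, shift = 3L, washout = 17L)[epoch]]
  p <- ggplot(traj, aes(t, mean_st, colour = group)) +
    geom_hline(yintercept = 0, linetype = 3) +
    geom_vline(xintercept = c(3.5, 17.5), linetype = 2, colour = "grey60") +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "experiment day", y = "pitch change (semitones)",
         title = "Daily group mean pitch change (baseline | shift | washout)") +
    theme_minimal()
  ggsave("results/trajectories.png", p, width = 9, height = 5, dpi = 150)
  message("wrote results/trajectories.png")
}
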