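#!/usr/bin/env Rscript
# Mixed-model validation of the bootstrap inference: nested random-intercept
# LMMs on end-of-shift semitone change, for the unlesioned pair (shift
# direction), the lesioned trio (-1/0/+1 coding) and the pooled
# shift-vs-no-shift contrast. Writes results/lmm_*.json.

suppressPackageStartupMessages(library(songshift))

dir.create("results", showWarnings = FALSE)
load_group <- function(g)
  read_pitch_csv(file.path("results/data", paste0("pitch_", g, ".csv")),
                 group_label = g)

report <- function(name, fit) {
  message(sprintf("%-22s beta1 = %+0.3f st, t = %0.2f, p = %0.3g%s",
                  name, fit$beta1, fit$t_fixed, fit$p_fixed,
                  if (fit$singular) " [singular]" else ""))
  write_lmm_json(fit, file.path("results", paste0("lmm_", name, ".json")))
}

unl <- lapply(c("unlesioned_plus1", "unlesioned_minus1"), load_group)
report("unlesioned_direction",
       fit_pitch_lmm(pitch_lmm_data(unl, c(1, -1))))

les <- lapply(c("lesioned_noshift", "lesioned_plus1", "lesioned_minus1"),
              load_group)
dat <- pitch_lmm_data(les, c(0, 1, -1))
report("lesioned_direction", fit_pitch_lmm(dat))

dat$x <- as.numeric(dat$x != 0)
report("lesioned_pooled_shift", fit_pitch_lmm(dat))
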