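#!/usr/bin/env Rscript
# Behavioral learning curve analysis (repeated-measures ANOVA with
# Greenhouse-Geisser correction over time-on-task bins) and stepwise
# regressions of task accuracy on the EEG measures per group.

suppressPackageStartupMessages(library(plimst))

beh <- read.csv("results/behavior_accuracy.csv")
bins <- as.matrix(beh[, grep("^bin", names(beh))])

an <- rm_anova_gg(bins, groups = beh$group)
message("learning-curve ANOVA (GG-corrected within effects):")
print(an, digits = 3, row.names = FALSE)
write.csv(an, "results/behavior_anova.csv", row.names = FALSE)

subject_level <- read.csv("results/subject_measures.csv")
outcomes <- data.frame(subject_id = beh$subject_id,
                       mean_accuracy = rowMeans(bins))
sw <- stepwise_tables(subject_level, outcomes)
write.csv(sw, "results/stepwise_regressions.csv", row.names = FALSE)
if (nrow(sw) == 0) {
  message("stepwise: no EEG predictor passed entry in either group ",
          "(an empty model is a valid outcome at this sample size)")
} else {
  message("stepwise regression steps:")
  print(sw, digits = 3, row.names = FALSE)
}
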