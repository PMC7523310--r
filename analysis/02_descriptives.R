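#!/usr/bin/env Rscript
# Descriptive tables: per-measure baseline / year-1 summaries by group on the
# native scale, and the weighted repeated-measures correlation between
# measures in the control group (transformed scale).

library(mdchange)

coh <- read_cohort("results/cohort.csv")
specs <- default_measures()

records <- filter_complete_timepoints(coh$records, specs$name)
records <- censor_on_treatment(records, coh$participants)
samples <- build_samples(records, coh$participants)
cat("analysis samples A/B/C:",
    lengths(lapply(samples, `[[`, "participant_ids")), "\n")

table1 <- density_summary_table(samples$A$records, coh$participants,
                                specs$name)
write.csv(table1, "results/table1_descriptives.csv", row.names = FALSE)

chg <- table1[table1$statistic == "T1-T0" & table1$group == "tamoxifen", ]
cat("mean year-1 change in the treated group (native scale):\n")
print(chg[, c("measure", "n", "mean", "sd", "mean_sd")])

transformed <- dplyr::bind_rows(lapply(seq_len(nrow(specs)), function(j) {
  r <- records[records$measure == specs$name[j], ]
  r$value <- transform_value(r$value, specs$transform[j])
  r
}))
ctrl_ids <- coh$participants$id[coh$participants$group == "control"]
ct <- correlation_table(
  transformed[transformed$participant_id %in%
                intersect(ctrl_ids, samples$A$participant_ids), ],
  specs$name
)
write.csv(as.data.frame(ct), "results/table2_correlations.csv")
cat("\nrepeated-measures correlations between measures (controls):\n")
print(round(ct, 2))
cat("minimum off-diagonal correlation:",
    round(min(ct[upper.tri(ct)]), 2), "\n")
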