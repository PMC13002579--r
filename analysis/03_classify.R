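#!/usr/bin/env Rscript
# Step 3: per-participant L1-logistic classifiers for the four chair
# control variables; test-set precision/recall/F, the aggregated
# coefficient-magnitude matrix, and selected-feature separability.

library(stschair)

features <- read.csv("results/features.csv")
analysis <- run_sts_analysis(features, seed = 1L)
print(analysis)

write.csv(analysis$metrics, "results/metrics_per_participant.csv",
          row.names = FALSE)
write.csv(analysis$summary, "results/metrics_summary.csv", row.names = FALSE)
write.csv(data.frame(variable = rownames(analysis$coefficients),
                     analysis$coefficients),
          "results/coefficient_matrix.csv", row.names = FALSE)
write.csv(analysis$eta_table, "results/separability.csv", row.names = FALSE)

eta <- analysis$eta_table[is.finite(analysis$eta_table$eta), ]
speed <- eta$variable %in% c("fwd_speed", "up_speed")
message(sprintf("mean selected-feature eta: speed %.2f vs timing %.2f",
                mean(eta$eta[speed]), mean(eta$eta[!speed])))

dir.create("results/models", showWarnings = FALSE)
for (fit in analysis$fits) {
  for (v in control_variables()) {
    write_model_json(fit$models[[v]],
                     sprintf("results/models/P%02d_%s.json",
                             fit$participant, v))
  }
}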