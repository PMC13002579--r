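#!/usr/bin/env Rscript
# Step 1: simulate the synthetic chair-assisted STS study and export a
# small demonstration subset as CSV, plus the full trial manifest.
#
# The full study (6 participants x 16 conditions x 10 trials) is large as
# raw CSV; downstream steps regenerate trials on the fly from the manifest
# seeds instead of reading them back, so only one participant's first
# condition block is written out here for inspection.

library(stschair)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- generator_config(seed = 1L)
manifest <- simulate_manifest(config)
write.csv(manifest, file.path("results", "manifest.csv"), row.names = FALSE)
message("planned ", nrow(manifest), " trials (",
        config$n_participants, " participants x 16 conditions x ",
        config$trials_per_condition, " trials)")

demo <- manifest[manifest$participant == 1, ][1:4, ]
trials <- lapply(seq_len(nrow(demo)), function(i) {
  generate_trial(unlist(demo[i, control_variables()]), 1, config,
                 seed = demo$seed[i])
})
names(trials) <- demo$trial_id
write_dataset(structure(list(trials = trials, manifest = demo),
                        class = "sts_dataset"), out_dir)
message("wrote ", nrow(demo), " demonstration trials to ", out_dir)
print(trials[[1]])
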