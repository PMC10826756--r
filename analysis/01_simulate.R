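#!/usr/bin/env Rscript
# Step 1: generate the synthetic surveillance dataset used by the later
# steps. Two eras share the same outbreak-generating process (discrete power
# law, alpha = 2.15, ~500 true outbreaks/year) but differ in detection of
# small outbreaks: the floor probability at size 1 rises from 0.2 to 0.5 in
# the second era, emulating a surveillance improvement. Ground truth
# (including the outbreaks that went undetected) is kept alongside.

suppressPackageStartupMessages(library(outbreaklaw))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
sim <- simulate_surveillance(seed = seed)
write_simulation(sim, "results/data/synthetic_outbreaks.csv")

message(sprintf("true outbreaks: %d; observed after size-dependent detection: %d",
                nrow(sim$truth), nrow(sim$records)))
print(sim$era_truth)
utils::write.table(sim$era_truth, "results/data/era_truth.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)
message("wrote results/data/synthetic_outbreaks.csv (+ .truth.json) and era_truth.tsv")
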