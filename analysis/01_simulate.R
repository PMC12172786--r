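#!/usr/bin/env Rscript
# Step 1: generate the synthetic three-study dataset.
#
# The generator mirrors the sample structure of the three source studies
# (29+28 and 20+20 participants with three runs each, 62+33 with one run)
# and plants three signatures with condition effects spanning the range
# seen empirically (strong positive, moderate positive, small negative),
# no group effect, and inter-run reliability around .55. Ground truth is
# written alongside so later steps can be checked against it.

suppressPackageStartupMessages(library(emosig))

seed <- 20240901L
cfg <- sim_preset("three_study",
                  n_signatures = 3,
                  d_within = c(2.0, 0.8, -0.2),
                  d_between = c(0, 0, 0),
                  icc = 0.55,
                  noise_orthogonal_sd = 1,
                  noise_iid_sd = 0.1,
                  seed = seed)

dir.create("results", showWarnings = FALSE)
truth <- simulate_expression(cfg)
write.table(truth, "results/truth.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("truth table: %d rows (%d participants, 3 signatures)\n",
            nrow(truth), length(unique(truth$participant))))

# a small sample of the voxel-level data, as NIfTI, for format inspection
cfg_small <- sim_config(cfg$studies[2], n_signatures = 1,
                        d_within = 2.0, icc = 0.55, seed = seed)
cfg_small$studies[[1]]$n_ed <- 2
cfg_small$studies[[1]]$n_hc <- 2
sim <- simulate_dataset(cfg_small, dir = "results/simulated_sample")
cat(sprintf("wrote %d sample beta maps + signature to results/simulated_sample/\n",
            nrow(sim$manifest)))
cat("done; step 2 scores the full dataset (regenerated from the same seed)\n")
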