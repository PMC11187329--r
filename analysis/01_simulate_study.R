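#!/usr/bin/env Rscript

# Step 1: generate the synthetic two-sample GWAS study.
#
# Builds summary statistics for the 13 drug-target/lipid-trait pairs with
# planted ground truth: positive-control (CHD-like) effects at the targets
# known to lower cardiovascular risk, disease (acne-like) effects only at
# the PCSK9-, LDLR- and LPL-like targets, and zero significant cis SNPs
# where the published selection came up empty. Writes the summary tables,
# LD matrices, and ground truth under results/synthetic/.

library(lipidmr)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

out_dir <- "results/synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(seed = seed)
cfg <- sim$config

for (trait in names(cfg$exposures)) {
  write_summary_tsv(cfg$exposures[[trait]],
                    file.path(out_dir, paste0("exposure_", trait, ".tsv")))
  write_ld_tsv(cfg$ld[[trait]], file.path(out_dir, paste0("ld_", trait, ".tsv")))
}
write_summary_tsv(cfg$control_outcome, file.path(out_dir, "outcome_control.tsv"))
write_summary_tsv(cfg$disease_outcome, file.path(out_dir, "outcome_disease.tsv"))

truth <- do.call(rbind, lapply(names(sim$truth), function(key) {
  tr <- sim$truth[[key]]
  data.frame(target = key, theta_control = tr$theta_control,
             theta_disease = tr$theta_disease,
             n_planted = length(tr$planted_ids))
}))
write.table(truth, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Synthetic study written to", out_dir, "(seed", seed, ")\n")
cat(sprintf("  %d targets, %d planted instruments in total\n",
            nrow(truth), sum(truth$n_planted)))
print(truth, row.names = FALSE)
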