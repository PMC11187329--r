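#!/usr/bin/env Rscript

# Step 3: sensitivity battery for every gate-passing target.
#
# For each target that reached the disease stage: Cochran's Q and
# I-squared, the Egger intercept test, MR-PRESSO global/outlier tests, the
# leave-one-out series, and funnel-plot data. Writes one summary table plus
# per-target leave-one-out and funnel exports under results/sensitivity/.

library(lipidmr)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 1L

out_dir <- "results/sensitivity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(seed = seed)
reports <- run_study(sim$config)

summaries <- list()
for (key in names(reports)) {
  r <- reports[[key]]
  if (is.null(r$disease_mr)) next
  sens <- r$disease_sensitivity
  row <- cbind(target = key, sens$summary)
  summaries[[key]] <- row
  write.table(sens$loo$loo,
              file.path(out_dir, paste0("loo_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(funnel_data(r$disease_set$pairs),
              file.path(out_dir, paste0("funnel_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
summary_tab <- do.call(rbind, summaries)
write.table(summary_tab, file.path(out_dir, "sensitivity_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Disease-stage sensitivity diagnostics:\n")
print(summary_tab[, c("target", "n_snps", "q", "i2", "q_pval",
                      "egger_intercept_p", "presso_global_p", "loo_robust")],
      row.names = FALSE)
flagged <- summary_tab[!is.na(summary_tab$presso_global_p) &
                         summary_tab$presso_global_p < 0.05, "target"]
if (length(flagged) == 0) {
  cat("\nNo target shows significant horizontal pleiotropy (MR-PRESSO",
      "global p >= 0.05 throughout), consistent with the valid-instrument",
      "generator regime.\n")
} else {
  cat("\nMR-PRESSO flags horizontal pleiotropy for:",
      paste(flagged, collapse = ", "), "\n")
}
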