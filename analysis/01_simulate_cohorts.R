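#!/usr/bin/env Rscript
# Simulate the two ADAD-like study cohorts and write their raw tables.
#
# Produces, under results/cohorts/: a metadata CSV and a long thickness CSV
# per cohort template, in the exact dialects the ingest functions read, so
# the rest of the workflow runs off files just as it would on real exports.

suppressMessages(library(cortasym))

out <- "results/cohorts"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (template in c("barcelona_like", "dian_like")) {
  cfg <- synthetic_config(template, seed = 20260925L)
  coh <- generate_cohort(cfg)
  write_metadata(coh$metadata, file.path(out, paste0(template, "_metadata.csv")))
  write_thickness(coh$thickness,
                  file.path(out, paste0(template, "_thickness.csv")), "long_csv")
  base <- coh$metadata[coh$metadata$visit == 0, ]
  cat(sprintf(
    "%-15s %3d participants (%d CTR / %d AMC / %d SMC), %d visits total\n",
    template, nrow(base), sum(base$group == "CTR"), sum(base$group == "AMC"),
    sum(base$group == "SMC"), nrow(coh$metadata)
  ))
}
cat("cohort tables written to", out, "\n")
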