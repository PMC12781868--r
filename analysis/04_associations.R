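#!/usr/bin/env Rscript
# Baseline associations of CAI with age, EYO, MMSE and NfL, by subgroup:
# Spearman for the small cohort, Pearson for the large one.
#
# Reads results/<template>_analysis_table.csv; writes
# results/<template>_correlations.csv.

suppressMessages(library(cortasym))

for (template in c("barcelona_like", "dian_like")) {
  at <- readr::read_csv(sprintf("results/%s_analysis_table.csv", template),
                        show_col_types = FALSE)
  res <- association_battery(at)
  readr::write_csv(res, sprintf("results/%s_correlations.csv", template))
  cat(sprintf("\n== %s (%s) ==\n", template, res$method[1]))
  show <- res[res$subgroup %in% c("mutation_carriers", "SMC") &
                res$variable %in% c("plasma_nfl_pg_ml", "mmse", "eyo_years") &
                res$flag == "ok", c("subgroup", "variable", "r", "p", "n")]
  print(as.data.frame(show), digits = 2, row.names = FALSE)
}
cat("\ncorrelation tables written to results/\n")
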