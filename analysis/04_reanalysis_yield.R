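#!/usr/bin/env Rscript
# Step 4: the stepwise reanalysis itself. Runs step 0 and reanalysis steps
# 1-3 over every simulated trio, checks planted-variant recovery against the
# generator's truth table, writes the merged candidate report, and accounts
# diagnostic yield on the bundled 128-case cohort ledger.

suppressMessages(library(triosplice))

SEED <- 1234L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = SEED)
models <- generate_gene_models(cfg)
cohort <- generate_trio_cohort(cfg, models, generate_constraint_table(cfg, models))
res <- run_cohort_reanalysis(cohort)

write_report(res$candidates, "results/reanalysis_candidates.tsv", "tsv")
utils::write.table(res$recovery, "results/planted_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Candidates by step over", length(cohort$trios), "trios:\n")
print(table(res$candidates$step))
cat("\nPlanted-variant recovery:\n")
print(res$recovery[, c("label", "model", "intended_step", "found_step",
                       "recovered")], row.names = FALSE)
stopifnot(all(res$recovery$recovered))
leak <- res$candidates[!is.na(res$candidates$af) & res$candidates$af > 1e-4, ]
cat("\nCommon-variant leakage into any step:", nrow(leak), "variants\n")

## yield accounting on the bundled ledger
y <- tally_yield(bundled_cohort_ledger())
yield_tab <- data.frame(
  quantity = c("cases", "diagnosed_initial", "initial_yield_pct",
               "undiagnosed_after_initial", "diagnosed_reanalysis",
               "reanalysis_yield_pct", "step3_universe"),
  value = c(y$n_cases, y$n_initial, y$initial_yield_pct,
            y$n_undiagnosed_initial, y$n_reanalysis,
            y$reanalysis_yield_pct, y$n_step3_universe))
utils::write.table(yield_tab, "results/yield_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nBundled cohort ledger yields:\n")
print(yield_tab, row.names = FALSE)
cat("\n-> results/reanalysis_candidates.tsv, results/planted_recovery.tsv,",
    "results/yield_summary.tsv\n")
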