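#!/usr/bin/env Rscript
# Step 2 — filter and score the replica cohort.
#
# Applies the applicability filter (the indicator set addresses incidents
# that directly or indirectly involve casualties), scores every applicable
# incident against the 11-item rubric, excludes incidents whose
# documentation is incomplete, and writes the case flow, the descriptive
# summary, the per-indicator table and the met/not-met fractions.

suppressPackageStartupMessages(library(micqi))

in_path <- "results/analysis/cohort_flow_replica.jsonl"
out_dir <- "results/analysis"
if (!file.exists(in_path)) stop("run analysis/01_simulate.R first")

res <- run_pipeline(input = in_path, out_dir = out_dir)

fl <- res$flow
cat("Case flow:\n")
cat(sprintf("  %d declared -> %d not applicable -> %d applicable (%s)\n",
            fl$n_total, fl$n_not_applicable, fl$n_applicable,
            format_percent(fl$n_applicable, fl$n_total)))
cat(sprintf("  -> %d incomplete documentation -> %d scoreable\n",
            fl$n_incomplete, fl$n_scoreable))

tot <- res$aggregate$totals
cat(sprintf("\n%d measurable indicators from %d incidents; %d (%s) met",
            tot$n_cells, fl$n_scoreable, tot$n_met,
            format_percent(tot$n_met, tot$n_cells)),
    sprintf("completely or partly, %d (%s) not met at all\n", tot$n_not_met,
            format_percent(tot$n_not_met, tot$n_cells)))

cat("\nPer-indicator mean scores (0-2):\n")
per <- res$aggregate$per_indicator
print(data.frame(indicator = per$indicator_id,
                 mean = round(per$mean, 2)), row.names = FALSE)
cat("\nreports written under", out_dir, "\n")
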