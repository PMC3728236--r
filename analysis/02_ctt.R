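#!/usr/bin/env Rscript
# Stage 2 — classical item screening: floor/ceiling percentages and
# corrected item-total correlations against the inclusion criteria
# (floor < 50%, r >= 0.80).
suppressPackageStartupMessages(library(absst))

responses <- read_responses("results/responses.csv")
stats_tab <- ctt_item_stats(responses)
write_report(stats_tab, "results/ctt.csv")

cat(sprintf("Floor criterion (< 50%% at category 0): %d of %d items pass: %s\n",
            sum(stats_tab$met_floor), nrow(stats_tab),
            paste(stats_tab$item_id[stats_tab$met_floor], collapse = ", ")))
cat(sprintf("Correlation criterion (item-rest r >= 0.80): %d items pass: %s\n",
            sum(stats_tab$met_correlation),
            paste(stats_tab$item_id[stats_tab$met_correlation],
                  collapse = ", ")))
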