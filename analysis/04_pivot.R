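#!/usr/bin/env Rscript
# Stage 4 — pivot anchoring: aggregate the clinician survey into per-item
# flag thresholds (modal threshold among endorsers, ties low) and the
# strict-majority clinician criterion.
suppressPackageStartupMessages(library(absst))

survey <- read_clinician_survey("results/survey.csv")
rule <- aggregate_thresholds(survey)
write_report(rule, "results/pivot_rule.csv")

cat(sprintf("%d clinicians responded.\n", length(survey$clinicians)))
cat(sprintf("Clinician majority criterion (> 50%%) met by %d items: %s\n",
            sum(rule$met_clinician),
            paste(rule$item_id[rule$met_clinician], collapse = ", ")))
print(rule[, c("item_id", "flag_threshold", "endorsement_pct")],
      row.names = FALSE)
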