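#!/usr/bin/env Rscript
# Stage 6 — predictive validity of the short-form raw total: cut-point
# sweep (odds ratios, Se/Sp, predictive values, per-cut c), ROC curve,
# logistic regression, and Hosmer-Lemeshow calibration.
suppressPackageStartupMessages(library(absst))

responses <- read_responses("results/responses.csv")
labels <- read_referral_labels("results/labels.csv")
labels <- labels[match(rownames(responses$values), labels$person), ]
retained <- readLines("results/retained_items.txt")
scores <- raw_total_score(responses, setdiff(retained, "item17"))

sweep <- cutpoint_sweep(scores, labels, c(21L, 9L, 6L, 4L, 1L))
write_report(sweep, "results/cutpoints.csv")
print(format_cutpoint_table(sweep), row.names = FALSE)

roc <- roc_auc(scores, labels)
write_roc_points(roc$points, "results/roc.csv")
lg <- fit_logistic(scores, labels)
hl <- suppressWarnings(hosmer_lemeshow(stats::fitted(lg$model), labels))
write_report(data.frame(c_statistic_overall = roc$auc,
                        logit_intercept = lg$intercept,
                        logit_slope = lg$slope, logit_slope_se = lg$se,
                        hl_chi2 = hl$chi2, hl_df = hl$df, hl_p = hl$p_value),
             "results/validity.csv")
cat(sprintf(
  "Overall c-statistic %.3f; logistic slope %.3f (SE %.3f); HL X2 = %.2f on %d df (p = %.4f).\n",
  roc$auc, lg$slope, lg$se, hl$chi2, hl$df, hl$p_value))
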