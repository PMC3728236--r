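# End-to-end orchestration: simulate (or read) inputs, run the classical,
# Rasch, pivot-scoring, item-reduction and predictive-validity stages in
# order, write per-stage tables, and record a manifest that makes a run
# reproducible byte-for-byte under its seed.

#' Run the full validation pipeline
#'
#' Stages: obtain inputs (simulate under the configured seed, or read the
#' response/survey/label files named in the config), classical item
#' statistics, Partial Credit Rasch fits (per subscale by default),
#' clinician pivot rule, criteria evaluation and item selection, raw-total
#' scoring over the retained items, and the cut-point/ROC/logistic
#' validation stage.  Every stage writes a CSV (plus JSON companion) under
#' `out_dir`; a `manifest.json` records the config, seed, package version
#' and MD5 of every output.
#'
#' @param config A YAML file path or a list.  Recognised fields:
#'   `seed`, `n_persons`, `cuts` (default 21, 9, 6, 4, 1), `policy`
#'   (selection policy), `whole_scale` (fit one Rasch model over all
#'   ordinal items instead of per subscale), `or_zero_cell_policy`, and
#'   optional input paths `responses`, `survey`, `labels` (all three given
#'   = no simulation).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `config`, `seed`, `files`,
#'   `retained_items`, `outputs`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("absst_run_")) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cuts <- config$cuts %||% c(21L, 9L, 6L, 4L, 1L)
  policy <- config$policy %||% "any_criterion"
  seed <- as.integer(config$seed %||% 20130709L)
  cfg <- run_config(seed = seed,
                    or_zero_cell_policy = config$or_zero_cell_policy %||%
                      "undefined")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inst <- absst_instrument()
  outputs <- character(0)
  put <- function(obj, name) {
    path <- file.path(out_dir, name)
    write_report(obj, path)
    outputs <<- c(outputs, path, paste0(path, ".json"))
    path
  }

  # -- inputs ---------------------------------------------------------------
  from_files <- all(c("responses", "survey", "labels") %in% names(config))
  if (from_files) {
    for (f in c("responses", "survey", "labels"))
      if (!file.exists(config[[f]]))
        stop("input file for '", f, "' not found: ", config[[f]])
    responses <- read_responses(config$responses, inst)
    survey <- read_clinician_survey(config$survey, inst)
    labels <- read_referral_labels(config$labels)
  } else {
    sim <- simulation_config(
      n_persons = as.integer(config$n_persons %||% 151L), seed = seed)
    drawn <- simulate_pcm_responses(sim)
    responses <- drawn$responses
    survey <- simulate_clinician_survey(sim, default_true_rule(inst))
    full_total <- raw_total_score(responses)
    labels <- simulate_referrals(full_total, sim)
  }
  responses <- drop_sparse_persons(responses)
  labels <- labels[match(rownames(responses$values), labels$person), ]
  if (anyNA(labels$referred))
    stop("labels do not cover every person in the response matrix")
  write_responses(responses, file.path(out_dir, "responses.csv"))
  write_clinician_survey(survey, file.path(out_dir, "survey.csv"))
  write_referral_labels(labels, file.path(out_dir, "labels.csv"))
  outputs <- c(outputs, file.path(out_dir, c("responses.csv", "survey.csv",
                                             "labels.csv")))

  # -- classical statistics -------------------------------------------------
  ctt <- ctt_item_stats(responses, cfg)
  put(ctt, "ctt.csv")
  message("ctt: ", sum(ctt$met_floor), "/", nrow(ctt),
          " items met the floor criterion; ", sum(ctt$met_correlation),
          " met the correlation criterion")

  # -- Rasch fits (per subscale unless whole_scale) -------------------------
  whole <- isTRUE(config$whole_scale)
  ord <- responses$items[!responses$items$is_binary, ]
  groups <- if (whole) list(all = ord$item_id) else
    split(ord$item_id, ord$subscale)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  fit_tabs <- list(); scale_tabs <- list()
  for (g in names(groups)) {
    sub <- subset_items(responses, groups[[g]])
    fit <- fit_pcm(sub, cfg)
    fs <- item_fit_statistics(fit, cfg)
    fs$group <- g
    sc <- separation_reliability(fit)
    fit_tabs[[g]] <- fs
    scale_tabs[[g]] <- data.frame(
      group = g, person_separation = sc$person_separation,
      person_reliability = sc$person_reliability,
      item_separation = sc$item_separation,
      item_reliability = sc$item_reliability,
      converged = fit$converged, iterations = fit$iterations,
      n_extreme = length(fit$dropped_persons))
  }
  fit_stats <- do.call(rbind, fit_tabs)
  class(fit_stats) <- c("item_fit_stats", "data.frame")
  put(fit_stats, "rasch_items.csv")
  put(do.call(rbind, scale_tabs), "rasch_scale.csv")
  message("rasch: ", sum(!fit_stats$misfit, na.rm = TRUE), "/",
          nrow(fit_stats), " items inside the ",
          cfg$infit_band[1], "-", cfg$infit_band[2], " fit band")

  # -- pivot rule -----------------------------------------------------------
  rule <- aggregate_thresholds(survey, cfg)
  put(rule, "pivot_rule.csv")

  # -- criteria + selection -------------------------------------------------
  report <- evaluate_criteria(ctt, fit_stats, rule, cfg)
  retained <- select_items(report, policy = policy,
                           binary_item = "item17")
  bin17 <- rule[rule$item_id == "item17", ]
  if (nrow(bin17) == 1L && isTRUE(bin17$met_clinician) &&
      !"item17" %in% retained)
    retained <- c(retained, "item17")
  put(report, "criteria.csv")
  writeLines(retained, file.path(out_dir, "retained_items.txt"))
  outputs <- c(outputs, file.path(out_dir, "retained_items.txt"))
  message("reduce (", policy, "): retained ",
          sum(retained != "item17"), " ordinal item(s)",
          if ("item17" %in% retained) " plus the yes/no help item" else "")

  # -- scoring --------------------------------------------------------------
  retained_ordinal <- setdiff(retained, "item17")
  scores <- raw_total_score(responses, retained_ordinal)
  flaggable <- intersect(retained,
                         rule$item_id[!is.na(rule$flag_threshold)])
  if (length(flaggable) < length(retained))
    message("score: no clinician threshold for ",
            paste(setdiff(retained, flaggable), collapse = ", "),
            "; excluded from the flag score")
  flags <- flag_matrix(subset_items(responses, flaggable), rule)
  score_tab <- data.frame(person = names(scores), raw_total = scores,
                          flag_score = rowSums(flags),
                          referred = as.integer(labels$referred))
  put(score_tab, "scores.csv")

  # -- predictive validity --------------------------------------------------
  sweep <- cutpoint_sweep(scores, labels, cuts,
                          policy = cfg$or_zero_cell_policy)
  put(sweep, "cutpoints.csv")
  roc <- roc_auc(scores, labels)
  write_roc_points(roc$points, file.path(out_dir, "roc.csv"))
  outputs <- c(outputs, file.path(out_dir, "roc.csv"))
  lg <- fit_logistic(scores, labels)
  hl <- tryCatch(hosmer_lemeshow(stats::fitted(lg$model), labels),
                 warning = function(w) suppressWarnings(
                   hosmer_lemeshow(stats::fitted(lg$model), labels)))
  validity <- data.frame(
    c_statistic_overall = roc$auc, logit_intercept = lg$intercept,
    logit_slope = lg$slope, logit_slope_se = lg$se,
    logit_converged = lg$converged, hl_chi2 = hl$chi2, hl_df = hl$df,
    hl_p = hl$p_value)
  put(validity, "validity.csv")
  message(sprintf(
    "validate: overall c = %.3f; logistic slope = %.3f (SE %.3f); HL p = %.4f",
    roc$auc, lg$slope, lg$se, hl$p_value))

  manifest <- list(
    package_version = as.character(utils::packageVersion("absst")),
    seed = seed,
    config = config[setdiff(names(config), NULL)],
    retained_items = retained,
    files = as.list(tools::md5sum(sort(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default generating pivot rule for simulations
#'
#' The published critical screening ratings for the nine short-form items
#' ([table1_pivot_rule()]), extended to the full instrument with threshold
#' 3 and moderate endorsement for the remaining items; used as the truth
#' when simulating clinician surveys.
#'
#' @param instrument An [instrument()].
#' @return A [pivot_rule()] over all instrument items.
#' @export
default_true_rule <- function(instrument = absst_instrument()) {
  pub <- table1_pivot_rule()
  thr <- pub$flag_threshold[match(instrument$item_id, pub$item_id)]
  thr[is.na(thr)] <- pmin(3L, instrument$max_category[is.na(thr)])
  endorse <- ifelse(instrument$item_id %in%
                      sprintf("item%02d", c(3, 8, 10, 11, 17)), 75, 35)
  pivot_rule(instrument$item_id, thr, endorsement_pct = endorse)
}

#' Reproduce the published cut-point performance table
#'
#' Runs the deterministic score/label fixture through [cutpoint_sweep()]
#' at the published cut-points.
#'
#' @param cuts Cut-points (default 21, 9, 6, 4, 1).
#' @param formatted Return the display-rounded table
#'   ([format_cutpoint_table()]) instead of full precision.
#' @return A `cutpoint_report` (or its formatted version).
#' @export
table3_report <- function(cuts = c(21L, 9L, 6L, 4L, 1L), formatted = FALSE) {
  fx <- table3_fixture()
  rep <- cutpoint_sweep(fx$scores, fx$labels, cuts, policy = "undefined")
  if (formatted) format_cutpoint_table(rep) else rep
}
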