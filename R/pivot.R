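# Pivot-anchored clinician scoring: aggregate per-item clinician thresholds
# into a flag rule, dichotomise patient responses at those thresholds, and
# compute the raw total score used for the referral cut-point analysis.

#' Aggregate a clinician survey into a per-item pivot rule
#'
#' For each item, the endorsement percentage is the share of responding
#' clinicians who marked the item relevant; the flag threshold is the modal
#' threshold among endorsers, ties broken toward the *lower* category (the
#' survey asked for the lowest concerning rating, so the more sensitive
#' reading wins).  The clinician inclusion criterion is a strict majority.
#'
#' @param survey A [clinician_survey()].
#' @param cfg A [run_config()]; `clinician_majority` (default 0.5) sets the
#'   strict endorsement fraction.
#' @return Data frame of class `pivot_rule`: `item_id`, `flag_threshold`
#'   (`NA` when no clinician endorsed the item), `endorsement_pct`,
#'   `n_endorsers`, `met_clinician`.
#' @export
aggregate_thresholds <- function(survey, cfg = run_config()) {
  stopifnot(inherits(survey, "clinician_survey"))
  n_resp <- length(survey$clinicians)
  if (n_resp < 1L) stop("need at least one responding clinician")
  rows <- lapply(seq_len(ncol(survey$relevant)), function(j) {
    endorse <- survey$relevant[, j]
    thr <- survey$threshold[endorse & !is.na(survey$threshold[, j]), j]
    pct <- 100 * sum(endorse) / n_resp
    t_i <- if (length(thr)) {
      tab <- table(thr)
      cand <- as.integer(names(tab)[tab == max(tab)])
      min(cand)                          # tie toward the lower category
    } else NA_integer_
    data.frame(item_id = survey$items$item_id[j], flag_threshold = t_i,
               endorsement_pct = pct, n_endorsers = sum(endorse),
               met_clinician = pct > 100 * cfg$clinician_majority)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pivot_rule", "data.frame")
  out
}

#' Construct a pivot rule directly
#'
#' @param item_ids Item identifiers.
#' @param flag_threshold Integer thresholds (category at or above which a
#'   response is flagged), aligned with `item_ids`.
#' @param endorsement_pct Optional endorsement percentages (default 100).
#' @return A `pivot_rule` data frame.
#' @export
pivot_rule <- function(item_ids, flag_threshold, endorsement_pct = 100) {
  out <- data.frame(item_id = as.character(item_ids),
                    flag_threshold = as.integer(flag_threshold),
                    endorsement_pct = rep_len(endorsement_pct,
                                              length(item_ids)),
                    n_endorsers = NA_integer_,
                    met_clinician = rep_len(endorsement_pct,
                                            length(item_ids)) > 50)
  if (any(!is.na(out$flag_threshold) & out$flag_threshold < 1L))
    stop("flag thresholds must be >= 1")
  class(out) <- c("pivot_rule", "data.frame")
  out
}

#' Dichotomise patient responses at the pivot thresholds
#'
#' A response is flagged 1 ("potential bladder problem") when it is at or
#' above the item's flag threshold, else 0.  Missing responses are flagged
#' 0; their count is attached as `attr(,"n_missing")` so the conservative
#' imputation stays auditable.
#'
#' @param responses A [response_matrix()].
#' @param rule A `pivot_rule` covering every item in `responses`.
#' @return Integer 0/1 matrix, persons x items, with `n_missing` attribute.
#' @export
flag_matrix <- function(responses, rule) {
  stopifnot(inherits(responses, "response_matrix"))
  ids <- responses$items$item_id
  thr <- rule$flag_threshold[match(ids, rule$item_id)]
  missing_rule <- ids[is.na(thr)]
  if (length(missing_rule))
    stop("no flag threshold for item(s): ",
         paste(missing_rule, collapse = ", "))
  flags <- sweep(responses$values, 2L, thr, `>=`)
  n_missing <- sum(is.na(flags))
  flags[is.na(flags)] <- FALSE
  flags <- flags * 1L
  storage.mode(flags) <- "integer"
  attr(flags, "n_missing") <- n_missing
  flags
}

#' Raw total score over the retained ordinal items
#'
#' Sum of the ordinal response categories over the retained items (the
#' binary help-seeking item never contributes to the total).  Missing
#' responses count as 0; the number imputed is attached as
#' `attr(,"n_missing")`.
#'
#' @param responses A [response_matrix()].
#' @param retained_items Item identifiers to sum over; defaults to every
#'   ordinal item in the matrix.
#' @return Named integer vector of per-person totals.
#' @export
raw_total_score <- function(responses,
                            retained_items = NULL) {
  stopifnot(inherits(responses, "response_matrix"))
  if (is.null(retained_items))
    retained_items <- responses$items$item_id[!responses$items$is_binary]
  missing_items <- setdiff(retained_items, responses$items$item_id)
  if (length(missing_items))
    stop("retained item(s) not in matrix: ",
         paste(missing_items, collapse = ", "))
  keep <- intersect(retained_items,
                    responses$items$item_id[!responses$items$is_binary])
  V <- responses$values[, keep, drop = FALSE]
  out <- as.integer(rowSums(V, na.rm = TRUE))
  names(out) <- rownames(responses$values)
  attr(out, "n_missing") <- sum(is.na(V))
  out
}

#' Referral classification at a score cut-point
#'
#' @param score Integer score(s).
#' @param cut Non-negative cut-point; classification is inclusive
#'   (`score >= cut`).
#' @return Logical: refer recommended.
#' @export
classify_referral <- function(score, cut) {
  stopifnot(cut >= 0)
  score >= cut
}
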