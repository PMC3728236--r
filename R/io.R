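# File formats: comma-separated UTF-8, "NA" as the missing marker.
# Responses: first column person id, remaining columns named by item_id.
# Clinician survey: first column clinician id, then <item>_relevant (0/1)
# and <item>_threshold pairs.  Labels: person, referred (0/1).

#' Read a person-by-item response table
#'
#' @param path CSV file: first column person identifiers, remaining columns
#'   named by `item_id`, cells integer categories or `NA`.
#' @param instrument An [instrument()] describing the items.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, instrument = absst_instrument()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("response file needs a person column plus items")
  persons <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "integer"
  rownames(values) <- persons
  response_matrix(values, instrument)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]; `read_responses(write_responses(x))`
#' restores `x` exactly, including missing cells.
#'
#' @param responses A [response_matrix()].
#' @param path Output CSV path.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "response_matrix"))
  df <- data.frame(person = rownames(responses$values),
                   responses$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Clinician pivot-anchoring survey
#'
#' Holds, for each responding clinician and item, whether the clinician
#' marked the item clinically relevant and, if so, the lowest response
#' category ("pivot threshold") that would indicate a potential bladder
#' problem.  Thresholds are only present for relevant items and must lie in
#' `1..max_category`.
#'
#' @param relevant Logical matrix, clinicians x items.
#' @param threshold Integer matrix, clinicians x items; `NA` where not
#'   relevant.
#' @param items An [instrument()].
#' @param clinicians Optional clinician identifiers.
#' @return An object of class `clinician_survey`.
#' @export
clinician_survey <- function(relevant, threshold, items,
                             clinicians = NULL) {
  if (!inherits(items, "absst_instrument")) items <- instrument(items)
  relevant <- as.matrix(relevant); threshold <- as.matrix(threshold)
  storage.mode(relevant) <- "logical"
  storage.mode(threshold) <- "integer"
  if (!all(dim(relevant) == dim(threshold)))
    stop("relevant and threshold matrices must have identical shape")
  if (nrow(relevant) == 0L) stop("no clinicians in survey")
  if (ncol(relevant) != nrow(items))
    stop("survey covers ", ncol(relevant), " items, instrument has ",
         nrow(items))
  if (is.null(clinicians)) {
    clinicians <- rownames(relevant)
    if (is.null(clinicians))
      clinicians <- sprintf("C%02d", seq_len(nrow(relevant)))
  }
  dimnames(relevant) <- dimnames(threshold) <-
    list(as.character(clinicians), items$item_id)
  for (j in seq_len(ncol(threshold))) {
    t_j <- threshold[, j]
    orphan <- which(!is.na(t_j) & !relevant[, j])
    if (length(orphan))
      stop(sprintf(
        "clinician '%s' reports a threshold for item '%s' without marking it relevant",
        clinicians[orphan[1]], items$item_id[j]))
    bad <- which(!is.na(t_j) & (t_j < 1L | t_j > items$max_category[j]))
    if (length(bad))
      stop(sprintf(
        "clinician '%s', item '%s': threshold %d outside 1..%d (a flag threshold must be >= 1)",
        clinicians[bad[1]], items$item_id[j], t_j[bad[1]],
        items$max_category[j]))
  }
  structure(list(clinicians = as.character(clinicians), relevant = relevant,
                 threshold = threshold, items = items),
            class = "clinician_survey")
}

#' Read a clinician pivot survey from CSV
#'
#' @param path CSV with first column clinician id and, per item, columns
#'   `<item_id>_relevant` (0/1) and `<item_id>_threshold` (integer or `NA`).
#' @param instrument An [instrument()].
#' @return A [clinician_survey()].
#' @export
read_clinician_survey <- function(path, instrument = absst_instrument()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no clinicians in survey file '", path, "'")
  ids <- instrument$item_id
  rel_cols <- paste0(ids, "_relevant")
  thr_cols <- paste0(ids, "_threshold")
  miss <- setdiff(c(rel_cols, thr_cols), names(df))
  if (length(miss))
    stop("survey file missing column(s): ", paste(miss, collapse = ", "))
  relevant <- as.matrix(df[, rel_cols, drop = FALSE]) == 1
  threshold <- as.matrix(df[, thr_cols, drop = FALSE])
  clinician_survey(relevant, threshold, instrument,
                   clinicians = as.character(df[[1]]))
}

#' @rdname read_clinician_survey
#' @param survey A [clinician_survey()].
#' @export
write_clinician_survey <- function(survey, path) {
  stopifnot(inherits(survey, "clinician_survey"))
  ids <- survey$items$item_id
  out <- data.frame(clinician = survey$clinicians, check.names = FALSE)
  for (j in seq_along(ids)) {
    out[[paste0(ids[j], "_relevant")]] <- as.integer(survey$relevant[, j])
    out[[paste0(ids[j], "_threshold")]] <- survey$threshold[, j]
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-person referral recommendation labels
#'
#' @param referred Logical/0-1 vector: did the clinician recommend urologist
#'   referral for this person?
#' @param persons Person identifiers aligned with `referred`.
#' @return A data frame of class `referral_labels`.
#' @export
referral_labels <- function(referred, persons = NULL) {
  referred <- as.logical(referred)
  if (anyNA(referred)) stop("referral labels must be 0/1, no missing")
  if (is.null(persons)) persons <- sprintf("P%03d", seq_along(referred))
  if (anyDuplicated(persons)) stop("person identifiers must be unique")
  out <- data.frame(person = as.character(persons), referred = referred,
                    stringsAsFactors = FALSE)
  class(out) <- c("referral_labels", "data.frame")
  out
}

#' Read/write referral labels
#' @param path CSV with columns `person`, `referred` (0/1).
#' @export
read_referral_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("person", "referred") %in% names(df)))
    stop("labels file needs columns person, referred")
  referral_labels(df$referred, persons = df$person)
}

#' @rdname read_referral_labels
#' @param labels A [referral_labels()] object.
#' @export
write_referral_labels <- function(labels, path) {
  out <- data.frame(person = labels$person,
                    referred = as.integer(labels$referred))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a stage report
#'
#' Writes any stage output as a delimited table (`<path>`) plus a
#' machine-readable JSON companion (`<path>.json`) holding the full,
#' unrounded values.  Cut-point reports use the display rounding of the
#' published table (2 decimals for odds ratios and percents, 3 for
#' c-statistics); other tables are written at full precision.
#'
#' @param results A data frame (cut-point report, item statistics, criteria
#'   report, ...) or a coercible object.
#' @param path Output CSV path.
#' @export
write_report <- function(results, path) {
  if (inherits(results, "cutpoint_report")) {
    disp <- format_cutpoint_table(results)
  } else {
    disp <- as.data.frame(results)
  }
  utils::write.csv(disp, path, row.names = FALSE, quote = FALSE, na = ".")
  jsonlite::write_json(as.data.frame(results), paste0(path, ".json"),
                       dataframe = "rows", na = "null", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Export / import ROC points
#'
#' Points are stored as `(fpr, tpr)` = (1 - specificity, sensitivity) pairs
#' in threshold order; re-reading them reproduces the trapezoidal area.
#'
#' @param roc A data frame with columns `fpr`, `tpr` (as from [roc_auc()]).
#' @param path CSV path.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  utils::write.csv(roc[, c("fpr", "tpr")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_roc_points
#' @export
read_roc_points <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("fpr", "tpr") %in% names(df)))
  df
}

#' Trapezoidal area under a set of ROC points
#'
#' @param roc Data frame with columns `fpr`, `tpr`.
#' @return Area under the piecewise-linear ROC curve.
#' @export
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
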