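# Predictive-validity engine: 2x2 screening tables, diagnostic metrics,
# cut-point sweeps, ROC/c-statistic, logistic regression, and
# Hosmer-Lemeshow calibration.

#' 2x2 screening table at a score cut-point
#'
#' Positive class = clinician recommends referral; predicted positive =
#' score at or above the cut.
#'
#' @param scores Per-person numeric scores.
#' @param labels A [referral_labels()] data frame or logical vector aligned
#'   with `scores`.
#' @param cut Cut-point (inclusive).
#' @return List of class `confusion_table` with integer cells `tp`, `fn`,
#'   `fp`, `tn`.
#' @export
contingency_table <- function(scores, labels, cut) {
  y <- if (inherits(labels, "data.frame")) labels$referred else
    as.logical(labels)
  if (length(scores) == 0L) stop("no persons")
  if (length(scores) != length(y))
    stop("scores and labels not aligned: ", length(scores), " vs ",
         length(y))
  pred <- classify_referral(scores, cut)
  structure(list(tp = sum(pred & y), fn = sum(!pred & y),
                 fp = sum(pred & !y), tn = sum(!pred & !y)),
            class = "confusion_table")
}

#' Diagnostic metrics from a 2x2 screening table
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(fp+tn)`, predictive values,
#' percent correctly classified, each on the 0--100 scale, and the
#' diagnostic odds ratio `(tp*tn)/(fn*fp)`.  With a zero off-diagonal cell
#' the odds ratio is reported as `NA` under the default policy (printed as
#' "." in reports) or Haldane-corrected (+0.5 to every cell) under
#' `policy = "haldane"`.
#'
#' @param tab A [contingency_table()] result.
#' @param policy Zero-cell odds-ratio policy, `"undefined"` or `"haldane"`.
#' @return One-row data frame: `odds_ratio`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `pct_correct` (full precision; display rounding is
#'   applied by [format_cutpoint_table()]).
#' @export
diagnostic_metrics <- function(tab, policy = c("undefined", "haldane")) {
  stopifnot(inherits(tab, "confusion_table"))
  policy <- match.arg(policy)
  tp <- tab$tp; fn <- tab$fn; fp <- tab$fp; tn <- tab$tn
  if (tp + fn < 1L || fp + tn < 1L)
    stop("both referred and non-referred persons are required")
  or <- if (fn * fp == 0) {
    if (policy == "haldane")
      ((tp + 0.5) * (tn + 0.5)) / ((fn + 0.5) * (fp + 0.5))
    else NA_real_
  } else (tp * tn) / (fn * fp)
  n <- tp + fn + fp + tn
  data.frame(
    odds_ratio = or,
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (fp + tn),
    ppv = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) 100 * tn / (tn + fn) else NA_real_,
    pct_correct = 100 * (tp + tn) / n)
}

#' ROC curve and c-statistic
#'
#' The c-statistic (area under the ROC curve) is computed by the rank
#' (Mann-Whitney concordance) formula with ties counted one half; this
#' equals the trapezoidal area under the empirical ROC, and for a
#' dichotomised predictor equals `(Se + Sp) / 2`.
#'
#' @param scores Per-person numeric predictor.
#' @param labels Referral labels (data frame or logical vector).
#' @return List of class `roc_result`: `auc`, and `points` (data frame
#'   `threshold`, `fpr`, `tpr` over all distinct thresholds, anchored at
#'   (0,0) and (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  y <- if (inherits(labels, "data.frame")) labels$referred else
    as.logical(labels)
  stopifnot(length(scores) == length(y))
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present for a ROC analysis")
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) sum(scores[!y] >= t) / n_neg,
                      numeric(1))),
    tpr = c(0, vapply(thr, function(t) sum(scores[y] >= t) / n_pos,
                      numeric(1))))
  structure(list(auc = auc, points = pts), class = "roc_result")
}

#' Cut-point performance sweep
#'
#' One row of diagnostic metrics per cut, in the order given, with a
#' per-cut c-statistic: the AUC of the predictor dichotomised at that cut,
#' i.e. `(Se + Sp) / 2`.  This per-row dichotomised c (not the overall
#' continuous-score c) is what a cut-point table reports.
#'
#' @inheritParams contingency_table
#' @param cuts Integer vector of cut-points.
#' @param policy Zero-cell odds-ratio policy (see [diagnostic_metrics()]).
#' @return Data frame of class `cutpoint_report`: `cut`, `odds_ratio`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `pct_correct`,
#'   `c_statistic`, plus the four cell counts.
#' @export
cutpoint_sweep <- function(scores, labels, cuts,
                           policy = c("undefined", "haldane")) {
  policy <- match.arg(policy)
  rows <- lapply(cuts, function(cut) {
    tab <- contingency_table(scores, labels, cut)
    met <- diagnostic_metrics(tab, policy)
    cstat <- roc_auc(as.integer(classify_referral(scores, cut)), labels)$auc
    cbind(data.frame(cut = cut), met,
          data.frame(c_statistic = cstat, tp = tab$tp, fn = tab$fn,
                     fp = tab$fp, tn = tab$tn))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutpoint_report", "data.frame")
  out
}

#' Display formatting for a cut-point report
#'
#' Applies the conventional rounding of published screening tables: odds
#' ratios and percents to 2 decimals, predictive values and percent
#' warranting referral to 1, c-statistics to 3; undefined odds ratios print
#' as ".".
#'
#' @param report A [cutpoint_sweep()] result.
#' @return Character data frame ready for printing/CSV.
#' @export
format_cutpoint_table <- function(report) {
  stopifnot(inherits(report, "cutpoint_report"))
  if (nrow(report) == 0L)
    return(data.frame(cut_point = character(0), odds_ratio = character(0),
                      sensitivity = character(0), specificity = character(0),
                      ppv = character(0), npv = character(0),
                      pct_warranting_referral = character(0),
                      c_statistic = character(0)))
  data.frame(
    cut_point = paste0(">= ", report$cut),
    odds_ratio = ifelse(is.na(report$odds_ratio), ".",
                        sprintf("%.2f", report$odds_ratio)),
    sensitivity = sprintf("%.2f", report$sensitivity),
    specificity = sprintf("%.2f", report$specificity),
    ppv = sprintf("%.1f", report$ppv),
    npv = sprintf("%.1f", report$npv),
    pct_warranting_referral = sprintf("%.1f", report$pct_correct),
    c_statistic = sprintf("%.3f", report$c_statistic),
    stringsAsFactors = FALSE)
}

#' Logistic regression of referral on a score
#'
#' Maximum-likelihood logistic fit (binomial GLM, iteratively reweighted
#' least squares / Newton-Raphson).  For a dichotomous predictor with all
#' four 2x2 cells positive, `exp(slope)` equals the cross-product odds
#' ratio.  Complete or quasi-complete separation (a zero off-diagonal
#' cell) is detected and reported via `converged = FALSE` and
#' `separation = TRUE`, mirroring the undefined-odds-ratio case.
#'
#' @param x Per-person predictor.
#' @param y Referral labels (data frame or logical/0-1 vector).
#' @return List of class `logistic_fit`: `intercept`, `slope`, `se`
#'   (slope SE), `se_intercept`, `converged`, `separation`, `model` (the
#'   underlying `glm`).
#' @export
fit_logistic <- function(x, y) {
  if (inherits(y, "data.frame")) y <- y$referred
  y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (length(unique(y)) < 2L)
    stop("both classes must be present to fit a logistic model")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  # a slope standard error on the order of hundreds of logits means the
  # likelihood is flat along a separating direction (zero off-diagonal cell)
  if (is.finite(se[2]) && se[2] > 10) separated <- TRUE
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 se = unname(se[2]), se_intercept = unname(se[1]),
                 converged = fit$converged && !separated,
                 separation = separated, model = fit),
            class = "logistic_fit")
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping: persons are sorted by fitted probability and
#' split into `groups` near-equal-count groups, keeping tied probabilities
#' together.  The statistic is
#' `X2 = sum_g (O_g - n_g pbar_g)^2 / (n_g pbar_g (1 - pbar_g))` with
#' `df = groups - 2` and an upper-tail chi-square p-value.  A group whose
#' mean probability is exactly 0 or 1 is merged with its neighbour (with a
#' warning) and the degrees of freedom adjusted.
#'
#' @param p Fitted probabilities.
#' @param y Observed 0/1 outcomes (or referral labels).
#' @param groups Number of risk groups (default 10; must be >= 3).
#' @return List of class `hl_test`: `chi2`, `df`, `p_value`, `groups_used`.
#' @export
hosmer_lemeshow <- function(p, y, groups = 10L) {
  if (inherits(y, "data.frame")) y <- y$referred
  y <- as.numeric(y)
  stopifnot(length(p) == length(y), groups >= 3L, length(p) >= groups)
  o <- order(p)
  p <- p[o]; y <- y[o]
  n <- length(p)
  # equal-count breaks, tied probabilities kept in one group
  idx_breaks <- unique(round(seq(0, n, length.out = groups + 1L)))
  grp <- cut(seq_len(n), breaks = idx_breaks, labels = FALSE,
             include.lowest = TRUE)
  # move ties across a boundary into the earlier group
  for (i in 2:n) if (p[i] == p[i - 1L] && grp[i] != grp[i - 1L])
    grp[i] <- grp[i - 1L]
  grp <- match(grp, sort(unique(grp)))
  agg <- function(g) {
    ng <- tapply(rep(1, n), g, sum)
    Og <- tapply(y, g, sum)
    pg <- tapply(p, g, mean)
    list(n = as.numeric(ng), O = as.numeric(Og), p = as.numeric(pg))
  }
  a <- agg(grp)
  merged <- 0L
  while (any(a$p %in% c(0, 1)) && length(a$n) > 3L) {
    bad <- which(a$p %in% c(0, 1))[1]
    neigh <- if (bad == 1L) 2L else bad - 1L
    lab <- sort(unique(grp))
    grp[grp == lab[bad]] <- lab[neigh]
    grp <- match(grp, sort(unique(grp)))
    a <- agg(grp)
    merged <- merged + 1L
  }
  if (merged > 0L)
    warning("merged ", merged,
            " degenerate risk group(s) with a neighbour")
  E <- a$n * a$p
  V <- a$n * a$p * (1 - a$p)
  chi2 <- sum((a$O - E)^2 / V)
  df <- length(a$n) - 2L
  structure(list(chi2 = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 groups_used = length(a$n)), class = "hl_test")
}
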