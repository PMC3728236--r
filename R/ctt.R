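# Classical test theory item screening.

#' Floor and ceiling percentages for one item
#'
#' Percent of non-missing responses at the lowest (0) and highest
#' (`max_category`) category.  The inclusion criterion is a floor effect
#' below the configured limit, strict: exactly 50\% at the floor fails.
#'
#' @param responses A [response_matrix()].
#' @param item_id Item identifier.
#' @return Named numeric vector `c(floor_pct, ceiling_pct)` (0--100 scale).
#' @export
floor_ceiling <- function(responses, item_id) {
  stopifnot(inherits(responses, "response_matrix"))
  j <- match(item_id, responses$items$item_id)
  if (is.na(j)) stop("unknown item: ", item_id)
  x <- responses$values[, j]
  x <- x[!is.na(x)]
  if (!length(x)) stop("item '", item_id, "' has no non-missing responses")
  c(floor_pct = 100 * mean(x == 0L),
    ceiling_pct = 100 * mean(x == responses$items$max_category[j]))
}

#' Corrected item-total (item-rest) correlation
#'
#' Pearson correlation between an item and the sum of the *other* ordinal
#' items (the rest score), so the item does not correlate with itself.
#' The binary help-seeking item never enters a rest score.  Persons missing
#' the item are excluded; the rest score sums each person's non-missing
#' remaining items.
#'
#' @param responses A [response_matrix()].
#' @param item_id Item identifier.
#' @param corrected If `FALSE`, correlate with the full total including the
#'   item itself (reported for reference; the criterion uses the corrected
#'   form).
#' @return Correlation in `[-1, 1]`, or `NA` when the item or rest score is
#'   constant.
#' @export
item_total_correlation <- function(responses, item_id, corrected = TRUE) {
  stopifnot(inherits(responses, "response_matrix"))
  j <- match(item_id, responses$items$item_id)
  if (is.na(j)) stop("unknown item: ", item_id)
  ord <- which(!responses$items$is_binary)
  others <- if (corrected) setdiff(ord, j) else ord
  if (!length(others)) stop("no other ordinal items for rest score")
  x <- responses$values[, j]
  rest <- rowSums(responses$values[, others, drop = FALSE], na.rm = TRUE)
  ok <- !is.na(x)
  if (sum(ok) < 3L)
    stop("need at least 3 persons with item '", item_id, "' observed")
  if (stats::sd(x[ok]) == 0 || stats::sd(rest[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], rest[ok])
}

#' Kuder-Richardson Formula 20
#'
#' Internal-consistency reliability for dichotomous items:
#' `KR20 = k/(k-1) * (1 - sum(p_i q_i) / var(total))`, with population
#' (divide-by-n) variances.  Accepts a plain 0/1 matrix (e.g. a pivot flag
#' matrix) or a [response_matrix()] restricted to binary items.
#'
#' @param x 0/1 matrix (persons x items) or a binary [response_matrix()].
#' @return KR-20 in `(-Inf, 1]`, or `NA` when the total score has zero
#'   variance.
#' @export
kr20 <- function(x) {
  if (inherits(x, "response_matrix")) {
    if (any(!x$items$is_binary))
      stop("kr20 needs binary items; restrict the matrix first")
    x <- x$values
  }
  x <- as.matrix(x)
  if (anyNA(x)) stop("kr20 requires complete 0/1 data")
  if (!all(x %in% c(0, 1))) stop("kr20 requires 0/1 values")
  k <- ncol(x); n <- nrow(x)
  if (k < 2L || n < 2L) stop("need >= 2 items and >= 2 persons")
  pvar <- function(v) mean((v - mean(v))^2)   # population convention
  tot_var <- pvar(rowSums(x))
  if (tot_var == 0) return(NA_real_)
  p <- colMeans(x)
  (k / (k - 1)) * (1 - sum(p * (1 - p)) / tot_var)
}

#' Classical item statistics table
#'
#' Per-item floor/ceiling percentages and item-total correlations (both
#' corrected and uncorrected), with the corresponding inclusion-criterion
#' flags, for all ordinal items.
#'
#' @param responses A [response_matrix()].
#' @param cfg A [run_config()].
#' @return Data frame of class `ctt_stats` with one row per ordinal item:
#'   `item_id`, `floor_pct`, `ceiling_pct`, `item_total_r` (corrected),
#'   `item_total_r_raw`, `n_used`, `met_floor`, `met_correlation`.
#' @export
ctt_item_stats <- function(responses, cfg = run_config()) {
  stopifnot(inherits(responses, "response_matrix"))
  ids <- responses$items$item_id[!responses$items$is_binary]
  rows <- lapply(ids, function(id) {
    fc <- floor_ceiling(responses, id)
    r_c <- item_total_correlation(responses, id, corrected = TRUE)
    r_u <- item_total_correlation(responses, id, corrected = FALSE)
    n_used <- sum(!is.na(responses$values[, id]))
    data.frame(item_id = id, floor_pct = unname(fc["floor_pct"]),
               ceiling_pct = unname(fc["ceiling_pct"]),
               item_total_r = r_c, item_total_r_raw = r_u, n_used = n_used,
               met_floor = unname(fc["floor_pct"]) < cfg$floor_limit,
               met_correlation = !is.na(r_c) & r_c >= cfg$corr_limit)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ctt_stats", "data.frame")
  out
}
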