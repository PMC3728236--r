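#' Person-by-item ordinal response matrix
#'
#' The universal input to every analysis stage: an integer matrix of
#' response categories (persons in rows, items in columns) tied to an
#' [instrument()] describing each item's category range.  Missing responses
#' are `NA`.
#'
#' @param values Integer matrix, persons x items; dimnames optional.
#' @param items An `absst_instrument` data frame whose `item_id`s match the
#'   matrix columns (by name if the matrix has column names, else by
#'   position).
#' @param persons Optional character vector of person identifiers; defaults
#'   to matrix rownames, else `"P001"...`.
#' @return An object of class `response_matrix`: a list with elements
#'   `values` (integer matrix with person/item dimnames) and `items`.
#' @export
response_matrix <- function(values, items, persons = NULL) {
  if (!inherits(items, "absst_instrument")) items <- instrument(items)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (ncol(values) != nrow(items)) {
    if (!is.null(colnames(values))) {
      missing_items <- setdiff(colnames(values), items$item_id)
      if (length(missing_items))
        stop("unknown item column(s): ", paste(missing_items, collapse = ", "))
      items <- items[match(colnames(values), items$item_id), , drop = FALSE]
      class(items) <- c("absst_instrument", "data.frame")
    } else {
      stop("values has ", ncol(values), " columns but instrument has ",
           nrow(items), " items")
    }
  } else if (!is.null(colnames(values))) {
    if (!setequal(colnames(values), items$item_id))
      stop("unknown item column(s): ",
           paste(setdiff(colnames(values), items$item_id), collapse = ", "))
    items <- items[match(colnames(values), items$item_id), , drop = FALSE]
    class(items) <- c("absst_instrument", "data.frame")
  }
  if (is.null(persons)) {
    persons <- rownames(values)
    if (is.null(persons)) persons <- sprintf("P%03d", seq_len(nrow(values)))
  }
  if (anyDuplicated(persons)) stop("person identifiers must be unique")
  dimnames(values) <- list(as.character(persons), items$item_id)
  rownames(items) <- NULL
  # range validation, naming the offending cell
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    bad <- which(!is.na(v) & (v < 0L | v > items$max_category[j]))
    if (length(bad))
      stop(sprintf(
        "response out of range for person '%s', item '%s': %d (allowed 0..%d)",
        rownames(values)[bad[1]], items$item_id[j], v[bad[1]],
        items$max_category[j]))
  }
  structure(list(values = values, items = items), class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$values), "persons x", ncol(x$values),
      "items\n")
  cat("Subscales:", paste(unique(x$items$subscale), collapse = ", "), "\n")
  nm <- sum(is.na(x$values))
  if (nm) cat("Missing responses:", nm, "\n")
  invisible(x)
}

#' Restrict a response matrix to a subset of items
#'
#' @param responses A [response_matrix()].
#' @param item_ids Character vector of item identifiers to keep, or the name
#'   of a subscale.
#' @return A [response_matrix()] over the selected items.
#' @export
subset_items <- function(responses, item_ids) {
  stopifnot(inherits(responses, "response_matrix"))
  if (length(item_ids) == 1L && item_ids %in% responses$items$subscale)
    item_ids <- responses$items$item_id[responses$items$subscale == item_ids]
  missing_items <- setdiff(item_ids, responses$items$item_id)
  if (length(missing_items))
    stop("items not in matrix: ", paste(missing_items, collapse = ", "))
  response_matrix(responses$values[, item_ids, drop = FALSE],
                  responses$items[match(item_ids, responses$items$item_id), ,
                                  drop = FALSE])
}

#' Drop persons with mostly-missing response records
#'
#' Persons missing more than `limit` of their item responses are removed
#' (with a warning naming them); analyses downstream treat remaining missing
#' cells pairwise.
#'
#' @param responses A [response_matrix()].
#' @param limit Maximum tolerated fraction missing (default 0.5).
#' @return A filtered [response_matrix()].
#' @export
drop_sparse_persons <- function(responses, limit = 0.5) {
  stopifnot(inherits(responses, "response_matrix"))
  frac <- rowMeans(is.na(responses$values))
  drop <- frac > limit
  if (any(drop)) {
    warning("dropping ", sum(drop), " person(s) missing >",
            round(100 * limit), "% of items: ",
            paste(rownames(responses$values)[drop], collapse = ", "))
    responses <- response_matrix(
      responses$values[!drop, , drop = FALSE], responses$items)
  }
  responses
}
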