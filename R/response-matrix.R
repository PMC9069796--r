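#' Construct a response matrix
#'
#' The central data container: a persons x items matrix of ordered-category
#' codes (integers in `1..n_categories`, `NA` for missing) plus optional
#' per-person covariates used for differential item functioning.
#'
#' @param X Integer matrix of category codes; rows are persons, columns
#'   items. `NA` marks a missing response.
#' @param n_categories Number of ordered categories `m`; every non-missing
#'   cell must lie in `1..m`.
#' @param persons,items Optional id vectors; default to dimnames or
#'   generated labels.
#' @param covariates Optional data frame (one row per person) of grouping
#'   attributes such as sex or obesity status.
#' @return An object of class `"response_matrix"` with elements `X`,
#'   `persons`, `items`, `n_categories`, `covariates`.
#' @export
response_matrix <- function(X, n_categories, persons = NULL, items = NULL,
                            covariates = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "integer"
  m <- as.integer(n_categories)
  if (m < 2L) stop("n_categories must be >= 2", call. = FALSE)
  persons <- as.character(persons %||% rownames(X) %||%
                            (if (nrow(X)) paste0("P", seq_len(nrow(X))) else character()))
  items <- as.character(items %||% colnames(X) %||%
                          (if (ncol(X)) paste0("I", seq_len(ncol(X))) else character()))
  if (length(persons) != nrow(X) || length(items) != ncol(X))
    stop("person/item ids must match the matrix dimensions", call. = FALSE)
  if (anyDuplicated(persons))
    stop("duplicate person id: ", persons[duplicated(persons)][1], call. = FALSE)
  if (anyDuplicated(items))
    stop("duplicate item id: ", items[duplicated(items)][1], call. = FALSE)
  bad <- which(!is.na(X) & (X < 1L | X > m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("response code %d outside 1..%d at person '%s', item '%s'",
                 X[bad[1, 1], bad[1, 2]], m,
                 persons[bad[1, 1]], items[bad[1, 2]]), call. = FALSE)
  }
  dimnames(X) <- list(persons, items)
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = persons)
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(X))
      stop("covariates must have one row per person", call. = FALSE)
    rownames(covariates) <- persons
  }
  structure(list(X = X, persons = persons, items = items,
                 n_categories = m, covariates = covariates),
            class = "response_matrix")
}

#' @export
dim.response_matrix <- function(x) dim(x$X)

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %d categories\n",
              nrow(x$X), ncol(x$X), x$n_categories))
  miss <- sum(is.na(x$X))
  if (miss) cat("  missing cells:", miss, "\n")
  if (ncol(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a response matrix by item or person ids
#'
#' @param rm A [response_matrix()].
#' @param items,persons Ids to retain, in the order given.
#' @return A new `response_matrix`.
#' @export
subset_items <- function(rm, items) {
  if (!all(items %in% rm$items))
    stop("unknown item id(s): ",
         paste(setdiff(items, rm$items), collapse = ", "), call. = FALSE)
  response_matrix(rm$X[, items, drop = FALSE], rm$n_categories,
                  persons = rm$persons, items = items,
                  covariates = rm$covariates)
}

#' @rdname subset_items
#' @export
subset_persons <- function(rm, persons) {
  if (!all(persons %in% rm$persons))
    stop("unknown person id(s): ",
         paste(setdiff(persons, rm$persons), collapse = ", "), call. = FALSE)
  response_matrix(rm$X[persons, , drop = FALSE], rm$n_categories,
                  persons = persons, items = rm$items,
                  covariates = rm$covariates[persons, , drop = FALSE])
}

#' Read a response CSV
#'
#' Expects a header row `person_id,<item ids...>[,<covariates...>]`. Cells in
#' item columns may be integer category codes (`1..m`), category labels
#' (case-insensitive, per the instrument's `category_labels`), or blank for
#' missing. Columns that are not item ids are kept as person covariates.
#'
#' @param path CSV file path.
#' @param schema An [instrument()]; supplies item ids, category count and
#'   label-to-code mapping.
#' @return A [response_matrix()].
#' @export
read_responses <- function(path, schema = eat26_instrument()) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  if (!ncol(df)) stop("empty CSV: ", path, call. = FALSE)
  id_col <- names(df)[1]
  persons <- df[[id_col]]
  if (anyDuplicated(persons))
    stop("duplicate person id '", persons[duplicated(persons)][1],
         "' in ", path, call. = FALSE)
  missing_items <- setdiff(schema$item_ids, names(df))
  if (length(missing_items))
    stop("missing item column(s): ", paste(missing_items, collapse = ", "),
         call. = FALSE)
  m <- schema$n_categories
  labels_lc <- tolower(schema$category_labels)
  decode <- function(v, item) {
    out <- rep(NA_integer_, length(v))
    has <- !is.na(v)
    val <- trimws(v[has])
    idx <- match(tolower(val), labels_lc)
    num <- suppressWarnings(as.integer(val))
    code <- ifelse(!is.na(idx), idx, num)
    bad <- which(is.na(code) | code < 1L | code > m)
    if (length(bad)) {
      row <- which(has)[bad[1]]
      stop(sprintf("invalid response '%s' at person '%s', item '%s'",
                   val[bad[1]], persons[row], item), call. = FALSE)
    }
    out[has] <- code
    out
  }
  X <- vapply(schema$item_ids, function(it) decode(df[[it]], it),
              integer(nrow(df)))
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, schema$item_ids))
  cov_cols <- setdiff(names(df), c(id_col, schema$item_ids))
  covariates <- if (length(cov_cols)) {
    cv <- df[cov_cols]
    cv[] <- lapply(cv, utils::type.convert, as.is = TRUE)
    cv
  } else NULL
  response_matrix(X, m, persons = persons, items = schema$item_ids,
                  covariates = covariates)
}

#' Write a response matrix to CSV
#'
#' Writes the dialect [read_responses()] reads: `person_id`, one column per
#' item (integer codes, blank for missing), then covariate columns.
#'
#' @param rm A [response_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(rm, path) {
  df <- data.frame(person_id = rm$persons, check.names = FALSE)
  for (it in rm$items) df[[it]] <- rm$X[, it]
  for (cv in names(rm$covariates)) df[[cv]] <- rm$covariates[[cv]]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
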