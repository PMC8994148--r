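#' Discrete case matrix
#'
#' The analysis-ready container consumed by screening, structure learning and
#' parameter estimation: one row per report, one column per discrete variable,
#' cells stored as 1-based state indices.
#'
#' @param data integer matrix of state indices (1-based), one named column per
#'   variable.
#' @param levels named list of character vectors giving the state labels of
#'   each variable, in index order; names must match `colnames(data)`.
#' @param outcome name of the outcome variable (must be a column of `data`).
#'
#' @return An object of class `case_matrix`: a list with elements `data`,
#'   `levels`, `cards` (named integer vector of cardinalities) and `outcome`.
#' @export
case_matrix <- function(data, levels, outcome) {
  data <- as.matrix(data)
  if (is.null(colnames(data)) || anyDuplicated(colnames(data)))
    stop("`data` must have unique column names")
  if (!setequal(names(levels), colnames(data)))
    stop("`levels` names must match the columns of `data`")
  levels <- levels[colnames(data)]
  cards <- vapply(levels, length, integer(1))
  if (any(cards < 2L))
    stop("every variable needs at least 2 states")
  storage.mode(data) <- "integer"
  for (v in colnames(data)) {
    x <- data[, v]
    if (anyNA(x) || any(x < 1L) || any(x > cards[[v]]))
      stop("invalid state index in variable '", v, "'")
  }
  if (!outcome %in% colnames(data))
    stop("outcome variable '", outcome, "' not present in the matrix")
  structure(
    list(data = data, levels = levels, cards = cards, outcome = outcome),
    class = "case_matrix"
  )
}

#' @export
print.case_matrix <- function(x, ...) {
  cat("case_matrix:", nrow(x$data), "reports x", ncol(x$data), "variables\n")
  cat("  outcome:", x$outcome, "\n")
  cat("  variables:", paste0(names(x$cards), "(", x$cards, ")",
                             collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.case_matrix <- function(x) dim(x$data)

#' Subset the rows of a case matrix
#'
#' @param m a [case_matrix()].
#' @param i integer or logical row index.
#' @return A `case_matrix` restricted to the selected reports.
#' @export
cm_subset <- function(m, i) {
  case_matrix(m$data[i, , drop = FALSE], m$levels, m$outcome)
}

#' Convert a case matrix to a data frame of state labels
#'
#' @param x a [case_matrix()].
#' @param ... unused.
#' @return A data frame with one factor column per variable.
#' @export
as.data.frame.case_matrix <- function(x, ...) {
  out <- lapply(names(x$cards), function(v) {
    factor(x$levels[[v]][x$data[, v]], levels = x$levels[[v]])
  })
  names(out) <- names(x$cards)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Write / read a case matrix as delimited text
#'
#' State labels (not indices) are written, so files are self-describing.
#'
#' @param m a [case_matrix()].
#' @param path file path.
#' @param sep field separator.
#' @export
write_case_matrix <- function(m, path, sep = ",") {
  utils::write.table(as.data.frame(m), path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' @rdname write_case_matrix
#' @param outcome outcome variable name.
#' @param levels optional named list fixing state labels (and their order);
#'   defaults to sorted observed labels per column.
#' @export
read_case_matrix <- function(path, outcome, levels = NULL, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(levels))
    levels <- lapply(df, function(x) sort(unique(as.character(x))))
  data <- vapply(names(df), function(v) {
    idx <- match(as.character(df[[v]]), levels[[v]])
    if (anyNA(idx)) stop("unknown state label in variable '", v, "'")
    idx
  }, integer(nrow(df)))
  if (nrow(df) == 1L) data <- matrix(data, nrow = 1L,
                                     dimnames = list(NULL, names(df)))
  case_matrix(data, levels, outcome)
}

# linear configuration index of a set of columns (1 when `cols` is empty)
.col_config <- function(X, cols, cards) {
  if (length(cols) == 0L) return(rep.int(1L, nrow(X)))
  w <- cumprod(c(1, cards[cols][-length(cols)]))
  as.integer(1 + (X[, cols, drop = FALSE] - 1L) %*% w)
}
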