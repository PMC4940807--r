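#' Criteria table: alternatives scored on minimization criteria
#'
#' The central container of the package: `n` named alternatives (genes or
#' probes) scored on `C` criteria, all expressed in minimization sense
#' (smaller is better). Differential-expression workflows build one with
#' [build_criteria()]; a table can also be constructed directly from any
#' numeric matrix, or read from TSV with [read_criteria_tsv()].
#'
#' @param values numeric matrix or data frame, one row per alternative and
#'   one column per criterion. All entries must be finite.
#' @param ids character vector of unique alternative labels; defaults to the
#'   row names of `values` (or `g1..gn` when absent).
#' @param criterion_names labels for the criteria; defaults to the column
#'   names of `values` (or `crit_1..crit_C`).
#' @return An object of class `criteria_table`: a list with elements
#'   `ids`, `values` (numeric matrix with dimnames set) and
#'   `criterion_names`.
#' @examples
#' ct <- criteria_table(rbind(c(1, 4), c(3, 2)), ids = c("a", "b"))
#' pareto_frontier(ct)$frontier_ids
#' @seealso [pareto_frontier()], [worked_example()]
#' @export
criteria_table <- function(values, ids = NULL, criterion_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("criteria values must be numeric")
  }
  n <- nrow(values)
  C <- ncol(values)
  if (n < 1L) stop("criteria table needs at least one alternative")
  if (C < 2L) stop("criteria table needs at least two criteria (C >= 2)")
  if (anyNA(values) || any(!is.finite(values))) {
    stop("criteria table must not contain missing or non-finite values")
  }
  if (is.null(ids)) {
    ids <- rownames(values)
    if (is.null(ids)) ids <- paste0("g", seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("length of ids must match number of rows")
  if (anyDuplicated(ids)) stop("alternative ids must be unique")
  if (is.null(criterion_names)) {
    criterion_names <- colnames(values)
    if (is.null(criterion_names)) criterion_names <- paste0("crit_", seq_len(C))
  }
  criterion_names <- as.character(criterion_names)
  if (length(criterion_names) != C) {
    stop("length of criterion_names must match number of columns")
  }
  dimnames(values) <- list(ids, criterion_names)
  structure(
    list(ids = ids, values = values, criterion_names = criterion_names),
    class = "criteria_table"
  )
}

#' @export
print.criteria_table <- function(x, ...) {
  cat(sprintf(
    "criteria_table: %d alternatives x %d criteria (minimization sense)\n",
    nrow(x$values), ncol(x$values)
  ))
  utils::str(x$values, give.attr = FALSE)
  invisible(x)
}

#' @export
dim.criteria_table <- function(x) dim(x$values)

#' Subset a criteria table by alternative
#'
#' @param x a `criteria_table`
#' @param ids character vector of alternative ids to keep (in the table's
#'   original order).
#' @return a smaller `criteria_table`
#' @keywords internal
#' @export
subset_criteria <- function(x, ids) {
  stopifnot(inherits(x, "criteria_table"))
  keep <- x$ids %in% ids
  if (!any(keep)) stop("no matching ids in criteria table")
  criteria_table(x$values[keep, , drop = FALSE],
                 ids = x$ids[keep],
                 criterion_names = x$criterion_names)
}

#' Read / write a criteria table as TSV
#'
#' The on-disk form is a tab-separated file with header
#' `id<TAB>crit_1<TAB>...<TAB>crit_C`; values are stored in minimization
#' sense, exactly as held in the table.
#'
#' @param path file path
#' @return `read_criteria_tsv` returns a `criteria_table`;
#'   `write_criteria_tsv` returns `path` invisibly.
#' @export
read_criteria_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("criteria TSV needs an id column and >= 2 criteria")
  criteria_table(as.matrix(df[, -1L, drop = FALSE]),
                 ids = df[[1L]],
                 criterion_names = colnames(df)[-1L])
}

#' @rdname read_criteria_tsv
#' @param x a `criteria_table`
#' @export
write_criteria_tsv <- function(x, path) {
  stopifnot(inherits(x, "criteria_table"))
  df <- data.frame(id = x$ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", x$criterion_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
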