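#' Expression dataset: probes x samples with sample annotations
#'
#' Container for a two-state (or multi-state) expression experiment:
#' a numeric probe x sample matrix (missing entries allowed), optional
#' per-probe gene symbols, and per-sample annotations such as disease
#' state, smoking status and gender. Built by [read_gds_soft()],
#' [read_expression_tsv()] or [generate_dataset()].
#'
#' @param values numeric matrix, probes in rows, samples in columns
#' @param probe_ids unique row labels; defaults to rownames
#' @param sample_ids unique column labels; defaults to colnames
#' @param gene_symbols optional per-probe symbol vector (may contain "")
#' @param sample_annotations data frame with one row per sample (rownames
#'   are sample ids) and one column per annotation key
#' @return an object of class `expression_dataset`
#' @export
expression_dataset <- function(values, probe_ids = NULL, sample_ids = NULL,
                               gene_symbols = NULL,
                               sample_annotations = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (is.null(probe_ids)) probe_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- colnames(values)
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample ids are required")
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values)) stop("probe_ids length mismatch")
  if (length(sample_ids) != ncol(values)) stop("sample_ids length mismatch")
  if (anyDuplicated(probe_ids)) stop("duplicated probe ids")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids")
  if (!is.null(gene_symbols) && length(gene_symbols) != length(probe_ids)) {
    stop("gene_symbols length mismatch")
  }
  if (is.null(sample_annotations)) {
    sample_annotations <- data.frame(row.names = sample_ids)
  }
  if (!all(rownames(sample_annotations) == sample_ids)) {
    sample_annotations <- sample_annotations[sample_ids, , drop = FALSE]
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(values = values, probe_ids = probe_ids, sample_ids = sample_ids,
         gene_symbols = gene_symbols, sample_annotations = sample_annotations),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  keys <- colnames(x$sample_annotations)
  if (length(keys)) {
    cat("  annotations:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Select samples by annotation filters
#'
#' Returns the sample ids matching every filter (conjunction). Annotation
#' keys and values are normalized (lower-cased, trimmed) on both sides, so
#' `disease.state = "Lung Cancer"` matches a stored `"lung cancer"`.
#'
#' @param dataset an [expression_dataset()]
#' @param filters named character vector or list, annotation key -> value
#' @return character vector of matching sample ids in dataset column order
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 10, seed = 1))$dataset
#' length(select_samples(ds, c(disease.state = "control")))
#' @export
select_samples <- function(dataset, filters = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.null(filters) || !length(filters)) return(dataset$sample_ids)
  filters <- unlist(filters)
  ann <- dataset$sample_annotations
  keys <- normalize_key(names(filters))
  have <- normalize_key(colnames(ann))
  missing <- setdiff(keys, have)
  if (length(missing)) {
    stop("unknown annotation key(s): ", paste(missing, collapse = ", "),
         "; available: ", paste(colnames(ann), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(ann))
  for (f in seq_along(filters)) {
    col <- ann[[which(have == keys[f])[1]]]
    keep <- keep & !is.na(col) &
      normalize_label(col) == normalize_label(filters[[f]])
  }
  ids <- dataset$sample_ids[keep]
  if (!length(ids)) warning("no samples match the given filters")
  ids
}

normalize_label <- function(x) tolower(trimws(as.character(x)))

# keys additionally fold "." and "_" to spaces, so `disease.state` filters
# match the `disease state` subset type of SOFT files
normalize_key <- function(x) gsub("[._]", " ", normalize_label(x))

#' Read an expression matrix from TSV with a group-assignment sidecar
#'
#' The TSV holds probes in rows (first column `ID_REF`, optional second
#' column `IDENTIFIER` with gene symbols) and samples in columns. The
#' optional sidecar is a two-or-more-column TSV mapping `sample` ids to
#' annotation values, one annotation per remaining column.
#'
#' @param path expression TSV path
#' @param groups_path optional sidecar TSV path
#' @return an [expression_dataset()]
#' @export
read_expression_tsv <- function(path, groups_path = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "null", ""))
  if (!ncol(df) >= 2L) stop("expression TSV needs id plus sample columns")
  probe_ids <- as.character(df[[1L]])
  symbols <- NULL
  first_data <- 2L
  if (ncol(df) >= 2L && toupper(colnames(df)[2L]) == "IDENTIFIER") {
    symbols <- as.character(df[[2L]])
    first_data <- 3L
  }
  values <- as.matrix(df[, first_data:ncol(df), drop = FALSE])
  ann <- NULL
  if (!is.null(groups_path)) {
    g <- utils::read.delim(groups_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
    rownames(g) <- g[[1L]]
    ann <- g[colnames(values), -1L, drop = FALSE]
    rownames(ann) <- colnames(values)
  }
  expression_dataset(values, probe_ids = probe_ids,
                     sample_ids = colnames(values), gene_symbols = symbols,
                     sample_annotations = ann)
}
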