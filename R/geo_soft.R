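#' Read a GEO SOFT / GDS expression file
#'
#' Parses the curated GDS dialect of GEO's SOFT format: `^DATASET` /
#' `!dataset_...` metadata headers, `#` column declarations, `^SUBSET`
#' blocks declaring sample groups, and the probes x samples value table
#' between `!dataset_table_begin` and `!dataset_table_end`. Each subset
#' block becomes one sample annotation: its `!subset_type` (e.g.
#' `disease.state`, `stress`, `gender`) is the annotation key and its
#' `!subset_description` the value for the listed `!subset_sample_id`s.
#' `null` and empty table cells are read as missing. Line endings may be
#' LF or CRLF.
#'
#' @param path path to a SOFT-format text file
#' @param quiet suppress the row/column count message
#' @return an [expression_dataset()]
#' @export
read_gds_soft <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)

  tb <- grep("^!dataset_table_begin", lines)
  te <- grep("^!dataset_table_end", lines)
  if (length(tb) != 1L || length(te) != 1L || te <= tb + 1L) {
    stop("no data table found (missing !dataset_table_begin/_end)")
  }

  # subset blocks
  subsets <- list()
  cur <- NULL
  for (ln in seq_len(tb - 1L)) {
    line <- lines[ln]
    if (startsWith(line, "^SUBSET")) {
      if (!is.null(cur)) subsets[[length(subsets) + 1L]] <- cur
      cur <- list()
    } else if (!is.null(cur) && startsWith(line, "!subset_")) {
      kv <- strsplit(sub("^!subset_", "", line), "\\s*=\\s*")[[1L]]
      if (length(kv) == 2L) cur[[kv[1L]]] <- kv[2L]
    } else if (startsWith(line, "^") && !is.null(cur)) {
      subsets[[length(subsets) + 1L]] <- cur
      cur <- NULL
    }
  }
  if (!is.null(cur)) subsets[[length(subsets) + 1L]] <- cur

  # value table
  header <- strsplit(lines[tb + 1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L || toupper(header[1L]) != "ID_REF") {
    stop("malformed table header (expected ID_REF-led columns)")
  }
  has_symbol <- length(header) >= 2L && toupper(header[2L]) == "IDENTIFIER"
  first_data <- if (has_symbol) 3L else 2L
  data_lines <- lines[(tb + 2L):(te - 1L)]
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop(sprintf("unparseable data row at line %d: %d fields, expected %d",
                 tb + 1L + bad, nf[bad], length(header)))
  }
  cells <- matrix(unlist(fields, use.names = FALSE),
                  nrow = length(fields), byrow = TRUE)
  probe_ids <- cells[, 1L]
  if (anyDuplicated(probe_ids)) {
    stop("duplicated probe ids in data table: ",
         paste(utils::head(unique(probe_ids[duplicated(probe_ids)]), 3),
               collapse = ", "))
  }
  symbols <- if (has_symbol) cells[, 2L] else NULL
  raw <- cells[, first_data:ncol(cells), drop = FALSE]
  is_missing <- raw %in% c("", "null", "NA") | is.na(raw)
  values <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad_cell <- which(is.na(values) & !is_missing, arr.ind = TRUE)
  if (nrow(bad_cell)) {
    stop(sprintf("unparseable data row at line %d: non-numeric value '%s'",
                 tb + 1L + bad_cell[1L, 1L], raw[bad_cell[1L, , drop = FALSE]]))
  }
  sample_ids <- header[first_data:length(header)]

  # subset blocks -> per-sample annotation columns
  ann <- data.frame(row.names = sample_ids)
  for (s in subsets) {
    if (is.null(s$type) || is.null(s$sample_id)) next
    ids <- trimws(strsplit(s$sample_id, ",", fixed = TRUE)[[1L]])
    unknown <- setdiff(ids, sample_ids)
    if (length(unknown)) {
      stop("subset '", s$description %||% s$type,
           "' references unknown sample id(s): ",
           paste(utils::head(unknown, 3), collapse = ", "))
    }
    key <- s$type
    if (!key %in% colnames(ann)) ann[[key]] <- NA_character_
    ann[ids, key] <- s$description %||% NA_character_
  }

  if (!quiet) {
    message(sprintf("read %d probes x %d samples (%d annotation key(s))",
                    length(probe_ids), length(sample_ids), ncol(ann)))
  }
  expression_dataset(values, probe_ids = probe_ids, sample_ids = sample_ids,
                     gene_symbols = symbols, sample_annotations = ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a frontier report
#'
#' The report is a TSV with columns `id`, `beta`, `layer`, `on_frontier`
#' (0/1) and `duplicate_group` (0 = unique criteria vector, k = member of
#' the k-th identical-vector group), preceded by `#`-prefixed metadata
#' lines recording the tool version, penalty W, criteria count C, the
#' membership threshold C*W and any contrast labels or seed supplied.
#'
#' @param result a `frontier_result` or the list returned by
#'   [peel_frontiers()]
#' @param criteria the [criteria_table()] the result was computed from
#' @param path output file path
#' @param contrasts optional character vector of contrast labels to record
#' @param seed optional integer seed to record
#' @return `path`, invisibly
#' @export
write_frontier_report <- function(result, criteria, path, contrasts = NULL,
                                  seed = NULL) {
  if (inherits(result, "frontier_result")) result <- list(result)
  stopifnot(length(result) >= 1L,
            all(vapply(result, inherits, logical(1), "frontier_result")))
  first <- result[[1L]]
  rows <- frontier_report_rows(result)
  dup_of <- duplicate_index(first$duplicate_groups, rows$id)

  meta <- c(
    sprintf("# tool = mcoFrontier %s",
            as.character(utils::packageVersion("mcoFrontier"))),
    sprintf("# W = %g", first$W),
    sprintf("# C = %d", first$C),
    sprintf("# threshold = %g", first$threshold),
    if (!is.null(contrasts))
      sprintf("# contrasts = %s", paste(contrasts, collapse = ", ")),
    if (!is.null(seed)) sprintf("# seed = %d", as.integer(seed)),
    sprintf("# generated = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  rows$duplicate_group <- dup_of
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

frontier_report_rows <- function(layers) {
  rows <- lapply(layers, function(res) {
    data.frame(id = res$frontier_ids,
               beta = unname(res$beta[res$frontier_ids]),
               layer = res$layer, on_frontier = 1L,
               stringsAsFactors = FALSE)
  })
  last <- layers[[length(layers)]]
  rest <- setdiff(last$ids, last$frontier_ids)
  if (length(rest)) {
    rows[[length(rows) + 1L]] <-
      data.frame(id = rest, beta = unname(last$beta[rest]),
                 layer = last$layer, on_frontier = 0L,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

duplicate_index <- function(groups, ids) {
  idx <- integer(length(ids))
  for (g in seq_along(groups)) idx[ids %in% groups[[g]]] <- g
  idx
}

#' @rdname write_frontier_report
#' @return `read_frontier_report` returns the report data frame with the
#'   metadata lines attached as the `"metadata"` attribute.
#' @export
read_frontier_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}
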