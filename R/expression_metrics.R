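#' Define a two-group contrast
#'
#' A contrast names two disjoint sample groups ("control" vs "cancer" in
#' the typical design) and the statistics whose absolute group difference
#' becomes a performance measure. One criterion column is produced per
#' requested statistic, so a single contrast with
#' `statistics = c("mean", "median")` yields the classic two-measure
#' single-study analysis, and several median-only contrasts yield a
#' meta-analysis.
#'
#' @param name contrast label (used as criterion-column prefix)
#' @param group_a,group_b character vectors of sample ids; disjoint and
#'   nonempty
#' @param statistics subset of `c("mean", "median")`
#' @return an object of class `group_contrast`
#' @export
group_contrast <- function(name, group_a, group_b,
                           statistics = c("mean", "median")) {
  statistics <- match.arg(statistics, c("mean", "median"),
                          several.ok = TRUE)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (!length(group_a) || !length(group_b)) {
    stop("contrast '", name, "': both groups must be nonempty")
  }
  if (length(intersect(group_a, group_b))) {
    stop("contrast '", name, "': groups overlap: ",
         paste(utils::head(intersect(group_a, group_b), 3), collapse = ", "))
  }
  structure(list(name = as.character(name), group_a = group_a,
                 group_b = group_b, statistics = statistics),
            class = "group_contrast")
}

#' Absolute group-statistic difference per gene
#'
#' For each probe, computes `|stat(group_a) - stat(group_b)|` where `stat`
#' is the arithmetic mean or the sample median (even-count medians are the
#' midpoint of the two central order statistics, as computed by
#' [stats::median()]). Statistics are taken over non-missing entries; a
#' probe with fewer than two usable values in either group cannot support
#' the statistic and yields `NA`, to be excluded (and reported) downstream.
#'
#' @param dataset an [expression_dataset()]
#' @param contrast a [group_contrast()] (its first statistic is used unless
#'   `statistic` is given)
#' @param statistic `"mean"` or `"median"`
#' @return named numeric vector of nonnegative differences, `NA` where a
#'   group had fewer than two usable values
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 20, seed = 4))$dataset
#' ctr <- group_contrast("cvn",
#'   select_samples(ds, c(disease.state = "control")),
#'   select_samples(ds, c(disease.state = "lung cancer")))
#' head(group_stat_difference(ds, ctr, "mean"))
#' @export
group_stat_difference <- function(dataset, contrast,
                                  statistic = contrast$statistics[1L]) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(contrast, "group_contrast"))
  statistic <- match.arg(statistic, c("mean", "median"))
  for (grp in list(contrast$group_a, contrast$group_b)) {
    missing <- setdiff(grp, dataset$sample_ids)
    if (length(missing)) {
      stop("contrast '", contrast$name, "': unknown sample id(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
  }
  stat_of <- function(ids) {
    m <- dataset$values[, ids, drop = FALSE]
    usable <- rowSums(!is.na(m)) >= 2L
    s <- if (statistic == "mean") {
      rowMeans(m, na.rm = TRUE)
    } else {
      apply(m, 1L, stats::median, na.rm = TRUE)
    }
    s[!usable] <- NA_real_
    s
  }
  d <- abs(stat_of(contrast$group_a) - stat_of(contrast$group_b))
  names(d) <- dataset$probe_ids
  d
}

#' Transform nonnegative differences to minimization direction
#'
#' The frontier machinery minimizes, while large expression changes are
#' what we seek; the differences are therefore negated so that the largest
#' change maps to the smallest criterion value. Any strictly decreasing
#' transform gives the same frontier (monotone invariance); negation is
#' used for transparency. Negative inputs are rejected since they signal
#' that the absolute value was skipped upstream.
#'
#' @param values numeric vector of nonnegative differences (NA allowed)
#' @return the negated values
#' @export
to_minimization <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    stop("negative differences supplied; take the absolute value first")
  }
  -values
}

#' Build a criteria table from grouped expression data
#'
#' Turns one or more contrasts into the criteria table consumed by
#' [pareto_frontier()]: one column per (contrast, statistic) pair, each the
#' negated absolute group difference. Expression values are used exactly as
#' stored — no normalization or log transform — and probes are kept at row
#' (probe) level, with gene symbols carried along for reporting. Probes
#' lacking two usable values in any group of any contrast are excluded and
#' listed in the `excluded` attribute.
#'
#' @param dataset an [expression_dataset()]
#' @param contrasts a [group_contrast()] or list of them; the total number
#'   of (contrast, statistic) columns must be between 2 and 5 (five
#'   measures is the proven limit of the scheme)
#' @return a [criteria_table()] with attributes `excluded` (character
#'   vector of dropped probe ids) and `gene_symbols` (named vector, when
#'   the dataset carries symbols)
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 50, seed = 2))$dataset
#' ctr <- group_contrast("cvn",
#'   select_samples(ds, c(disease.state = "control")),
#'   select_samples(ds, c(disease.state = "lung cancer")))
#' ct <- build_criteria(ds, ctr)
#' dim(ct)
#' @export
build_criteria <- function(dataset, contrasts) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (inherits(contrasts, "group_contrast")) contrasts <- list(contrasts)
  stopifnot(all(vapply(contrasts, inherits, logical(1), "group_contrast")))
  nm <- vapply(contrasts, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    stop("duplicated contrast name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  C <- sum(vapply(contrasts, function(x) length(x$statistics), integer(1)))
  if (C < 2L) stop("at least 2 criteria required; request more statistics")
  if (C > 5L) {
    stop("more than 5 criteria requested (", C, "); the pairwise scheme ",
         "is proven for up to five performance measures — drop contrasts ",
         "or statistics")
  }
  cols <- list()
  for (ctr in contrasts) {
    for (s in ctr$statistics) {
      cols[[paste(ctr$name, s, sep = ".")]] <-
        to_minimization(group_stat_difference(dataset, ctr, s))
    }
  }
  m <- do.call(cbind, cols)
  keep <- rowSums(is.na(m)) == 0L
  excluded <- dataset$probe_ids[!keep]
  ct <- criteria_table(m[keep, , drop = FALSE],
                       ids = dataset$probe_ids[keep],
                       criterion_names = names(cols))
  attr(ct, "excluded") <- excluded
  if (!is.null(dataset$gene_symbols)) {
    attr(ct, "gene_symbols") <-
      stats::setNames(dataset$gene_symbols[keep], ct$ids)
  }
  ct
}
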