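#' Specification for a synthetic two-group expression dataset
#'
#' Describes a planted-truth dataset emulating the structure of a curated
#' two-state expression study: a noisy background of exchangeable genes
#' plus a small set of planted genes whose expression is shifted in the
#' non-reference group(s). Defaults mirror a small single-study design:
#' 500 genes, 15 control and 16 cancer samples, 5 planted genes shifted by
#' ten background standard deviations.
#'
#' @param n_genes number of genes (rows)
#' @param group_sizes named integer vector, group label -> sample count;
#'   the FIRST group is the reference ("control"), planted genes are
#'   shifted in all later groups
#' @param n_planted number of large-effect genes, `<= n_genes`
#' @param noise_sd background standard deviation (expression units)
#' @param effect_size shift added to planted genes in non-reference groups
#'   (expression units); default `10 * noise_sd`
#' @param baseline background location
#' @param seed integer seed; randomness is fully determined by it
#' @param background `"normal"` for Gaussian noise or `"lognormal"` for a
#'   heavy-tailed background, which drives mean and median apart and makes
#'   the two statistics genuinely conflicting criteria
#' @return an object of class `synthetic_spec`
#' @export
synthetic_spec <- function(n_genes = 500,
                           group_sizes = c(control = 15, cancer = 16),
                           n_planted = 5, noise_sd = 1,
                           effect_size = 10 * noise_sd, baseline = 8,
                           seed = 1L,
                           background = c("normal", "lognormal")) {
  background <- match.arg(background)
  if (is.null(names(group_sizes)) || any(names(group_sizes) == "")) {
    stop("group_sizes must be a named vector")
  }
  if (any(group_sizes < 1)) stop("all group sizes must be positive")
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_planted < 0 || n_planted > n_genes) {
    stop("n_planted must lie in [0, n_genes]")
  }
  if (noise_sd <= 0) stop("noise_sd must be positive")
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 n_planted = as.integer(n_planted), noise_sd = noise_sd,
                 effect_size = effect_size, baseline = baseline,
                 seed = as.integer(seed), background = background),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Background genes are i.i.d. around `baseline` with standard deviation
#' `noise_sd` in every group; the planted genes additionally receive
#' `effect_size` in every non-reference group. Sample annotations mimic
#' curated GEO subsets: `disease.state` carries the group label (the
#' reference group as `"control"`, others as `"lung cancer"` unless a
#' group is itself named e.g. `"cancer"`, which is kept verbatim as
#' annotation value), plus alternating `stress` (smoking status) and
#' `gender` labels so that annotation-filter logic can be exercised.
#' Output is fully reproducible from `spec$seed`; the global RNG state is
#' restored on exit.
#'
#' @param spec a [synthetic_spec()]
#' @return list with `dataset` (an [expression_dataset()]), `planted`
#'   (character vector of planted gene ids) and `spec`
#' @examples
#' out <- generate_dataset(synthetic_spec(n_genes = 100, seed = 11))
#' dim(out$dataset)
#' out$planted
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  n_samples <- length(groups)
  sample_ids <- sprintf("GSM%04d", seq_len(n_samples))
  gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))

  noise <- switch(spec$background,
    normal = stats::rnorm(spec$n_genes * n_samples, 0, spec$noise_sd),
    lognormal = {
      # standardized lognormal: mean 0, sd noise_sd, right-skewed
      z <- stats::rlnorm(spec$n_genes * n_samples, 0, 1)
      (z - exp(0.5)) / sqrt((exp(1) - 1) * exp(1)) * spec$noise_sd
    })
  values <- matrix(spec$baseline + noise, nrow = spec$n_genes,
                   dimnames = list(gene_ids, sample_ids))

  planted <- sort(sample(gene_ids, spec$n_planted))
  shifted <- groups != names(spec$group_sizes)[1L]
  # Planted genes emulate biomarkers with distinct response architectures:
  # gene j gets a uniform shift that grows with j (raising its median
  # difference) plus an extreme-responder component concentrated in a
  # single shifted sample that shrinks with j (raising its mean but not
  # its median difference). The profiles trade mean against median, so the
  # planted set is mutually Pareto-incomparable — the regime a
  # multi-criteria frontier is meant to capture — while every planted
  # difference still clears the background by >= effect_size in both
  # statistics.
  k <- length(planted)
  n_shift <- sum(shifted)
  for (j in seq_len(k)) {
    uniform <- spec$effect_size * (1 + 0.25 * (j - 1))
    values[planted[j], shifted] <- values[planted[j], shifted] + uniform
    extreme <- 0.5 * spec$effect_size * (k - j)
    if (extreme > 0 && n_shift > 0) {
      one <- which(shifted)[1L]
      values[planted[j], one] <- values[planted[j], one] + extreme * n_shift
    }
  }

  disease <- ifelse(groups == names(spec$group_sizes)[1L],
                    "control", groups)
  disease[disease == "cancer"] <- "lung cancer"
  ann <- data.frame(
    disease.state = disease,
    stress = rep_len(c("never smoked", "currently smoking"), n_samples),
    gender = rep_len(c("female", "male"), n_samples),
    row.names = sample_ids, stringsAsFactors = FALSE
  )

  ds <- expression_dataset(values, probe_ids = gene_ids,
                           sample_ids = sample_ids,
                           gene_symbols = toupper(gene_ids),
                           sample_annotations = ann)
  list(dataset = ds, planted = planted, spec = spec)
}

#' Six-gene worked example
#'
#' The canonical small instance used throughout the documentation and
#' tests: six genes scored on two minimization criteria,
#' g1(1,4), g2(3,4), g3(5,6), g4(7,5), g5(3,2), g6(4,1). Its
#' Pareto-efficient frontier is {g1, g5, g6} and the membership cutoff at
#' the default penalty W = 1000 is C*W = 2000.
#'
#' @return a [criteria_table()] with 6 alternatives and 2 criteria
#' @examples
#' pareto_frontier(worked_example())$frontier_ids
#' @export
worked_example <- function() {
  criteria_table(
    rbind(g1 = c(1, 4), g2 = c(3, 4), g3 = c(5, 6),
          g4 = c(7, 5), g5 = c(3, 2), g6 = c(4, 1)),
    criterion_names = c("m1", "m2")
  )
}

#' Write a miniature SOFT-format fixture
#'
#' Emits a small, fully deterministic GDS-dialect SOFT file (6 probes x 8
#' samples, two subset annotations, one `null` cell) used to exercise the
#' SOFT reader without external downloads.
#'
#' @param path output file path
#' @param eol line terminator; `"\n"` (default) or `"\r\n"` to emulate
#'   CRLF files
#' @return `path`, invisibly
#' @export
write_mini_soft <- function(path, eol = "\n") {
  samples <- sprintf("GSM%03d", 1:8)
  header <- c(
    "^DATABASE = GeoMiniature",
    "!Database_name = miniature fixture",
    "^DATASET = MINI0001",
    "!dataset_title = synthetic miniature two-state dataset",
    "!dataset_sample_count = 8",
    "#ID_REF = probe identifier",
    "#IDENTIFIER = gene symbol",
    "^SUBSET = MINI0001_1",
    "!subset_dataset_id = MINI0001",
    "!subset_description = normal",
    sprintf("!subset_sample_id = %s", paste(samples[1:4], collapse = ",")),
    "!subset_type = disease state",
    "^SUBSET = MINI0001_2",
    "!subset_dataset_id = MINI0001",
    "!subset_description = lung cancer",
    sprintf("!subset_sample_id = %s", paste(samples[5:8], collapse = ",")),
    "!subset_type = disease state",
    "^SUBSET = MINI0001_3",
    "!subset_dataset_id = MINI0001",
    "!subset_description = never smoked",
    sprintf("!subset_sample_id = %s",
            paste(samples[c(1, 2, 5, 6)], collapse = ",")),
    "!subset_type = stress",
    "^SUBSET = MINI0001_4",
    "!subset_dataset_id = MINI0001",
    "!subset_description = currently smoking",
    sprintf("!subset_sample_id = %s",
            paste(samples[c(3, 4, 7, 8)], collapse = ",")),
    "!subset_type = stress",
    "^DATASET = MINI0001",
    "!dataset_table_begin",
    paste(c("ID_REF", "IDENTIFIER", samples), collapse = "\t")
  )
  # A1 and A3 are the two strong movers, built to be incomparable: A1 has
  # the larger mean shift (one outlying cancer sample), A3 the larger
  # median shift; the rest are background.
  vals <- rbind(
    A1 = c(7.0, 7.1, 6.9, 7.0, 20.0, 9.2, 9.0, 9.0),
    A2 = c(5.0, 5.2, 5.1, 4.9, 5.1, 5.0, 4.8, 5.2),
    A3 = c(6.5, 6.6, 6.4, 6.5, 2.5, 2.6, 2.4, 2.5),
    A4 = c(8.0, 8.1, 7.9, 8.2, 8.1, 8.0, 7.9, 8.1),
    A5 = c(4.2, 4.0, 4.1, 4.3, 4.1, 4.2, 4.0, 4.2),
    A6 = c(9.0, 9.2, 9.1, 8.9, 9.1, 9.0, 9.2, 8.9)
  )
  rows <- vapply(rownames(vals), function(p) {
    cells <- format(vals[p, ], trim = TRUE)
    if (p == "A5") cells[3] <- "null"   # exercise missing-value handling
    paste(c(p, paste0("SYM_", p), cells), collapse = "\t")
  }, character(1))
  footer <- "!dataset_table_end"
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, rows, footer), con, sep = eol)
  invisible(path)
}
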