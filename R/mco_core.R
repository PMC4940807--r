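#' Per-criterion pairwise comparison matrix
#'
#' Builds the n x n comparison matrix for one criterion of a minimization
#' problem. Entry (i, j) encodes how alternative i compares with
#' alternative j on that criterion:
#' \itemize{
#'   \item `-1` when i is strictly better (smaller value),
#'   \item `0` on a tie,
#'   \item `W` (the penalty) when i is strictly worse (larger value).
#' }
#' The diagonal is therefore all zeros, and for every off-diagonal pair the
#' entries (i, j) and (j, i) are either both 0 or the pair `{-1, W}`.
#'
#' @param criteria a [criteria_table()]
#' @param k criterion index, `1 <= k <= C`
#' @param W penalty constant, a positive integer with `W > C` so that sums
#'   of comparison entries over criteria cannot collide with multiples of
#'   `W` (the accumulated value is always `p*W - q` with `0 <= q <= C`).
#' @param tie_tol nonnegative tolerance for declaring a tie:
#'   `|m_i - m_j| <= tie_tol` scores 0. The default 0 compares raw values
#'   exactly, which is the intended behaviour for stored expression values.
#' @return an n x n numeric matrix with entries in `{-1, 0, W}`
#' @examples
#' d <- build_delta(worked_example(), k = 1)
#' d[1, 2]  # -1: gene 1 beats gene 2 on the first criterion
#' @export
build_delta <- function(criteria, k, W = 1000, tie_tol = 0) {
  stopifnot(inherits(criteria, "criteria_table"))
  C <- ncol(criteria$values)
  if (length(k) != 1L || is.na(k) || k < 1L || k > C) {
    stop(sprintf("criterion index k must be in 1..%d", C))
  }
  check_penalty(W, C)
  if (tie_tol < 0) stop("tie_tol must be nonnegative")
  v <- criteria$values[, k]
  if (any(!is.finite(v))) stop("non-finite value encountered in criterion ", k)
  d <- outer(v, v, "-")                 # d[i, j] = m_i - m_j
  delta <- matrix(0, nrow = length(v), ncol = length(v))
  delta[d < -tie_tol] <- -1
  delta[d > tie_tol] <- W
  delta
}

#' Accumulate per-criterion comparison matrices
#'
#' Sums the `C` per-criterion matrices into a single matrix
#' `alpha[i, j] = sum_k delta_k[i, j]`. Because each summand lies in
#' `{-1, 0, W}`, every entry has the form `p*W - q` where `p` counts the
#' criteria on which i is worse than j and `q` those on which i is better;
#' with `W > C` the two counts are recoverable from the entry.
#'
#' @param deltas list of matrices from [build_delta()] (same shape, same W)
#' @return the n x n summation matrix
#' @export
accumulate_alpha <- function(deltas) {
  if (!length(deltas)) stop("need at least one delta matrix")
  dims <- vapply(deltas, dim, integer(2))
  if (any(dims != dims[, 1])) stop("delta matrices differ in shape")
  Reduce(`+`, deltas)
}

#' Penalize the accumulated comparison matrix
#'
#' Converts the summation matrix into the penalty matrix used for the
#' frontier test. `alpha[i, j]` belongs to `{0, W, ..., (C-1)*W}` exactly
#' when j is at least as good as i on every criterion without beating it
#' everywhere (ties on the rest), and equals `C*W` when i is worse on all
#' criteria. Those are the configurations in which i cannot exclude j from
#' dominating it, so they are penalized:
#' \itemize{
#'   \item `gamma = (C/2)*W` for `alpha` in `{0, W, ..., (C-1)*W}`,
#'   \item `gamma = C*W` for `alpha = C*W`,
#'   \item `gamma = 0` otherwise (i is strictly better somewhere).
#' }
#' For C = 2 this reduces to `gamma = W` for `alpha` in `{0, W}` and
#' `gamma = 2W` for `alpha = 2W`. The diagonal (`alpha = 0`) always scores
#' `(C/2)*W`, which is why the frontier threshold is `C*W`: one penalized
#' off-diagonal entry pushes the row sum to at least `C*W`.
#'
#' @param alpha matrix from [accumulate_alpha()]
#' @param C number of criteria the deltas were built from
#' @param W the penalty constant used upstream
#' @return n x n penalty matrix with entries in `{0, (C/2)*W, C*W}`
#' @export
assess_gamma <- function(alpha, C, W = 1000) {
  check_penalty(W, C)
  if (!is.matrix(alpha) || nrow(alpha) != ncol(alpha)) {
    stop("alpha must be a square matrix")
  }
  check_alpha_values(alpha, C, W)
  n <- nrow(alpha)
  gamma <- matrix(0, n, n)
  weak <- matrix(alpha %in% (W * (0:(C - 1L))), n, n)
  gamma[weak] <- (C / 2) * W
  gamma[alpha == C * W] <- C * W
  gamma
}

#' Row sums of the penalty matrix
#'
#' `beta[i]` aggregates all penalties against alternative i, including the
#' self-comparison term `(C/2)*W` on the diagonal. An alternative is
#' nondominated exactly when no other alternative penalizes it, i.e. when
#' `beta[i] = (C/2)*W`, strictly below the frontier cutoff `C*W`.
#'
#' @param gamma matrix from [assess_gamma()]
#' @return numeric vector of row sums
#' @export
beta_sums <- function(gamma) {
  if (!is.matrix(gamma) || nrow(gamma) != ncol(gamma)) {
    stop("gamma must be a square matrix")
  }
  rowSums(gamma)
}

#' Pareto-efficient frontier by the penalty-matrix scheme
#'
#' Finds the nondominated alternatives of a minimization criteria table by
#' full pairwise comparison: the per-criterion matrices are accumulated,
#' penalized, and row-summed, and the frontier is the set with
#' `beta < C*W`. All arithmetic is on exact integer-valued matrices, so the
#' threshold test involves no floating-point tolerance.
#'
#' Alternatives with exactly identical criteria vectors would penalize one
#' another under the raw scheme and all drop off the frontier even when
#' nondominated. By default such duplicates are collapsed to a single
#' representative before the computation and restored afterwards, which
#' matches the classical Pareto conditions (a duplicate is not "strictly
#' better" anywhere, hence does not dominate). Set
#' `strict_duplicates = TRUE` for the raw behaviour in which every member
#' of a duplicate group is excluded. Either way the duplicate groups are
#' reported.
#'
#' For tables larger than `max_direct` rows the n x n matrices become the
#' memory bottleneck and the computation is routed through
#' [tournament_frontier()], which gives the identical frontier.
#'
#' @param criteria a [criteria_table()]
#' @param W penalty constant (default 1000), must exceed the number of
#'   criteria
#' @param strict_duplicates keep the raw exclusion of identical-vector
#'   groups instead of collapsing them (default `FALSE`)
#' @param tie_tol tie tolerance passed to [build_delta()]
#' @param max_direct row count above which the tournament path is used
#' @return an object of class `frontier_result`: list with
#'   `frontier_ids` (ids with `beta < C*W`, in table order), `beta`
#'   (named vector over all alternatives), `threshold` (`C*W`), `W`, `C`,
#'   `layer` (0 for a direct computation) and `duplicate_groups` (list of
#'   id vectors sharing identical criteria vectors).
#' @examples
#' res <- pareto_frontier(worked_example())
#' res$frontier_ids   # "g1" "g5" "g6"
#' res$threshold      # 2000
#' @export
pareto_frontier <- function(criteria, W = 1000, strict_duplicates = FALSE,
                            tie_tol = 0, max_direct = 5000) {
  stopifnot(inherits(criteria, "criteria_table"))
  C <- ncol(criteria$values)
  check_penalty(W, C)
  n <- nrow(criteria$values)
  if (n > max_direct) {
    return(tournament_frontier(criteria, partition_size = max_direct, W = W,
                               strict_duplicates = strict_duplicates,
                               tie_tol = tie_tol))
  }

  dup <- duplicate_groups(criteria)
  work <- criteria
  if (!strict_duplicates && length(dup$groups)) {
    work <- subset_criteria(criteria, criteria$ids[dup$representative])
  }

  beta_rep <- frontier_beta(work, W, tie_tol)
  threshold <- C * W

  if (strict_duplicates || !length(dup$groups)) {
    beta <- beta_rep[criteria$ids]
  } else {
    # every member of a duplicate group inherits its representative's beta
    beta <- beta_rep[dup$key_of[criteria$ids]]
  }
  names(beta) <- criteria$ids
  frontier <- criteria$ids[beta < threshold]

  new_frontier_result(
    ids = criteria$ids, beta = beta, frontier_ids = frontier,
    threshold = threshold, W = W, C = C, layer = 0L,
    duplicate_groups = dup$groups
  )
}

# beta vector of a table, named by representative id
frontier_beta <- function(criteria, W, tie_tol) {
  C <- ncol(criteria$values)
  n <- nrow(criteria$values)
  alpha <- matrix(0, n, n)
  for (k in seq_len(C)) {
    alpha <- alpha + build_delta(criteria, k, W, tie_tol)
  }
  beta <- beta_sums(assess_gamma(alpha, C, W))
  names(beta) <- criteria$ids
  beta
}

#' Nondominated set by direct definition (test oracle)
#'
#' Literal implementation of the Pareto-dominance conditions: alternative j
#' dominates i when j is no worse than i on every criterion and strictly
#' better on at least one. Identical vectors do not dominate each other and
#' are all retained. Quadratic in n and independent of the penalty-matrix
#' path; used to cross-check [pareto_frontier()].
#'
#' @inheritParams pareto_frontier
#' @return a `frontier_result` (beta is `NA`; this path does not compute it)
#' @export
brute_force_frontier <- function(criteria) {
  stopifnot(inherits(criteria, "criteria_table"))
  vals <- criteria$values
  n <- nrow(vals)
  C <- ncol(vals)
  dominated <- logical(n)
  for (i in seq_len(n)) {
    vi <- matrix(vals[i, ], n, C, byrow = TRUE)
    no_worse <- rowSums(vals <= vi) == C
    better <- rowSums(vals < vi) > 0
    dom_by <- no_worse & better
    dom_by[i] <- FALSE
    dominated[i] <- any(dom_by)
  }
  dup <- duplicate_groups(criteria)
  new_frontier_result(
    ids = criteria$ids,
    beta = stats::setNames(rep(NA_real_, n), criteria$ids),
    frontier_ids = criteria$ids[!dominated],
    threshold = NA_real_, W = NA_real_, C = C, layer = 0L,
    duplicate_groups = dup$groups
  )
}

#' Frontier by tournament partitioning
#'
#' Memory-bounded variant for large tables: the alternatives are split into
#' consecutive blocks of at most `partition_size`, the local frontier of
#' each block is found with [pareto_frontier()], the local winners are
#' pooled and the frontier is recomputed on the pool. Because dominance is
#' transitive and any globally nondominated alternative is nondominated in
#' its own block, the result is identical to the direct computation on the
#' full table, for any partition size and any input order.
#'
#' @inheritParams pareto_frontier
#' @param partition_size maximal block size, at least 2
#' @return a `frontier_result`. `beta` values are reported for the
#'   alternatives that reached the final pooled stage and are `NA` for
#'   those eliminated inside a block; frontier members always carry their
#'   full-table value `(C/2)*W`.
#' @export
tournament_frontier <- function(criteria, partition_size = 5000, W = 1000,
                                strict_duplicates = FALSE, tie_tol = 0) {
  stopifnot(inherits(criteria, "criteria_table"))
  if (partition_size < 2) stop("partition_size must be at least 2")
  C <- ncol(criteria$values)
  check_penalty(W, C)
  n <- nrow(criteria$values)

  blocks <- split(seq_len(n), ceiling(seq_len(n) / partition_size))
  pool <- unlist(lapply(blocks, function(idx) {
    local <- criteria_table(criteria$values[idx, , drop = FALSE],
                            ids = criteria$ids[idx],
                            criterion_names = criteria$criterion_names)
    pareto_frontier(local, W = W, strict_duplicates = strict_duplicates,
                    tie_tol = tie_tol, max_direct = Inf)$frontier_ids
  }), use.names = FALSE)

  pooled <- subset_criteria(criteria, pool)
  final <- pareto_frontier(pooled, W = W, strict_duplicates = strict_duplicates,
                           tie_tol = tie_tol, max_direct = Inf)

  beta <- stats::setNames(rep(NA_real_, n), criteria$ids)
  beta[names(final$beta)] <- final$beta
  dup <- duplicate_groups(criteria)
  new_frontier_result(
    ids = criteria$ids, beta = beta, frontier_ids = final$frontier_ids,
    threshold = C * W, W = W, C = C, layer = 0L,
    duplicate_groups = dup$groups
  )
}

#' Successive frontier peeling
#'
#' Computes consecutive nondominated layers: layer 0 is the frontier of the
#' full table; layer l is the frontier of the table with all alternatives
#' of layers < l removed. Peeling recovers strong candidates that
#' experimental error pushed just behind the first frontier. Stops early
#' once no alternatives remain.
#'
#' @inheritParams pareto_frontier
#' @param layers maximal number of layers to peel, at least 1
#' @return list of `frontier_result`, one per nonempty layer, each with its
#'   `layer` index set (0-based); the layers are disjoint
#' @examples
#' lapply(peel_frontiers(worked_example(), layers = 2), `[[`, "frontier_ids")
#' @export
peel_frontiers <- function(criteria, layers, W = 1000,
                           strict_duplicates = FALSE, tie_tol = 0) {
  stopifnot(inherits(criteria, "criteria_table"))
  if (length(layers) != 1L || is.na(layers) || layers < 1) {
    stop("layers must be a positive integer")
  }
  out <- list()
  remaining <- criteria
  for (l in seq_len(layers)) {
    res <- pareto_frontier(remaining, W = W,
                           strict_duplicates = strict_duplicates,
                           tie_tol = tie_tol)
    res$layer <- l - 1L
    out[[l]] <- res
    rest <- setdiff(remaining$ids, res$frontier_ids)
    if (!length(rest)) break
    remaining <- subset_criteria(remaining, rest)
  }
  out
}

new_frontier_result <- function(ids, beta, frontier_ids, threshold, W, C,
                                layer, duplicate_groups) {
  structure(
    list(ids = ids, beta = beta, frontier_ids = frontier_ids,
         threshold = threshold, W = W, C = C, layer = layer,
         duplicate_groups = duplicate_groups),
    class = "frontier_result"
  )
}

#' @export
print.frontier_result <- function(x, ...) {
  cat(sprintf(
    "frontier_result (layer %d): %d of %d alternatives on the frontier\n",
    x$layer, length(x$frontier_ids), length(x$ids)
  ))
  if (!is.na(x$threshold)) {
    cat(sprintf("  C = %d, W = %g, threshold C*W = %g\n", x$C, x$W,
                x$threshold))
  }
  cat("  frontier:", paste(utils::head(x$frontier_ids, 10), collapse = ", "),
      if (length(x$frontier_ids) > 10) "..." else "", "\n")
  if (length(x$duplicate_groups)) {
    cat(sprintf("  %d duplicate group(s) of identical criteria vectors\n",
                length(x$duplicate_groups)))
  }
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

check_penalty <- function(W, C) {
  if (length(W) != 1L || is.na(W) || W <= C || W != round(W)) {
    stop(sprintf(
      "penalty W must be a positive integer greater than C = %d (got %s)",
      C, format(W)
    ))
  }
  invisible(W)
}

# every alpha entry must be expressible as p*W - q with p, q >= 0, p + q <= C
check_alpha_values <- function(alpha, C, W) {
  a <- unique(as.vector(alpha))
  r <- a %% W
  q <- ifelse(r == 0, 0, W - r)
  p <- (a + q) / W
  bad <- q > C | p < 0 | p != round(p) | (p + q) > C
  if (any(bad)) {
    stop(sprintf(
      "alpha contains value(s) not producible from delta entries (e.g. %g); upstream corruption",
      a[bad][1]
    ))
  }
  invisible(alpha)
}

# identify groups of alternatives with exactly identical criteria vectors
duplicate_groups <- function(criteria) {
  keys <- apply(criteria$values, 1L, paste, collapse = "\r")
  first <- !duplicated(keys)
  rep_id <- stats::setNames(criteria$ids[first], keys[first])
  key_of <- stats::setNames(rep_id[keys], criteria$ids)
  groups <- split(criteria$ids, keys)
  groups <- unname(groups[lengths(groups) > 1L])
  list(groups = groups, representative = which(first), key_of = key_of)
}
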