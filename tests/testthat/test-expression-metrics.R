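make_two_group <- function(a_vals, b_vals) {
  na <- length(a_vals)
  m <- matrix(c(a_vals, b_vals), nrow = 1,
              dimnames = list("gene1",
                              c(paste0("A", seq_len(na)),
                                paste0("B", seq_along(b_vals)))))
  list(ds = tiny_dataset(m),
       ctr = group_contrast("c", colnames(m)[seq_len(na)],
                            colnames(m)[-seq_len(na)]))
}

test_that("group statistic differences follow mean and median arithmetic", {
  x <- make_two_group(c(2, 4), c(7, 9))
  expect_equal(unname(group_stat_difference(x$ds, x$ctr, "mean")), 5)

  y <- make_two_group(c(1, 3, 100), c(10, 11, 12, 13))
  expect_equal(unname(group_stat_difference(y$ds, y$ctr, "median")), 8.5)

  z <- make_two_group(c(5, 6, 7), c(5, 6, 7))
  expect_equal(unname(group_stat_difference(z$ds, z$ctr, "mean")), 0)
  expect_equal(unname(group_stat_difference(z$ds, z$ctr, "median")), 0)
})

test_that("probes without two usable values per group are flagged", {
  m <- rbind(ok = c(1, 2, 5, 6), thin = c(1, NA, 5, 6))
  colnames(m) <- c("A1", "A2", "B1", "B2")
  ds <- tiny_dataset(m)
  ctr <- group_contrast("c", c("A1", "A2"), c("B1", "B2"))
  d <- group_stat_difference(ds, ctr, "mean")
  expect_equal(unname(d["ok"]), 4)
  expect_true(is.na(d["thin"]))
  ct <- build_criteria(ds, ctr)
  expect_equal(attr(ct, "excluded"), "thin")
  expect_equal(ct$ids, "ok")
})

test_that("contrast definitions are validated", {
  expect_error(group_contrast("c", character(), "B1"), "nonempty")
  expect_error(group_contrast("c", c("A1", "B1"), c("B1", "B2")), "overlap")
  m <- matrix(1:4, 1, 4, dimnames = list("g", paste0("S", 1:4)))
  ds <- tiny_dataset(m)
  expect_error(
    group_stat_difference(ds, group_contrast("c", c("S1", "S9"), c("S3", "S4"))),
    "unknown sample")
})

test_that("the minimization transform negates and rejects signed input", {
  expect_equal(to_minimization(c(5, 0, 8.5)), c(-5, 0, -8.5))
  expect_error(to_minimization(c(1, -2)), "absolute value")
})

test_that("maximizing differences equals minimizing their negation", {
  set.seed(21)
  d <- matrix(stats::runif(200), 100, 2)   # nonnegative differences
  ct <- criteria_table(to_minimization(d))
  res <- pareto_frontier(ct)
  # direct maximization dominance: j beats i if >= everywhere, > somewhere
  dominated <- vapply(1:100, function(i) {
    ge <- d[, 1] >= d[i, 1] & d[, 2] >= d[i, 2]
    gt <- d[, 1] > d[i, 1] | d[, 2] > d[i, 2]
    any(ge & gt & seq_len(100) != i)
  }, logical(1))
  expect_setequal(res$frontier_ids, ct$ids[!dominated])
})

test_that("criteria assembly covers single-study and meta layouts", {
  out <- generate_dataset(synthetic_spec(n_genes = 60, seed = 31))
  ds <- out$dataset
  ctl <- select_samples(ds, c(disease.state = "control"))
  cnc <- select_samples(ds, c(disease.state = "lung cancer"))

  ct2 <- build_criteria(ds, group_contrast("cvn", ctl, cnc))
  expect_equal(ncol(ct2$values), 2L)
  expect_equal(ct2$criterion_names, c("cvn.mean", "cvn.median"))
  expect_true(all(ct2$values <= 0))

  quarters <- split(ds$sample_ids, rep_len(1:4, length(ds$sample_ids)))
  four <- lapply(1:4, function(i) {
    others <- setdiff(ds$sample_ids, quarters[[i]])[1:8]
    group_contrast(paste0("m", i), quarters[[i]], others,
                   statistics = "median")
  })
  ct4 <- build_criteria(ds, four)
  expect_equal(ncol(ct4$values), 4L)

  six <- c(four, list(group_contrast("m5", quarters[[1]], quarters[[2]],
                                     statistics = c("mean", "median"))))
  expect_error(build_criteria(ds, six), "more than 5")
  expect_error(build_criteria(ds, c(four, four[1])), "duplicated contrast")
})

test_that("a planted large-effect gene lands on the first frontier", {
  out <- generate_dataset(synthetic_spec(n_genes = 200, n_planted = 1,
                                         effect_size = 10, seed = 8))
  ds <- out$dataset
  ctr <- group_contrast("cvn",
                        select_samples(ds, c(disease.state = "control")),
                        select_samples(ds, c(disease.state = "lung cancer")))
  res <- pareto_frontier(build_criteria(ds, ctr))
  expect_true(out$planted %in% res$frontier_ids)

  # scaling one group by a positive constant cannot un-plant the gene
  scaled <- ds$values
  cancer <- select_samples(ds, c(disease.state = "lung cancer"))
  scaled[, cancer] <- scaled[, cancer] * 3
  ds2 <- expression_dataset(scaled, sample_annotations = ds$sample_annotations)
  res2 <- pareto_frontier(build_criteria(ds2, ctr))
  expect_true(out$planted %in% res2$frontier_ids)
})
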