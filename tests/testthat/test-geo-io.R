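test_that("the miniature SOFT fixture parses into a full dataset", {
  path <- withr::local_tempfile(fileext = ".soft")
  write_mini_soft(path)
  ds <- read_gds_soft(path, quiet = TRUE)
  expect_equal(dim(ds), c(6L, 8L))
  expect_setequal(colnames(ds$sample_annotations),
                  c("disease state", "stress"))
  expect_equal(ds$gene_symbols[1], "SYM_A1")
  # the fixture's "null" cell becomes a missing value
  expect_true(is.na(ds$values["A5", "GSM003"]))
  expect_equal(sum(is.na(ds$values)), 1L)
})

test_that("parsing is independent of line endings", {
  lf <- withr::local_tempfile(fileext = ".soft")
  crlf <- withr::local_tempfile(fileext = ".soft")
  write_mini_soft(lf, eol = "\n")
  write_mini_soft(crlf, eol = "\r\n")
  a <- read_gds_soft(lf, quiet = TRUE)
  b <- read_gds_soft(crlf, quiet = TRUE)
  expect_equal(a$values, b$values)
  expect_equal(a$sample_annotations, b$sample_annotations)
})

test_that("annotation filters select the declared subsets", {
  path <- withr::local_tempfile(fileext = ".soft")
  write_mini_soft(path)
  ds <- read_gds_soft(path, quiet = TRUE)
  expect_length(select_samples(ds, c("disease state" = "normal")), 4L)
  # conjunction of filters, with case-insensitive matching
  both <- select_samples(ds, c("disease state" = "Lung Cancer",
                               "stress" = "never smoked"))
  expect_equal(both, c("GSM005", "GSM006"))
  expect_equal(select_samples(ds), ds$sample_ids)
  expect_error(select_samples(ds, c(tissue = "lung")), "unknown annotation")
  expect_warning(out <- select_samples(ds, c(stress = "former smoker")),
                 "no samples")
  expect_length(out, 0L)
})

test_that("malformed SOFT files fail with pointed errors", {
  path <- withr::local_tempfile(fileext = ".soft")
  write_mini_soft(path)
  lines <- readLines(path)

  broken <- sub("^A3\t[^\t]*\t", "A3\t", lines)  # drop one field from row A3
  f1 <- withr::local_tempfile(); writeLines(broken, f1)
  expect_error(read_gds_soft(f1, quiet = TRUE), "unparseable data row")

  dup <- sub("^A2\t", "A1\t", lines)             # duplicate probe id
  f2 <- withr::local_tempfile(); writeLines(dup, f2)
  expect_error(read_gds_soft(f2, quiet = TRUE), "duplicated probe")

  f3 <- withr::local_tempfile()
  writeLines(grep("dataset_table", lines, invert = TRUE, value = TRUE), f3)
  expect_error(read_gds_soft(f3, quiet = TRUE), "no data table")

  ghost <- sub("GSM005,GSM006,GSM007,GSM008", "GSM005,GSM999", lines)
  f4 <- withr::local_tempfile(); writeLines(ghost, f4)
  expect_error(read_gds_soft(f4, quiet = TRUE), "unknown sample id")
})

test_that("TSV expression input with a group sidecar matches the SOFT path", {
  soft <- withr::local_tempfile(fileext = ".soft")
  write_mini_soft(soft)
  ds <- read_gds_soft(soft, quiet = TRUE)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  sidecar <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(ID_REF = ds$probe_ids, IDENTIFIER = ds$gene_symbols,
                    ds$values, check.names = FALSE)
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample = ds$sample_ids, ds$sample_annotations,
                    check.names = FALSE)
  utils::write.table(ann, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  back <- read_expression_tsv(tsv, sidecar)
  expect_equal(back$values, ds$values)
  expect_equal(back$gene_symbols, ds$gene_symbols)
  expect_equal(select_samples(back, c("disease state" = "normal")),
               select_samples(ds, c("disease state" = "normal")))
})

test_that("frontier reports round-trip with membership intact", {
  ct <- worked_example()
  res <- pareto_frontier(ct)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frontier_report(res, ct, path, contrasts = "demo", seed = 7L)
  rep <- read_frontier_report(path)
  expect_equal(nrow(rep), 6L)
  expect_setequal(rep$id[rep$on_frontier == 1], res$frontier_ids)
  expect_equal(sort(rep$beta[rep$on_frontier == 1]), rep(1000, 3))
  meta <- attr(rep, "metadata")
  expect_true(any(grepl("threshold = 2000", meta)))
  expect_true(any(grepl("seed = 7", meta)))

  # peeled layers serialize with their layer index
  layers <- peel_frontiers(ct, layers = 2)
  write_frontier_report(layers, ct, path)
  rep2 <- read_frontier_report(path)
  expect_equal(rep2$layer[rep2$id == "g2"], 1L)
  expect_equal(rep2$on_frontier[rep2$id == "g2"], 1L)
})
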