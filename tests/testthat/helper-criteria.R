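# random minimization table with (almost surely) pairwise-distinct values
random_criteria <- function(n, C, seed) {
  set.seed(seed)
  criteria_table(matrix(stats::runif(n * C), n, C),
                 ids = sprintf("a%04d", seq_len(n)))
}

expect_same_frontier <- function(a, b) {
  expect_setequal(a$frontier_ids, b$frontier_ids)
}

# tiny two-group dataset builder for metric tests
tiny_dataset <- function(values, ann = NULL) {
  expression_dataset(values,
                     probe_ids = rownames(values),
                     sample_ids = colnames(values),
                     sample_annotations = ann)
}
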