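# experiment-level wrappers: statistics tables, census, checkpoints

test_that("structure_stats_experiment reproduces oracle rows in miniature", {
  r <- structure_stats_experiment(folding_oracle(), model = NULL, lengths = 70L,
                         per_length = 60L, seed = 11L)
  st <- r$oracle[["70"]]
  expect_s3_class(st, "structure_stats")
  # paired fraction in a plausible band around the reference 0.508
  expect_gt(unname(st$context_freq[["P"]]), 0.4)
  expect_lt(unname(st$context_freq[["P"]]), 0.62)
  expect_equal(sum(st$context_freq), 1, tolerance = 1e-9)
  expect_null(r$model[["70"]])
})

test_that("raw network output contains pseudoknots the ground truth lacks", {
  tr <- cached_bundle(60L, 30L, seed = 14L)
  va <- cached_bundle(20L, 30L, seed = 15L, split = "validation")
  fit <- train_matrix_model(matrix_model_spec(0L, channels = 8L), tr, va,
                            training_protocol(2L, lr = 3e-3, batch_size = 15L,
                                              seed = 16L))
  cen <- pseudoknot_census_experiment(fit, folding_oracle(), length = 30L,
                                      count = 30L, seed = 17L)
  # ground truth census is all zero (tested elsewhere); an undertrained
  # network binarized without postprocessing emits conflicting pairs
  expect_gt(cen$structures_crossing + cen$structures_multipair, 0L)
  # census totals >= structure counts when nonzero
  if (cen$structures_crossing > 0L)
    expect_gte(cen$crossing_pairs, cen$structures_crossing)
  if (cen$structures_multipair > 0L)
    expect_gte(cen$multi_pairings, cen$structures_multipair)
})

test_that("checkpoints round-trip parameters and spec", {
  m <- build_matrix_model(matrix_model_spec(0L, channels = 6L), seed = 18L)
  s <- sample_sequences(1L, length_distribution("fixed", 20L), seed = 19L)
  p1 <- predict_matrix(m, s)
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_equal(predict_matrix(m2, s), p1, tolerance = 1e-15)
  unlink(ck)
})
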