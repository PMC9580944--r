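# paired/unpaired predictors: encodings, model contracts, training loop

test_that("window encoding pads symmetrically with the padding channel", {
  w <- encode_windows("ACGU", 3L)
  expect_equal(dim(w), c(4L, 3L, 5L))
  # window at position 1 = [pad, A, C]
  expect_equal(w[1L, 1L, ], c(0, 0, 0, 0, 1))
  expect_equal(w[1L, 2L, ], c(1, 0, 0, 0, 0))
  expect_equal(w[1L, 3L, ], c(0, 1, 0, 0, 0))
  expect_true(all(apply(w, 1:2, sum) == 1)) # exactly one hot channel

  w1 <- encode_windows("ACGU", 1L)
  expect_equal(dim(w1), c(4L, 1L, 5L))
  expect_equal(w1[2L, 1L, ], c(0, 1, 0, 0, 0))

  # window larger than the sequence: every window contains padding
  w71 <- encode_windows(strrep("A", 70L), 71L)
  expect_true(all(apply(w71[, , 5L], 1L, sum) > 0))
  expect_error(encode_windows("ACGU", 4L), "odd")
})

test_that("model construction follows the documented model grid", {
  b40 <- build_pairedness_model(pairedness_model_spec("BLSTM", hidden = 40L))
  b80 <- build_pairedness_model(pairedness_model_spec("BLSTM", hidden = 80L))
  expect_gt(n_parameters(b80), n_parameters(b40))
  b3 <- build_pairedness_model(pairedness_model_spec("BLSTM", layers = 3L,
                                                     hidden = 40L))
  expect_gt(n_parameters(b3), n_parameters(b40))

  # untrained forward passes are finite probabilities
  for (fam in c("FFN", "CNN", "BLSTM")) {
    m <- build_pairedness_model(pairedness_model_spec(fam, window = 15L))
    p <- predict_pairedness(m, c("ACGUACGUACGUACGU", "GGGGAAAACCCCAAAA"))
    expect_true(all(vapply(p, function(v)
      all(is.finite(v) & v >= 0 & v <= 1), TRUE)))
    expect_equal(lengths(p), c(16L, 16L))
  }
  expect_error(pairedness_model_spec("FFN", window = 16L), "odd")
})

test_that("training returns a full trace and selects by validation MCC", {
  tr <- cached_bundle(120L, 30L, seed = 1L)
  va <- cached_bundle(40L, 30L, seed = 2L, split = "validation")
  fit <- train_pairedness(pairedness_model_spec("FFN", window = 15L), tr, va,
                          training_protocol(2L, batch_size = 32L, seed = 3L))
  expect_equal(nrow(fit$trace), 2L)
  expect_true(all(c("accuracy", "f1", "loss", "mcc") %in% names(fit$trace)))
  expect_lte(fit$selected_epoch, 2L)
  expect_equal(max(fit$trace$mcc), fit$trace$mcc[fit$selected_epoch])
  expect_error(train_pairedness(pairedness_model_spec("FFN"), tr,
                                dataset_bundle(character(0L), list(),
                                               split = "validation")),
               "empty")
})

test_that("degenerate all-unpaired data converges to unpaired, MCC 0", {
  seqs <- sample_sequences(60L, length_distribution("fixed", 12L),
                           composition = c(1, 0, 0, 0) / 1, seed = 4L) |>
    suppressWarnings() |> unique()
  # all-A sequences fold to all-unpaired; duplicate collapse leaves one, so
  # mix in AC-repeats which also cannot pair
  seqs <- unique(c(seqs, vapply(1:40, function(k)
    paste(rep(c("A", "C"), 6L)[sample(12L)], collapse = ""), "")))
  orc <- folding_oracle()
  b <- fold_dataset(seqs, orc, "train")
  expect_true(all(vapply(b$structures, function(pt) all(is.na(pt$partner)), TRUE)))
  fit <- train_pairedness(pairedness_model_spec("FFN", window = 7L), b, b,
                          training_protocol(10L, lr = 5e-3, batch_size = 16L,
                                            seed = 5L))
  last <- fit$trace[nrow(fit$trace), ]
  expect_gt(last$accuracy, 0.99)
  expect_equal(last$mcc, 0)
})

test_that("trivially separable labels reach MCC > 0.95 (training-loop oracle)", {
  # synthetic labels = "residue is A": learnable from the central symbol
  # alone. Pairing up the A positions yields pair tables whose paired-mask
  # is exactly "is A" (sequences with an odd A count are dropped).
  seqs <- sample_sequences(400L, length_distribution("fixed", 20L), seed = 6L)
  tr <- isA_label_bundle(seqs, keep = 150L)
  fit <- train_pairedness(pairedness_model_spec("FFN", window = 7L),
                          tr, tr, training_protocol(8L, lr = 3e-3,
                                                    batch_size = 32L, seed = 7L))
  expect_gt(max(fit$trace$mcc), 0.95)
})

test_that("batch and single-sequence prediction agree elementwise", {
  tr <- cached_bundle(40L, 25L, seed = 8L)
  m <- build_pairedness_model(pairedness_model_spec("BLSTM", hidden = 8L),
                              seed = 9L)
  batch <- predict_pairedness(m, tr$sequences[1:5])
  for (k in 1:5) {
    single <- predict_pairedness(m, tr$sequences[k])[[1L]]
    expect_equal(single, batch[[k]], tolerance = 1e-12)
  }
})
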