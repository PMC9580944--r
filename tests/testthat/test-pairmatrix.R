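# base-pair-matrix models: encoding, size-agnostic forward, training

test_that("pair-input encoding is local and channel-swap symmetric", {
  x <- encode_pair_input("ACGU")
  expect_equal(dim(x), c(4L, 4L, 8L))
  # entry (i, j) = one-hot(i) ++ one-hot(j)
  expect_equal(x[1L, 3L, ], c(1, 0, 0, 0, 0, 0, 1, 0)) # A, G
  # symmetry under (i, j) <-> (j, i) with channel-block swap
  set.seed(3)
  s <- sample_sequences(1L, length_distribution("fixed", 12L), seed = 3L)
  xs <- encode_pair_input(s)
  for (k in 1:10) {
    ij <- sample(12L, 2L)
    expect_equal(xs[ij[1L], ij[2L], ], xs[ij[2L], ij[1L], c(5:8, 1:4)])
  }
  # locality: changing residue k only changes row/column k
  s2 <- s
  substr(s2, 5L, 5L) <- if (substr(s, 5L, 5L) == "A") "C" else "A"
  d <- encode_pair_input(s2) - xs
  changed <- which(apply(d != 0, c(1L, 2L), any), arr.ind = TRUE)
  expect_true(all(changed[, 1L] == 5L | changed[, 2L] == 5L))
})

test_that("matrix models are size-agnostic with bounded outputs", {
  m0 <- build_matrix_model(matrix_model_spec(0L), seed = 1L)
  m1 <- build_matrix_model(matrix_model_spec(1L), seed = 1L)
  m3 <- build_matrix_model(matrix_model_spec(3L), seed = 1L)
  expect_gt(n_parameters(m1), n_parameters(m0))
  expect_gt(n_parameters(m3), n_parameters(m0))
  # only variant 3 contains the recurrent block
  expect_true(any(vapply(m3$layers, function(l) l$type == "bilstm2d", TRUE)))
  expect_false(any(vapply(m0$layers, function(l) l$type == "bilstm2d", TRUE)))
  expect_error(matrix_model_spec(2L), "unknown variant")

  s30 <- sample_sequences(1L, length_distribution("fixed", 30L), seed = 2L)
  s70 <- sample_sequences(1L, length_distribution("fixed", 70L), seed = 2L)
  for (m in list(m0, m3)) {
    p30 <- predict_matrix(m, s30)
    p70 <- predict_matrix(m, s70)
    expect_equal(dim(p30), c(30L, 30L))
    expect_equal(dim(p70), c(70L, 70L))
    expect_true(all(p30 >= 0 & p30 <= 1 & is.finite(p30)))
    # deterministic at inference
    expect_identical(p30, predict_matrix(m, s30))
  }
})

test_that("training reduces loss and postprocessed output is valid", {
  tr <- cached_bundle(60L, 30L, seed = 4L)
  va <- cached_bundle(20L, 30L, seed = 5L, split = "validation")
  fit <- train_matrix_model(matrix_model_spec(0L, channels = 8L), tr, va,
                            training_protocol(2L, lr = 3e-3, batch_size = 15L,
                                              seed = 6L))
  expect_equal(nrow(fit$trace), 2L)
  expect_lt(fit$trace$train_loss[2L], fit$trace$train_loss[1L])

  p <- predict_matrix(fit, va$sequences[1L])
  pt <- matrix_to_structure(p)
  expect_true(is_nested(pt))
  expect_s3_class(pt, "pair_table")
})

test_that("ground-truth matrices count their own pairs", {
  b <- cached_bundle(50L, 40L, seed = 7L)
  for (k in seq_along(b$structures)) {
    m <- structure_matrix(b$structures[[k]])
    np <- nrow(pairs_of(b$structures[[k]]))
    expect_equal(count_predicted_pairs(m), np)
    expect_lte(np, 20L) # <= n/2
  }
})

test_that("a variant-0 model memorizes 50 fixed structures (capacity oracle)", {
  seqs <- sample_sequences(50L, length_distribution("fixed", 20L), seed = 8L)
  tr <- fold_dataset(seqs, folding_oracle(), "train")
  va <- dataset_bundle(tr$sequences, tr$structures, split = "validation")
  model <- build_matrix_model(matrix_model_spec(0L, channels = 16L), seed = 9L)
  fit <- NULL
  mcc_now <- -Inf
  for (chunk in 1:8) { # train to convergence, at most 200 epochs
    fit <- train_matrix_model(if (is.null(fit)) model else fit, tr, va,
                              training_protocol(25L, lr = 4e-3,
                                                batch_size = 10L,
                                                seed = 10L + chunk))
    mcc_now <- max(fit$trace$mcc)
    if (mcc_now > 0.95) break
  }
  expect_gt(mcc_now, 0.95)
})
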