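# synthetic data: samplers, presets, shuffling, inverse folding, bias sets

test_that("sequence sampling is reproducible, unique and composition-aware", {
  d5 <- length_distribution("fixed", 5L)
  s1 <- sample_sequences(3L, d5, seed = 7L)
  s2 <- sample_sequences(3L, d5, seed = 7L)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 3L)
  expect_true(all(nchar(s1) == 5L))

  expect_error(sample_sequences(2L, d5, composition = c(0.5, 0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(sample_sequences(0L, d5), ">= 1")

  # degenerate composition: all-A sequences (uniqueness impossible)
  expect_warning(
    sA <- sample_sequences(5L, length_distribution("fixed", 10L),
                           composition = c(1, 0, 0, 0), seed = 1L),
    "duplicates")
  expect_true(all(sA == strrep("A", 10L)))
})

test_that("preset length distributions have the stated support and skews", {
  for (p in c("D1", "D2", "D3", "D4")) {
    lens <- with_seed_for_test(1L, sample_lengths(preset_length_distribution(p), 1e4L))
    expect_true(all(lens >= 25L & lens <= 100L), info = p)
  }
  l1 <- with_seed_for_test(2L, sample_lengths(preset_length_distribution("D1"), 1e4L))
  l4 <- with_seed_for_test(2L, sample_lengths(preset_length_distribution("D4"), 1e4L))
  expect_lt(stats::median(l4), stats::median(l1)) # D4 mostly very short
})

test_that("preset bundles are deterministic and disjoint", {
  a <- preset_distribution_sets("D4", seed = 3L, n_train = 60L, n_val = 20L)
  b <- preset_distribution_sets("D4", seed = 3L, n_train = 60L, n_val = 20L)
  expect_identical(a$train$sequences, b$train$sequences)
  expect_identical(a$validation$sequences, b$validation$sequences)
  expect_length(intersect(a$train$sequences, a$validation$sequences), 0L)
})

test_that("length series bundles follow the requested grid", {
  series <- length_series_sets(c(30L, 100L, 250L), per_bin = 10L, seed = 4L)
  expect_named(series, c("30", "100", "250"))
  expect_true(all(vapply(series, length, 0L) == 10L))
  expect_true(all(nchar(series[["250"]]$sequences) == 250L))
  expect_error(length_series_sets(c(30L, 40L), per_bin = 0L), "per_bin")
  expect_error(length_series_sets(integer(0L)), "non-empty")
})

test_that("dinucleotide shuffle conserves dinucleotide counts exactly", {
  # closed-case check: ACACAC admits exactly one valid shuffle
  expect_equal(dinucleotide_shuffle("ACACAC", seed = 3L), "ACACAC")
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1L), "AAAA")
  set.seed(11)
  for (k in 1:300) {
    L <- sample(6:80, 1L)
    s <- sample_sequences(1L, length_distribution("fixed", L), seed = 500L + k)
    sh <- dinucleotide_shuffle(s, seed = k)
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
    expect_identical(substr(sh, 1L, 1L), substr(s, 1L, 1L))
    expect_identical(substr(sh, L, L), substr(s, L, L))
  }
})

test_that("folding oracle produces nested canonical ground truth", {
  orc <- folding_oracle()
  db <- fold_sequences(c("GGGGAAAACCCC", "AAAAAAA"), orc)
  pt <- parse_dotbracket(db[1L])
  expect_gte(nrow(pairs_of(pt)), 3L)
  expect_true(is_nested(pt))
  expect_equal(db[2L], ".......") # no canonical pairs possible

  b <- cached_bundle(150L, 60L, seed = 21L)
  cen <- crossing_multipair_census(b$structures)
  expect_equal(unname(unlist(cen)), c(0L, 0L, 0L, 0L))
  st <- aggregate_stats(b$sequences, b$structures)
  expect_equal(unname(st$pairtype_freq["NC"]), 0)
})

test_that("fallback oracle is labeled and available without the engine", {
  orc <- folding_oracle("nussinov")
  expect_match(orc$id, "fallback")
  db <- fold_sequences("GGGGAAAACCCC", orc)
  expect_true(is_nested(parse_dotbracket(db[1L])))
  # maximizes pairs: at least as many as the thermodynamic engine here
  expect_gte(nrow(pairs_of(parse_dotbracket(db[1L]))), 4L)
})

test_that("dataset bundles enforce alignment and uniqueness", {
  expect_error(dataset_bundle(c("ACGU", "ACGU"),
                              list(pair_table(rep(NA_integer_, 4L)),
                                   pair_table(rep(NA_integer_, 4L)))),
               "duplicate")
  expect_error(dataset_bundle("ACGU", list(pair_table(rep(NA_integer_, 5L)))),
               "mismatch")
})

test_that("inverse folding designs small targets exactly", {
  orc <- folding_oracle()
  r <- inverse_fold(parse_dotbracket("((((....))))"), orc, tries = 3L, seed = 5L)
  expect_equal(r$distance, 0L)
  expect_equal(fold_sequences(r$sequence, orc)[1L], "((((....))))")

  r2 <- inverse_fold(parse_dotbracket("........."), orc, tries = 1L, seed = 2L)
  expect_equal(r2$distance, 0L)

  # best-of-k monotonicity on a harder target
  tgt <- random_nested_pt(50L, seed = 33L)
  d1 <- inverse_fold(tgt, orc, tries = 1L, seed = 9L, max_steps = 40L)$distance
  d6 <- inverse_fold(tgt, orc, tries = 6L, seed = 9L, max_steps = 40L)$distance
  expect_lte(d6, d1)
  expect_error(inverse_fold(pairs_to_table_for_test(
    rbind(c(1L, 6L), c(3L, 9L)), 9L)), "nested")
})

test_that("inverse folding solves >= 90% of small oracle-folded targets", {
  b <- cached_bundle(40L, 30L, seed = 77L)
  solved <- vapply(seq_along(b$structures), function(k)
    inverse_fold(b$structures[[k]], tries = 6L, seed = 1000L + k)$distance == 0L,
    logical(1L))
  expect_gte(mean(solved), 0.9)
})

test_that("bias emulator produces nested shapes in the 25-120 nt window", {
  one <- bias_emulator(1L, 100L, seed = 2L)
  expect_length(one, 100L)
  expect_true(all(vapply(one, function(p) attr(p, "shape"), 0L) == 1L))

  four <- bias_emulator(4L, 25L, seed = 3L)
  expect_length(four, 100L)
  expect_equal(sort(unique(vapply(four, function(p) attr(p, "shape"), 0L))), 1:4)
  lens <- vapply(four, function(p) p$n, 0L)
  expect_true(all(lens >= 25L & lens <= 120L))
  expect_true(all(vapply(four, is_nested, TRUE)))
  expect_error(bias_emulator(0L, 5L), "n_shapes")
})

test_that("bias replication filters, designs and splits as specified", {
  shapes <- bias_emulator(2L, 8L, seed = 4L)
  # plant a too-long structure and a heavily pseudoknotted one
  too_long <- pair_table(rep(NA_integer_, 150L))
  pk_pairs <- cbind(seq(1L, 13L, 2L), seq(20L, 32L, 2L))  # 7 mutually crossing
  heavy_pk <- pairs_to_table_for_test(pk_pairs, 40L)
  stopifnot(sum(crossing_flags_for_test(pk_pairs)) == 7L)
  r <- replicate_bias_dataset(c(shapes, list(too_long, heavy_pk)),
                              seed = 5L, tries = 2L)
  expect_equal(r$report$n_length_filtered, 1L)
  expect_equal(r$report$n_pseudoknot_dropped, 1L)
  expect_equal(r$report$n_designed, 16L)
  expect_equal(length(r$train$sequences), 12L) # floor(0.8 * 16)
  expect_equal(length(r$validation$sequences), 4L)
  # ground truth is the refold of the designed sequence
  orc <- folding_oracle()
  k <- 1L
  expect_equal(write_dotbracket(r$train$structures[[k]]),
               fold_sequences(r$train$sequences[k], orc)[1L])
})

test_that("sequence and structure files round-trip", {
  tmp <- tempfile()
  seqs <- stats::setNames(c("ACGUACGU", "GGGAAACCC"), c("a", "b"))
  write_fasta(seqs, tmp)
  expect_identical(read_fasta(tmp), seqs)

  b <- cached_bundle(5L, 30L, seed = 12L)
  write_dbn(b, tmp)
  dbn <- read_dbn(tmp)
  expect_identical(dbn$sequence, b$sequences)
  expect_identical(dbn$structure, vapply(b$structures, write_dotbracket, ""))

  write_bpseq(b$sequences[1L], b$structures[[1L]], tmp)
  bp <- read_bpseq(tmp)
  expect_identical(bp$sequence, b$sequences[1L])
  expect_identical(bp$structure$partner, b$structures[[1L]]$partner)

  write_bundle_manifest(b, tmp)
  b2 <- read_bundle_manifest(tmp)
  expect_identical(b2$sequences, b$sequences)
  expect_identical(vapply(b2$structures, write_dotbracket, ""),
                   vapply(b$structures, write_dotbracket, ""))
  unlink(tmp)
})
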