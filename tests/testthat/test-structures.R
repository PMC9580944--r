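# structure algebra: dot-bracket round trips, pseudoknot removal,
# loop decomposition and aggregate statistics

test_that("dot-bracket parsing matches hand-derived pair sets", {
  pt <- parse_dotbracket("(((...)))")
  expect_equal(unname(pairs_of(pt)), cbind(1:3, c(9L, 8L, 7L)))
  expect_false(attr(pt, "crossing"))

  empty <- parse_dotbracket(".........")
  expect_equal(empty$n, 9L)
  expect_equal(nrow(pairs_of(empty)), 0L)

  # multi-tier input with a crossing pair is parsed and flagged
  pk <- parse_dotbracket("((.[.)).]")
  expect_equal(unname(pairs_of(pk)), cbind(c(1L, 2L, 4L), c(7L, 6L, 9L)))
  expect_true(attr(pk, "crossing"))

  expect_error(parse_dotbracket("(()"), "position 1")
  expect_error(parse_dotbracket("())."), "position 3")
  expect_error(parse_dotbracket("(x)"), "invalid character")
})

test_that("dot-bracket writing round-trips and tiers crossing pairs", {
  expect_equal(write_dotbracket(parse_dotbracket("(((...)))")), "(((...)))")
  expect_equal(write_dotbracket(pair_table(rep(NA_integer_, 4L))), "....")
  # crossing pair goes to the second bracket tier
  raw <- pairs_to_table_for_test(cbind(c(1L, 2L, 4L), c(7L, 6L, 9L)), 9L)
  expect_equal(write_dotbracket(raw), "((.[.)).]")
  # round trip on oracle structures of assorted lengths
  for (k in 1:20) {
    pt <- random_nested_pt(20L + 3L * k, seed = 100L + k)
    expect_equal(pairs_of(parse_dotbracket(write_dotbracket(pt))),
                 pairs_of(pt))
  }
})

test_that("pair_table enforces its invariants", {
  expect_error(pair_table(c(2L, 1L, 3L)), "self-pairing")
  expect_error(pair_table(c(2L, NA, NA)), "not symmetric")
  expect_error(pair_table(c(5L, NA, NA), 3L), "out of range")
  expect_error(rna_sequence("ACGX"), "outside")
  expect_silent(rna_sequence("ACGN", allow_n = TRUE))
})

test_that("remove_pseudoknots matches its documented examples and is deterministic", {
  nested <- random_nested_pt(40L, seed = 5L)
  expect_equal(pairs_of(remove_pseudoknots(nested)), pairs_of(nested))

  r <- raw_pair_assignment(rbind(c(1L, 6L), c(3L, 9L)), 9L)
  expect_equal(unname(pairs_of(remove_pseudoknots(r))), cbind(1L, 6L))

  r2 <- raw_pair_assignment(
    rbind(c(1L, 10L), c(2L, 9L), c(5L, 13L), c(6L, 12L), c(7L, 11L)), 13L)
  expect_equal(unname(pairs_of(remove_pseudoknots(r2))),
               cbind(c(5L, 6L, 7L), c(13L, 12L, 11L)))
})

test_that("remove_pseudoknots equals exhaustive enumeration (<= 12 pairs)", {
  set.seed(42)
  for (rep in 1:500) {
    n <- sample(8:24, 1L)
    m <- sample(1:min(12L, n %/% 2L), 1L)
    pairs <- t(vapply(seq_len(m), function(i) sort(sample(n, 2L)), c(0L, 0L)))
    pairs <- unique(pairs)
    raw <- raw_pair_assignment(pairs, n)
    w <- if (rep %% 2L) rep(1, nrow(raw$pairs))
         else stats::runif(nrow(raw$pairs), 0.1, 1)
    got <- remove_pseudoknots(raw, weights = w)
    kept <- pairs_of(got)
    expect_true(is_nested(got))
    expect_false(anyDuplicated(c(kept)) > 0L)
    kept_w <- w[match(paste(kept[, 1L], kept[, 2L]),
                      paste(raw$pairs[, 1L], raw$pairs[, 2L]))]
    expect_equal(sum(kept_w), brute_force_pk(raw$pairs, w), tolerance = 1e-9)
  }
})

test_that("crossing and multi-pair census follows the counting rules", {
  nested <- lapply(1:5, function(k) random_nested_pt(30L, seed = k))
  cen <- crossing_multipair_census(nested)
  expect_equal(unlist(cen), c(structures_crossing = 0L, crossing_pairs = 0L,
                              structures_multipair = 0L, multi_pairings = 0L))

  one_cross <- raw_pair_assignment(rbind(c(1L, 6L), c(3L, 9L)), 9L)
  expect_equal(unlist(crossing_multipair_census(list(one_cross))),
               c(structures_crossing = 1L, crossing_pairs = 2L,
                 structures_multipair = 0L, multi_pairings = 0L))

  multi <- raw_pair_assignment(rbind(c(1L, 6L), c(1L, 8L)), 9L)
  expect_equal(unlist(crossing_multipair_census(list(multi))),
               c(structures_crossing = 0L, crossing_pairs = 0L,
                 structures_multipair = 1L, multi_pairings = 2L))
  # alternative counting rule: each distinct incident pair once
  expect_equal(crossing_multipair_census(list(multi), "pairs")$multi_pairings, 2L)
})

test_that("loop decomposition labels match hand decompositions", {
  expect_equal(as.character(loop_decomposition(parse_dotbracket("(((...)))"))),
               c("P", "P", "P", "HL", "HL", "HL", "P", "P", "P"))

  lab <- loop_decomposition(parse_dotbracket(".((..((...))))"))
  expect_equal(as.character(lab)[1L], "EL")
  expect_equal(as.character(lab)[4:5], c("BL", "BL"))

  lab2 <- loop_decomposition(parse_dotbracket("((.((...)).((...)).))"))
  expect_equal(as.character(lab2)[c(3L, 11L, 19L)], c("ML", "ML", "ML"))

  expect_error(
    loop_decomposition(pairs_to_table_for_test(rbind(c(1L, 6L), c(3L, 9L)), 9L)),
    "remove_pseudoknots")
})

test_that("loop decomposition partitions positions on oracle structures", {
  b <- cached_bundle(200L, 60L, seed = 9L)
  for (k in seq_along(b$structures)) {
    pt <- b$structures[[k]]
    lab <- loop_decomposition(pt)
    expect_equal(length(lab), pt$n)
    expect_equal(sum(lab == "P"), 2L * nrow(pairs_of(pt)))
    expect_false(anyNA(lab))
  }
})

test_that("element counts match hand decompositions", {
  expect_equal(count_elements(parse_dotbracket("(((...)))")),
               c(helix = 1, EL = 0, BL = 0, HL = 1, IL = 0, ML = 0))
  expect_equal(count_elements(parse_dotbracket("((...))((...))")),
               c(helix = 2, EL = 1, BL = 0, HL = 2, IL = 0, ML = 0))
  expect_equal(count_elements(parse_dotbracket("((.((...)).((...)).))")),
               c(helix = 3, EL = 0, BL = 0, HL = 2, IL = 0, ML = 1))
  # empty structure still has an exterior loop
  expect_equal(unname(count_elements(parse_dotbracket("...."))["EL"]), 1)
})

test_that("pair types classify by ordered residues", {
  pt <- pairs_to_table_for_test(cbind(1L, 5L), 5L)
  expect_equal(unname(pairtype_frequencies("GAAAC", pt)["GC"]), 1L)
  expect_equal(unname(pairtype_frequencies("CAAAG", pt)["CG"]), 1L)
  expect_equal(unname(pairtype_frequencies("AAAAA", pt)["NC"]), 1L)
  expect_error(pairtype_frequencies("AAAA", pt), "lengths differ")
})

test_that("multiloop lengths count unpaired nucleotides per multiloop", {
  expect_equal(multiloop_lengths(parse_dotbracket("(((...)))")), integer(0L))
  expect_equal(multiloop_lengths(parse_dotbracket("((.((...)).((...)).))")), 3L)
  expect_equal(multiloop_lengths(parse_dotbracket("(((...))((...))((...)))")), 0L)
})

test_that("aggregate statistics pool correctly and sum to one", {
  st <- aggregate_stats("GGGAAACCC", list(parse_dotbracket("(((...)))")))
  expect_equal(unname(st$context_freq["P"]), 6 / 9)
  expect_equal(unname(st$context_freq["HL"]), 3 / 9)
  expect_equal(unname(st$pairtype_freq["GC"]), 1)

  b <- cached_bundle(100L, 50L, seed = 3L)
  st2 <- aggregate_stats(b$sequences, b$structures)
  expect_equal(sum(st2$context_freq), 1, tolerance = 1e-9)
  expect_equal(sum(st2$pairtype_freq), 1, tolerance = 1e-9)
  expect_equal(unname(st2$pairtype_freq["NC"]), 0)
  expect_error(aggregate_stats(character(0L), list()), "empty")
})

test_that("matrix_to_structure implements the postprocessing rule", {
  pt <- parse_dotbracket("(((...)))")
  m <- structure_matrix(pt)
  expect_equal(pairs_of(matrix_to_structure(m)), pairs_of(pt)) # idempotence
  expect_equal(nrow(pairs_of(matrix_to_structure(matrix(0.2, 6L, 6L)))), 0L)

  # crossing candidates resolved by weight
  m2 <- matrix(0, 4L, 4L)
  m2[1L, 3L] <- m2[3L, 1L] <- 0.9
  m2[2L, 4L] <- m2[4L, 2L] <- 0.8
  expect_equal(unname(pairs_of(matrix_to_structure(m2))), cbind(1L, 3L))
  expect_error(matrix_to_structure(matrix(0, 2L, 3L)), "square")

  # output is always a valid nested pair table, even from noisy input
  set.seed(7)
  for (k in 1:25) {
    n <- sample(10:40, 1L)
    noisy <- matrix(stats::runif(n * n), n, n)
    out <- matrix_to_structure(noisy)
    expect_true(is_nested(out))
    expect_s3_class(out, "pair_table") # constructor enforces single partners
  }
})

test_that("count_predicted_pairs uses the upper triangle by default", {
  m <- structure_matrix(parse_dotbracket("(((...)))"))
  expect_equal(count_predicted_pairs(m), 3L)
  expect_equal(count_predicted_pairs(matrix(0, 5L, 5L)), 0L)
  expect_equal(count_predicted_pairs(matrix(0.6, 10L, 10L)), 45L)
  expect_equal(count_predicted_pairs(matrix(0.6, 10L, 10L), full_matrix = TRUE),
               100L)
})
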