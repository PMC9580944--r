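# Shared fixtures: small oracle-folded bundles, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_bundle <- function(count, L, seed, split = "train") {
  key <- paste("b", count, L, seed, split, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    seqs <- sample_sequences(count, length_distribution("fixed", L), seed = seed)
    .fixture_cache[[key]] <- fold_dataset(seqs, folding_oracle(), split)
  }
  .fixture_cache[[key]]
}

# random nested structure via the oracle (deterministic given seed)
random_nested_pt <- function(L, seed) {
  cached_bundle(1L, L, seed)$structures[[1L]]
}

# brute-force maximum-weight non-crossing, endpoint-disjoint subset
brute_force_pk <- function(pairs, w = rep(1, nrow(pairs))) {
  m <- nrow(pairs)
  if (m == 0L) return(0)
  best <- 0
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    if (!length(sel)) next
    ij <- pairs[sel, , drop = FALSE]
    if (anyDuplicated(c(ij))) next
    ok <- TRUE
    if (length(sel) > 1L) {
      a <- ij[, 1L]; b <- ij[, 2L]
      for (u in seq_along(sel)) {
        if (any(a < a[u] & a[u] < b & b < b[u])) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(w[sel]))
  }
  best
}

dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  table(paste0(ch[-length(ch)], ch[-1L]))
}

# build a pair_table from a possibly-crossing pair list (bypasses dot-bracket)
pairs_to_table_for_test <- function(pairs, n) {
  partner <- rep(NA_integer_, n)
  partner[pairs[, 1L]] <- pairs[, 2L]
  partner[pairs[, 2L]] <- pairs[, 1L]
  pair_table(partner, n)
}

with_seed_for_test <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

crossing_flags_for_test <- function(pairs) {
  a <- pairs[, 1L]; b <- pairs[, 2L]
  vapply(seq_len(nrow(pairs)), function(k)
    any(a < a[k] & a[k] < b & b < b[k]) || any(a[k] < a & a < b[k] & b[k] < b),
    logical(1L))
}

# bundle whose paired/unpaired labels equal "residue is A" exactly
isA_label_bundle <- function(seqs, keep) {
  out_s <- character(0L); out_p <- list()
  for (s in seqs) {
    pos <- which(strsplit(s, "")[[1L]] == "A")
    if (length(pos) %% 2L != 0L || length(pos) < 2L) next
    partner <- rep(NA_integer_, nchar(s))
    odd <- pos[seq(1L, length(pos), 2L)]
    even <- pos[seq(2L, length(pos), 2L)]
    partner[odd] <- even
    partner[even] <- odd
    out_s <- c(out_s, s)
    out_p[[length(out_p) + 1L]] <- pair_table(partner)
    if (length(out_s) == keep) break
  }
  dataset_bundle(out_s, out_p, split = "train")
}
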