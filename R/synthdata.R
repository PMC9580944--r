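# Synthetic dataset generation: random sequence samplers under configurable
# length distributions, oracle-folded ground truth, inverse-folded
# bias-replication sets and dinucleotide-shuffled controls.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sequence length distributions
#'
#' @param kind `"fixed"`, `"uniform"`, `"discretized_beta"` (a Beta law
#'   discretized onto `[lmin, lmax]`) or `"empirical"` (resample given
#'   lengths).
#' @param lmin,lmax support in nucleotides.
#' @param shape1,shape2 Beta shape parameters (discretized_beta only).
#' @param lengths observed lengths (empirical only).
#' @param id optional identifier (e.g. a preset name).
#' @return object of class `length_distribution`.
#' @export
length_distribution <- function(kind = c("fixed", "uniform", "discretized_beta",
                                         "empirical"),
                                lmin, lmax = lmin, shape1 = 1, shape2 = 1,
                                lengths = NULL, id = NULL) {
  kind <- match.arg(kind)
  if (lmin < 1L || lmax < lmin) stop("need 1 <= lmin <= lmax")
  if (kind == "empirical" && is.null(lengths)) stop("empirical kind needs lengths")
  structure(list(kind = kind, lmin = as.integer(lmin), lmax = as.integer(lmax),
                 shape1 = shape1, shape2 = shape2, lengths = lengths,
                 id = if (is.null(id)) kind else id),
            class = "length_distribution")
}

#' The four preset length distributions on 25-100 nt
#'
#' `D1` uniform; `D2` skewed toward long sequences; `D3` symmetric unimodal
#' around ~62 nt; `D4` strongly skewed toward very short sequences. The exact
#' shapes are package choices (the source figure is not numerically
#' specified); cross-distribution conclusions must be robust to them.
#'
#' @param preset `"D1"`, `"D2"`, `"D3"` or `"D4"`.
#' @export
preset_length_distribution <- function(preset = c("D1", "D2", "D3", "D4")) {
  preset <- match.arg(preset)
  switch(preset,
    D1 = length_distribution("uniform", 25, 100, id = "D1"),
    D2 = length_distribution("discretized_beta", 25, 100, 5, 1.5, id = "D2"),
    D3 = length_distribution("discretized_beta", 25, 100, 4, 4, id = "D3"),
    D4 = length_distribution("discretized_beta", 25, 100, 1.2, 6, id = "D4"))
}

#' Draw lengths from a length distribution
#' @param dist a [length_distribution()].
#' @param count number of draws.
#' @export
sample_lengths <- function(dist, count) {
  out <- switch(dist$kind,
    fixed = rep(dist$lmin, count),
    uniform = sample(dist$lmin:dist$lmax, count, replace = TRUE),
    discretized_beta = {
      u <- stats::rbeta(count, dist$shape1, dist$shape2)
      pmin(dist$lmax, dist$lmin + floor(u * (dist$lmax - dist$lmin + 1L)))
    },
    empirical = sample(dist$lengths, count, replace = TRUE))
  as.integer(out)
}

#' Sample i.i.d. random RNA sequences
#'
#' Draws `count` sequences with lengths from `dist` and residues i.i.d. from
#' `composition`. Duplicate sequences are re-drawn so the result is unique.
#' Reproducible given `seed`.
#'
#' @param count number of sequences (>= 1).
#' @param dist a [length_distribution()].
#' @param composition base probability 4-vector (A, C, G, U); must sum to 1.
#' @param seed integer seed.
#' @export
sample_sequences <- function(count, dist, composition = rep(0.25, 4),
                             seed = 1L) {
  if (count < 1L) stop("count must be >= 1")
  if (length(composition) != 4L || abs(sum(composition) - 1) > 1e-8)
    stop("composition must be a 4-vector summing to 1")
  with_seed(seed, {
    draw <- function(k) {
      lens <- sample_lengths(dist, k)
      vapply(lens, function(L)
        paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                     prob = composition), collapse = ""), "")
    }
    seqs <- draw(count)
    last_dups <- Inf
    for (iter in 1:100) {
      dup <- duplicated(seqs)
      if (!any(dup)) break
      if (sum(dup) >= last_dups && iter > 5L) {
        # sequence space exhausted (e.g. degenerate composition): keep
        # duplicates rather than loop forever
        warning("could not draw ", count,
                " unique sequences; returning with duplicates")
        break
      }
      last_dups <- sum(dup)
      seqs[dup] <- draw(sum(dup))
    }
    seqs
  })
}

#' Train/validation bundles for a preset length distribution
#'
#' @param preset `"D1"` to `"D4"`.
#' @param seed integer seed (train and validation use derived seeds).
#' @param oracle a [folding_oracle()].
#' @param n_train,n_val bundle sizes (defaults 30000/5000).
#' @return list with `train` and `validation` [dataset_bundle()]s.
#' @export
preset_distribution_sets <- function(preset, seed = 1L,
                                     oracle = folding_oracle(),
                                     n_train = 30000L, n_val = 5000L) {
  dist <- preset_length_distribution(preset)
  tr_seqs <- sample_sequences(n_train, dist, seed = seed)
  va_seqs <- sample_sequences(n_val, dist, seed = seed + 1000003L)
  # independent draws; enforce disjointness explicitly (collisions are rare)
  clash <- va_seqs %in% tr_seqs
  tries <- 0L
  while (any(clash) && tries < 100L) {
    va_seqs[clash] <- sample_sequences(sum(clash), dist,
                                       seed = seed + 2000003L + tries)
    clash <- va_seqs %in% tr_seqs | duplicated(va_seqs)
    tries <- tries + 1L
  }
  prov <- list(preset = preset, seed = seed)
  list(train = fold_dataset(tr_seqs, oracle, "train", prov),
       validation = fold_dataset(va_seqs, oracle, "validation", prov))
}

#' Evaluation bundles over a series of fixed lengths
#'
#' @param lengths vector of sequence lengths (e.g. `seq(30, 250, by = 20)`).
#' @param per_bin sequences per length bin (reference scale: 2000).
#' @param seed integer seed.
#' @param oracle a [folding_oracle()].
#' @return named list of [dataset_bundle()]s, one per length.
#' @export
length_series_sets <- function(lengths, per_bin = 2000L, seed = 1L,
                               oracle = folding_oracle()) {
  if (!length(lengths)) stop("lengths must be non-empty")
  if (per_bin < 1L) stop("per_bin must be >= 1")
  out <- lapply(seq_along(lengths), function(k) {
    L <- lengths[k]
    seqs <- sample_sequences(per_bin, length_distribution("fixed", L),
                             seed = seed + 17L * k)
    fold_dataset(seqs, oracle, "test", list(length = L, seed = seed))
  })
  names(out) <- as.character(lengths)
  out
}

#' Dinucleotide shuffle (Altschul-Erickson Euler-walk algorithm)
#'
#' Returns a random permutation of `seq` with exactly the same dinucleotide
#' count multiset (hence also the same mononucleotide composition and the
#' same first and last residue), sampled by drawing a random arborescence of
#' last-out edges toward the terminal vertex of the dinucleotide multigraph
#' and randomizing the remaining edge order.
#'
#' @param seq an RNA sequence (length >= 2).
#' @param seed integer seed.
#' @export
dinucleotide_shuffle <- function(seq, seed = 1L) {
  seq <- rna_sequence(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 2L) stop("need a sequence of length >= 2")
  verts <- unique(ch)
  if (length(verts) == 1L) return(seq)
  last <- ch[n]
  # outgoing edge target lists per vertex
  edges <- split(ch[-1L], factor(ch[-n], levels = verts))
  with_seed(seed, {
    repeat {
      # candidate last-out edge per non-terminal vertex
      last_out <- vapply(verts, function(v) {
        if (v == last || !length(edges[[v]])) NA_character_
        else sample(edges[[v]], 1L)
      }, "")
      names(last_out) <- verts
      # check the chosen edges form an arborescence into `last`
      ok <- TRUE
      for (v in verts) {
        if (v == last || !length(edges[[v]])) next
        seen <- character(0L); cur <- v
        while (cur != last) {
          if (cur %in% seen || is.na(last_out[cur])) { ok <- FALSE; break }
          seen <- c(seen, cur); cur <- last_out[cur]
        }
        if (!ok) break
      }
      if (ok) break
    }
    # order edges: random permutation, chosen last-out edge moved to the end
    ordered <- lapply(verts, function(v) {
      e <- edges[[v]]
      if (!length(e)) return(e)
      e <- sample(e)
      if (v != last && !is.na(last_out[v])) {
        k <- match(last_out[v], e)
        e <- c(e[-k], e[k])
      }
      e
    })
    names(ordered) <- verts
    # Euler walk from the first residue
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    out <- character(n)
    out[1L] <- ch[1L]
    cur <- ch[1L]
    for (k in 2:n) {
      nxt <- ordered[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[k] <- nxt
      cur <- nxt
    }
    paste(out, collapse = "")
  })
}

#' Inverse folding: design a sequence for a target structure
#'
#' Runs a structure-seeded stochastic hill climb against the folding oracle
#' up to `tries` times with distinct derived seeds and returns the best
#' candidate, scored by base-pair distance between the oracle MFE structure
#' of the candidate and the target (distance 0 = exact design).
#'
#' @param target a nested `pair_table`.
#' @param oracle a [folding_oracle()]; the `"turner"` engine uses a fast
#'   C++ search, other engines a slower R loop.
#' @param tries number of independent restarts (default 6).
#' @param seed integer seed.
#' @param max_steps mutation budget per restart (default `30 * n`).
#' @return list with `sequence` and `distance`.
#' @export
inverse_fold <- function(target, oracle = folding_oracle(), tries = 6L,
                         seed = 1L, max_steps = 30L * target$n) {
  if (!is_nested(target)) stop("inverse folding target must be nested")
  if (oracle$engine == "turner") {
    partner0 <- ifelse(is.na(target$partner), -1L, target$partner - 1L)
    return(.inverse_fold_cpp(partner0, as.integer(tries),
                             as.integer(max_steps), as.integer(seed)))
  }
  # generic R implementation for non-default engines
  tgt_pairs <- pairs_of(target)
  dist_to <- function(seq) {
    pt <- parse_dotbracket(fold_sequences(seq, oracle)[1L])
    p <- pairs_of(pt)
    key <- function(m) paste(m[, 1L], m[, 2L])
    length(setdiff(key(p), key(tgt_pairs))) +
      length(setdiff(key(tgt_pairs), key(p)))
  }
  best <- NULL
  with_seed(seed, {
    for (t in seq_len(tries)) {
      seq <- random_design_seed(target)
      d <- dist_to(seq)
      for (step in seq_len(max_steps)) {
        if (d == 0L) break
        cand <- mutate_design(seq, target)
        d2 <- dist_to(cand)
        if (d2 <= d) { seq <- cand; d <- d2 }
      }
      if (is.null(best) || d < best$distance)
        best <- list(sequence = seq, distance = d)
      if (best$distance == 0L) break
    }
  })
  best
}

random_design_seed <- function(target) {
  n <- target$n
  ch <- sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = c(.55, .15, .15, .15))
  pr <- pairs_of(target)
  if (nrow(pr)) {
    pick <- sample(1:6, nrow(pr), replace = TRUE, prob = c(3, 3, 1, 1, 1, 1) / 10)
    lut <- matrix(c("G", "C", "C", "G", "A", "U", "U", "A", "G", "U", "U", "G"),
                  ncol = 2L, byrow = TRUE)
    ch[pr[, 1L]] <- lut[pick, 1L]
    ch[pr[, 2L]] <- lut[pick, 2L]
  }
  paste(ch, collapse = "")
}

mutate_design <- function(seq, target) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(target$n, 1L)
  p <- target$partner[pos]
  if (!is.na(p)) {
    lut <- matrix(c("G", "C", "C", "G", "A", "U", "U", "A", "G", "U", "U", "G"),
                  ncol = 2L, byrow = TRUE)
    pick <- sample(6L, 1L)
    ch[min(pos, p)] <- lut[pick, 1L]
    ch[max(pos, p)] <- lut[pick, 2L]
  } else {
    ch[pos] <- sample(c("A", "C", "G", "U"), 1L)
  }
  paste(ch, collapse = "")
}

#' Emulate a structure-biased collection (bpRNA-like)
#'
#' Stands in for a family-dominated structure database: draws `n_shapes`
#' structure "shapes" (templates with frozen base dimensions: single hairpin,
#' bulged hairpin, two-hairpin, cloverleaf) and emits `n_per_shape` variants
#' each with slightly jittered helix/loop sizes. All output structures are
#' nested and 25-120 nt long; the collection is sequence-free.
#'
#' @param n_shapes number of shape families (>= 1).
#' @param n_per_shape variants per shape.
#' @param seed integer seed.
#' @return list of `pair_table`s with attribute `shape` (family index).
#' @export
bias_emulator <- function(n_shapes, n_per_shape, seed = 1L) {
  if (n_shapes < 1L) stop("n_shapes must be >= 1")
  with_seed(seed, {
    templates <- c("hairpin", "bulged", "twohairpin", "cloverleaf")
    shapes <- lapply(seq_len(n_shapes), function(s) {
      list(template = templates[(s - 1L) %% 4L + 1L],
           stem = sample(4:8, 1L), loop = sample(4:7, 1L),
           tail = sample(2:5, 1L), linker = sample(2:4, 1L))
    })
    out <- list()
    for (s in seq_len(n_shapes)) {
      for (v in seq_len(n_per_shape)) {
        sh <- shapes[[s]]
        j <- function(x, lo = 1L) max(lo, x + sample(-1:1, 1L))
        db <- build_shape(sh, j)
        pt <- parse_dotbracket(db)
        attr(pt, "shape") <- s
        out[[length(out) + 1L]] <- pt
      }
    }
    out
  })
}

build_shape <- function(sh, j) {
  hp <- function(stem, loop) paste0(strrep("(", stem), strrep(".", loop),
                                    strrep(")", stem))
  db <- switch(sh$template,
    hairpin = {
      stem <- j(sh$stem, 3L) + 4L
      paste0(strrep(".", j(sh$tail, 0L)), hp(stem, j(sh$loop, 3L)),
             strrep(".", j(sh$tail, 0L)))
    },
    bulged = {
      s1 <- j(sh$stem, 3L); s2 <- j(sh$stem, 3L)
      paste0(strrep(".", j(sh$tail, 0L)),
             strrep("(", s1), strrep(".", j(2L, 1L)),
             hp(s2, j(sh$loop, 3L)),
             strrep(")", s1), strrep(".", j(sh$tail, 0L)))
    },
    twohairpin = {
      paste0(strrep(".", j(sh$tail, 0L)),
             hp(j(sh$stem, 3L), j(sh$loop, 3L)),
             strrep(".", j(sh$linker, 1L)),
             hp(j(sh$stem, 3L), j(sh$loop, 3L)),
             strrep(".", j(sh$tail, 0L)))
    },
    cloverleaf = {
      arm <- function() hp(j(4L, 3L), j(sh$loop, 3L))
      s0 <- j(sh$stem, 3L)
      paste0(strrep(".", j(2L, 0L)),
             strrep("(", s0), ".", arm(), ".", arm(), ".", arm(), ".",
             strrep(")", s0), strrep(".", j(2L, 0L)))
    })
  # keep within the 25-120 nt window by padding/trimming external tails
  n <- nchar(db)
  if (n < 25L) db <- paste0(db, strrep(".", 25L - n))
  if (n > 120L) stop("emulated shape exceeds 120 nt")
  db
}

#' Replicate a structure-biased training set by inverse folding
#'
#' Filters a structure collection to 25-120 nt, removes pseudoknots (dropping
#' structures in which more than `max_pk_pairs` pairs were crossing-involved
#' before removal), designs a sequence for each survivor by inverse folding,
#' refolds the designed sequence with the oracle to obtain the ground truth
#' (the refolded structure, NOT the target), and splits 80/20 into train and
#' validation.
#'
#' @param structures list of `pair_table`s (e.g. from [bias_emulator()],
#'   [read_dbn()] records parsed with [parse_dotbracket()], or bpseq files).
#' @param oracle a [folding_oracle()].
#' @param seed integer seed.
#' @param tries inverse-folding restarts per target.
#' @param max_pk_pairs drop threshold for crossing-involved pairs (default 6).
#' @param len_range length filter (default 25-120 nt).
#' @param split_frac train fraction (default 0.8).
#' @return list with `train`, `validation` bundles and a `report` of counts.
#' @export
replicate_bias_dataset <- function(structures, oracle = folding_oracle(),
                                   seed = 1L, tries = 6L, max_pk_pairs = 6L,
                                   len_range = c(25L, 120L), split_frac = 0.8) {
  n_in <- length(structures)
  lens <- vapply(structures, function(pt) pt$n, 0L)
  keep_len <- lens >= len_range[1L] & lens <= len_range[2L]
  structures <- structures[keep_len]
  n_pk_drop <- 0L
  targets <- list()
  for (pt in structures) {
    ncross <- sum(crossing_flags(pairs_of(pt)))
    if (ncross > max_pk_pairs) { n_pk_drop <- n_pk_drop + 1L; next }
    targets[[length(targets) + 1L]] <- if (ncross > 0L) remove_pseudoknots(pt) else pt
  }
  seqs <- character(0L)
  pts <- list()
  dists <- integer(0L)
  for (k in seq_along(targets)) {
    res <- inverse_fold(targets[[k]], oracle, tries = tries,
                        seed = seed + 31L * k)
    if (res$sequence %in% seqs) next  # bundle uniqueness
    db <- fold_sequences(res$sequence, oracle)[1L]
    seqs <- c(seqs, res$sequence)
    pts[[length(pts) + 1L]] <- parse_dotbracket(db)
    dists <- c(dists, res$distance)
  }
  idx <- with_seed(seed + 999L, sample(length(seqs)))
  n_tr <- floor(split_frac * length(seqs))
  prov <- list(source = "replicate_bias_dataset", seed = seed,
               oracle_id = oracle$id)
  list(
    train = dataset_bundle(seqs[idx[seq_len(n_tr)]], pts[idx[seq_len(n_tr)]],
                           prov, "train"),
    validation = dataset_bundle(seqs[idx[-seq_len(n_tr)]],
                                pts[idx[-seq_len(n_tr)]], prov, "validation"),
    report = list(n_input = n_in, n_length_filtered = sum(!keep_len),
                  n_pseudoknot_dropped = n_pk_drop, n_designed = length(seqs),
                  mean_design_distance = mean(dists))
  )
}
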