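#' Validate RNA sequences
#'
#' Checks that strings are over the RNA alphabet A/C/G/U. `N` may be permitted
#' on read (e.g. from external files) but is always rejected before folding.
#'
#' @param x character vector of sequences.
#' @param allow_n allow the ambiguity code `N`.
#' @return `x`, invisibly upper-cased with `T` mapped to `U`.
#' @export
rna_sequence <- function(x, allow_n = FALSE) {
  x <- toupper(as.character(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  ok <- if (allow_n) grepl("^[ACGUN]+$", x) else grepl("^[ACGU]+$", x)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("sequence ", bad, " contains residues outside {A,C,G,U",
         if (allow_n) ",N", "}: ", substr(x[bad], 1L, 40L))
  }
  if (any(nchar(x) < 1L)) stop("empty sequence")
  x
}

#' Per-nucleotide partner table
#'
#' The canonical lossless representation of a secondary structure: an integer
#' vector `partner` of length `n` where `partner[i]` is the 1-based index of
#' the base paired with `i`, or `NA` if `i` is unpaired. Crossing
#' (pseudoknotted) pairs are representable; positions with multiple partners
#' are not (see [raw_pair_assignment()]).
#'
#' @param partner integer vector, `NA` for unpaired positions.
#' @param n sequence length; defaults to `length(partner)`.
#' @return object of class `pair_table`.
#' @export
pair_table <- function(partner, n = length(partner)) {
  partner <- as.integer(partner)
  if (length(partner) != n || n < 1L) stop("partner must have length n >= 1")
  idx <- which(!is.na(partner))
  if (any(partner[idx] < 1L | partner[idx] > n)) stop("partner index out of range")
  if (any(partner[idx] == idx)) stop("self-pairing is not allowed")
  if (!identical(partner[partner[idx]], idx)) stop("partner table is not symmetric")
  structure(list(n = n, partner = partner), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat("pair_table: n =", x$n, ",", nrow(pairs_of(x)), "pairs",
      if (is_nested(x)) "(nested)" else "(crossing)", "\n")
  cat(write_dotbracket(x), "\n")
  invisible(x)
}

#' Extract the pair list of a structure
#'
#' @param pt a `pair_table` or `raw_pair_assignment`.
#' @return two-column integer matrix of pairs `(i, j)` with `i < j`, 1-based,
#'   ordered lexicographically.
#' @export
pairs_of <- function(pt) {
  if (inherits(pt, "raw_pair_assignment")) return(pt$pairs)
  i <- which(!is.na(pt$partner) & pt$partner > seq_len(pt$n))
  cbind(i = i, j = pt$partner[i], deparse.level = 0L)
}

pairs_to_table <- function(pairs, n) {
  partner <- rep(NA_integer_, n)
  if (nrow(pairs)) {
    if (anyDuplicated(c(pairs[, 1L], pairs[, 2L])))
      stop("pair list has a position with multiple partners")
    partner[pairs[, 1L]] <- pairs[, 2L]
    partner[pairs[, 2L]] <- pairs[, 1L]
  }
  pair_table(partner, n)
}

#' Is a structure free of crossing pairs?
#' @param pt a `pair_table` or `raw_pair_assignment`.
#' @export
is_nested <- function(pt) {
  p <- pairs_of(pt)
  !has_crossing(p)
}

has_crossing <- function(pairs) {
  m <- nrow(pairs)
  if (m < 2L) return(FALSE)
  any(crossing_flags(pairs))
}

# logical vector: does pair k cross any other pair?
crossing_flags <- function(pairs) {
  m <- nrow(pairs)
  if (m == 0L) return(logical(0L))
  a <- pairs[, 1L]; b <- pairs[, 2L]
  out <- logical(m)
  for (k in seq_len(m)) {
    out[k] <- any(a < a[k] & a[k] < b & b < b[k]) ||
      any(a[k] < a & a < b[k] & b[k] < b)
  }
  out
}

#' Raw (possibly inconsistent) pair assignment
#'
#' Holds a pair list that may contain crossing pairs and positions with more
#' than one partner, as produced by thresholding a raw base-pair matrix from a
#' network before any postprocessing.
#'
#' @param pairs two-column matrix of 1-based indices; rows are stored
#'   canonically with `i < j`, sorted lexicographically.
#' @param n sequence length.
#' @export
raw_pair_assignment <- function(pairs, n) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  if (nrow(pairs)) {
    if (any(pairs < 1L | pairs > n)) stop("pair index out of [1, n]")
    if (any(pairs[, 1L] == pairs[, 2L])) stop("self pair")
    flip <- pairs[, 1L] > pairs[, 2L]
    pairs[flip, ] <- pairs[flip, 2:1]
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  colnames(pairs) <- c("i", "j")
  structure(list(n = as.integer(n), pairs = pairs),
            class = "raw_pair_assignment")
}

BRACKET_TIERS <- c("()", "[]", "{}", "<>")

#' Parse dot-bracket notation
#'
#' Bracket tiers beyond `()` (`[]`, `{}`, `<>`) encode pseudoknotted pairs.
#' The result is flagged with attribute `crossing` when crossing pairs are
#' present.
#'
#' @param text a single dot-bracket string over `".()[]{}<>"`.
#' @return a [pair_table()].
#' @export
parse_dotbracket <- function(text) {
  ch <- strsplit(text, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n == 0L) stop("empty dot-bracket string")
  bad <- which(!ch %in% c(".", unlist(strsplit(BRACKET_TIERS, ""))))
  if (length(bad))
    stop("invalid character '", ch[bad[1L]], "' at position ", bad[1L])
  partner <- rep(NA_integer_, n)
  for (tier in BRACKET_TIERS) {
    open <- substr(tier, 1L, 1L); close <- substr(tier, 2L, 2L)
    stack <- integer(0L)
    for (i in seq_len(n)) {
      if (ch[i] == open) stack <- c(stack, i)
      else if (ch[i] == close) {
        if (!length(stack))
          stop("unbalanced '", close, "' at position ", i)
        j <- stack[length(stack)]
        stack <- stack[-length(stack)]
        partner[i] <- j; partner[j] <- i
      }
    }
    if (length(stack))
      stop("unbalanced '", open, "' at position ", stack[length(stack)])
  }
  pt <- pair_table(partner, n)
  attr(pt, "crossing") <- !is_nested(pt)
  pt
}

#' Write dot-bracket notation
#'
#' Nested structures round-trip exactly with [parse_dotbracket()]. Crossing
#' pairs are emitted on additional bracket tiers: the maximum nested subset on
#' tier 1, the remainder assigned greedily to later tiers.
#'
#' @param pt a `pair_table`.
#' @export
write_dotbracket <- function(pt) {
  ch <- rep(".", pt$n)
  remaining <- pairs_of(pt)
  tier <- 1L
  while (nrow(remaining)) {
    if (tier > length(BRACKET_TIERS))
      stop("structure needs more than ", length(BRACKET_TIERS), " bracket tiers")
    keep <- .remove_pk_cpp(remaining - 1L, rep(1, nrow(remaining)), pt$n)
    sel <- remaining[keep, , drop = FALSE]
    ch[sel[, 1L]] <- substr(BRACKET_TIERS[tier], 1L, 1L)
    ch[sel[, 2L]] <- substr(BRACKET_TIERS[tier], 2L, 2L)
    remaining <- remaining[!keep, , drop = FALSE]
    tier <- tier + 1L
  }
  paste(ch, collapse = "")
}

#' Remove pseudoknots (maximum nested subset)
#'
#' Returns the maximum-cardinality (or maximum-weight, when `weights` are
#' given) subset of pairs such that no two pairs cross and no two pairs share
#' an endpoint, via interval dynamic programming. Ties are broken toward the
#' lexicographically smallest pair, so the result is deterministic.
#'
#' @param x a `pair_table` or `raw_pair_assignment`.
#' @param weights optional per-pair score (same order as `pairs_of(x)`).
#' @return a nested `pair_table`.
#' @export
remove_pseudoknots <- function(x, weights = NULL) {
  pairs <- pairs_of(x)
  n <- x$n
  if (is.null(weights)) weights <- rep(1, nrow(pairs))
  if (length(weights) != nrow(pairs)) stop("weights length must match pair count")
  if (nrow(pairs) == 0L) return(pairs_to_table(pairs, n))
  keep <- .remove_pk_cpp(pairs - 1L, as.numeric(weights), n)
  pairs_to_table(pairs[keep, , drop = FALSE], n)
}

#' Census of crossing pairs and multi-partnered positions
#'
#' For a collection of raw pair assignments, counts structures with at least
#' one crossing (non-nested) pair, the total number of crossing-involved
#' pairs, structures with at least one multi-partnered nucleotide, and the
#' total number of multi-pairings. A pair is crossing-involved if it crosses
#' any other pair of the same structure. Under the default counting rule
#' (`multipair_rule = "incidence"`) every pair incident to a position with
#' two or more partners contributes one multi-pairing per (position, pair)
#' incidence.
#'
#' @param raws list of `raw_pair_assignment` (or `pair_table`) objects.
#' @param multipair_rule `"incidence"` (default) or `"pairs"` (count each
#'   distinct pair touching a multi-partnered position once).
#' @return named list with `structures_crossing`, `crossing_pairs`,
#'   `structures_multipair`, `multi_pairings`.
#' @export
crossing_multipair_census <- function(raws, multipair_rule = c("incidence", "pairs")) {
  multipair_rule <- match.arg(multipair_rule)
  sc <- cp <- sm <- mp <- 0L
  for (x in raws) {
    pairs <- pairs_of(x)
    cf <- crossing_flags(pairs)
    if (any(cf)) { sc <- sc + 1L; cp <- cp + sum(cf) }
    deg <- tabulate(c(pairs[, 1L], pairs[, 2L]), nbins = x$n)
    multi <- which(deg >= 2L)
    if (length(multi)) {
      sm <- sm + 1L
      if (multipair_rule == "incidence") {
        mp <- mp + sum(deg[multi])
      } else {
        touch <- pairs[, 1L] %in% multi | pairs[, 2L] %in% multi
        mp <- mp + sum(touch)
      }
    }
  }
  list(structures_crossing = sc, crossing_pairs = cp,
       structures_multipair = sm, multi_pairings = mp)
}

#' Binary base-pair matrix of a structure
#'
#' @param pt a `pair_table`.
#' @return symmetric 0/1 matrix with zero diagonal.
#' @export
structure_matrix <- function(pt) {
  m <- matrix(0, pt$n, pt$n)
  p <- pairs_of(pt)
  m[p] <- 1
  m[p[, 2:1, drop = FALSE]] <- 1
  m
}

#' Derive a single structure from a base-pair matrix
#'
#' Implements the minimal postprocessing rule: keep only the highest entry per
#' row, drop entries below `threshold`, symmetrize, resolve remaining
#' multi-partner conflicts and remove pseudoknots (jointly, by maximum-weight
#' non-crossing selection with the matrix scores as weights).
#'
#' @param m square numeric matrix with entries in `[0, 1]`.
#' @param threshold survival threshold (default 0.5).
#' @param symmetrization `"either"` (default): keep `(i, j)` if it is the row
#'   maximum in row `i` or row `j` and `(m[i,j] + m[j,i]) / 2 >= threshold`;
#'   `"both"`: require the row maximum in both rows.
#' @return a nested `pair_table`.
#' @export
matrix_to_structure <- function(m, threshold = 0.5,
                                symmetrization = c("either", "both")) {
  symmetrization <- match.arg(symmetrization)
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  n <- nrow(m)
  # row maxima (diagonal ignored); ties toward smallest column index
  diag(m) <- -Inf
  rowmax_j <- max.col(m, ties.method = "first")
  survives <- matrix(FALSE, n, n)
  keep <- m[cbind(seq_len(n), rowmax_j)] >= threshold
  survives[cbind(which(keep), rowmax_j[keep])] <- TRUE
  cand <- which(survives | t(survives), arr.ind = TRUE)
  cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
  if (nrow(cand)) {
    sym_score <- (m[cand] + m[cand[, 2:1, drop = FALSE]]) / 2
    ok <- if (symmetrization == "either") {
      (survives[cand] | survives[cand[, 2:1, drop = FALSE]]) & sym_score >= threshold
    } else {
      survives[cand] & survives[cand[, 2:1, drop = FALSE]] & sym_score >= threshold
    }
    cand <- cand[ok, , drop = FALSE]
    sym_score <- sym_score[ok]
  } else sym_score <- numeric(0L)
  if (nrow(cand) == 0L) return(pairs_to_table(cand, n))
  keep <- .remove_pk_cpp(cand - 1L, sym_score, n)
  pairs_to_table(cand[keep, , drop = FALSE], n)
}

#' Count predicted pairs in a base-pair matrix
#'
#' Counts entries strictly greater than `threshold`, by default in the upper
#' triangle only so that a ground-truth binary matrix counts each pair once.
#'
#' @param m square numeric matrix.
#' @param threshold default 0.5.
#' @param full_matrix count over the full matrix instead (replicates the
#'   raw "entries > 0.5" convention including both triangles).
#' @export
count_predicted_pairs <- function(m, threshold = 0.5, full_matrix = FALSE) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  if (full_matrix) return(sum(m > threshold))
  sum(m[upper.tri(m)] > threshold)
}
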