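#' Loop decomposition of a nested secondary structure
#'
#' Assigns every position one structural context label: `P` (paired), or for
#' unpaired bases the class of the enclosing loop — hairpin (`HL`, closing
#' pair and no branch helix), bulge (`BL`, one branch, unpaired bases on
#' exactly one side), interior (`IL`, one branch, unpaired on both sides),
#' multiloop (`ML`, two or more branches) or exterior (`EL`, not enclosed by
#' any pair).
#'
#' @param pt a nested `pair_table`.
#' @return factor of length `n` with levels `P, EL, BL, HL, IL, ML`.
#' @export
loop_decomposition <- function(pt) {
  if (!is_nested(pt))
    stop("structure contains crossing pairs; call remove_pseudoknots() first")
  n <- pt$n
  partner <- pt$partner
  labels <- rep("EL", n)
  labels[!is.na(partner)] <- "P"
  loops <- enumerate_loops(pt)
  for (lp in loops) {
    if (length(lp$unpaired)) labels[lp$unpaired] <- lp$class
  }
  factor(labels, levels = c("P", "EL", "BL", "HL", "IL", "ML"))
}

# Walk all loops closed by a pair. Returns list of
# list(class = "HL"/"BL"/"IL"/"ML" (or NULL for a stack), unpaired = indices,
#      branches = count). Stacks (one branch, no unpaired) are skipped.
enumerate_loops <- function(pt) {
  partner <- pt$partner
  out <- list()
  pr <- pairs_of(pt)
  for (k in seq_len(nrow(pr))) {
    i <- pr[k, 1L]; j <- pr[k, 2L]
    unpaired <- integer(0L)
    branches <- 0L
    seg_lens <- integer(0L)   # unpaired run lengths between consecutive branches
    run <- 0L
    pos <- i + 1L
    while (pos < j) {
      if (is.na(partner[pos])) {
        unpaired <- c(unpaired, pos); run <- run + 1L; pos <- pos + 1L
      } else {
        branches <- branches + 1L
        seg_lens <- c(seg_lens, run); run <- 0L
        pos <- partner[pos] + 1L
      }
    }
    seg_lens <- c(seg_lens, run)
    cls <- if (branches == 0L) "HL"
      else if (branches >= 2L) "ML"
      else if (seg_lens[1L] > 0L && seg_lens[2L] > 0L) "IL"
      else if (seg_lens[1L] > 0L || seg_lens[2L] > 0L) "BL"
      else NA_character_  # perfect stack, no loop
    if (!is.na(cls))
      out[[length(out) + 1L]] <- list(class = cls, unpaired = unpaired,
                                      branches = branches)
  }
  out
}

#' Count structural elements of a structure
#'
#' A helix is a maximal run of stacked pairs `(i, j), (i+1, j-1), ...`; loop
#' elements are counted per [loop_decomposition()] instance. The exterior loop
#' counts as one element when there is at least one external unpaired base or
#' at least two top-level branches; a single helix spanning the entire
#' sequence has no exterior loop.
#'
#' @param pt a nested `pair_table`.
#' @return named numeric vector `helix, EL, BL, HL, IL, ML`.
#' @export
count_elements <- function(pt) {
  if (!is_nested(pt))
    stop("structure contains crossing pairs; call remove_pseudoknots() first")
  partner <- pt$partner
  n <- pt$n
  pr <- pairs_of(pt)
  helix <- 0L
  if (nrow(pr)) {
    i <- pr[, 1L]; j <- pr[, 2L]
    outerp <- rep(NA_integer_, n + 2L)
    outerp[2:(n + 1L)] <- partner
    # helix start: (i, j) without stacked outer pair (i-1, j+1)
    helix <- sum(is.na(outerp[i]) | outerp[i] != j + 1L)
  }
  counts <- c(helix = helix, EL = 0L, BL = 0L, HL = 0L, IL = 0L, ML = 0L)
  for (lp in enumerate_loops(pt)) counts[lp$class] <- counts[lp$class] + 1L
  # exterior loop
  ext_unpaired <- sum(is.na(partner) & ext_mask(pt))
  top_branches <- n_top_branches(pt)
  counts["EL"] <- as.integer(ext_unpaired > 0L || top_branches >= 2L)
  counts
}

ext_mask <- function(pt) {
  mask <- rep(TRUE, pt$n)
  pr <- pairs_of(pt)
  # positions strictly inside any top-level pair are not external
  pos <- 1L
  while (pos <= pt$n) {
    p <- pt$partner[pos]
    if (!is.na(p) && p > pos) {
      mask[pos:p] <- FALSE
      pos <- p + 1L
    } else pos <- pos + 1L
  }
  mask
}

n_top_branches <- function(pt) {
  k <- 0L; pos <- 1L
  while (pos <= pt$n) {
    p <- pt$partner[pos]
    if (!is.na(p) && p > pos) { k <- k + 1L; pos <- p + 1L } else pos <- pos + 1L
  }
  k
}

#' Classify base pairs by their ordered residues
#'
#' Each pair `(i, j)` with `i < j` is classified by `(seq[i], seq[j])` into
#' GC, CG, AU, UA, GU, UG or NC (non-canonical: anything else).
#'
#' @param seq an RNA sequence string.
#' @param pt matching `pair_table`.
#' @return named integer vector of counts over
#'   `GC, CG, AU, UA, GU, UG, NC`.
#' @export
pairtype_frequencies <- function(seq, pt) {
  seq <- rna_sequence(seq)
  if (nchar(seq) != pt$n) stop("sequence and structure lengths differ")
  pr <- pairs_of(pt)
  out <- stats::setNames(integer(7L), c("GC", "CG", "AU", "UA", "GU", "UG", "NC"))
  if (!nrow(pr)) return(out)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  key <- paste0(ch[pr[, 1L]], ch[pr[, 2L]])
  key[!key %in% names(out)] <- "NC"
  tab <- table(factor(key, levels = names(out)))
  out[] <- as.integer(tab)
  out
}

#' Unpaired length of every multiloop
#'
#' @param pt a nested `pair_table`.
#' @return integer vector, one entry per multiloop: the number of unpaired
#'   nucleotides inside that loop (closing and branch pairs not counted).
#' @export
multiloop_lengths <- function(pt) {
  if (!is_nested(pt))
    stop("structure contains crossing pairs; call remove_pseudoknots() first")
  lens <- integer(0L)
  for (lp in enumerate_loops(pt))
    if (lp$class == "ML") lens <- c(lens, length(lp$unpaired))
  lens
}

#' Aggregate structural statistics over a dataset
#'
#' Pools per-base context frequencies and per-pair type frequencies over all
#' structures, averages element counts per structure, and reports the median
#' multiloop length over all multiloops pooled.
#'
#' @param seqs character vector of sequences.
#' @param pts list of matching nested `pair_table`s.
#' @return object of class `structure_stats` with fields `context_freq`,
#'   `element_counts`, `pairtype_freq`, `multiloop_length_median`,
#'   `multiloop_lengths`, `n_structures`.
#' @export
aggregate_stats <- function(seqs, pts) {
  if (length(seqs) == 0L) stop("empty input")
  if (length(seqs) != length(pts)) stop("seqs and pts must be aligned")
  ctx <- stats::setNames(numeric(6L), c("P", "EL", "BL", "HL", "IL", "ML"))
  elem <- stats::setNames(numeric(6L), c("helix", "EL", "BL", "HL", "IL", "ML"))
  ptf <- stats::setNames(numeric(7L), c("GC", "CG", "AU", "UA", "GU", "UG", "NC"))
  mls <- integer(0L)
  for (k in seq_along(seqs)) {
    lab <- loop_decomposition(pts[[k]])
    ctx <- ctx + as.vector(table(lab))
    elem <- elem + count_elements(pts[[k]])
    ptf <- ptf + pairtype_frequencies(seqs[k], pts[[k]])
    mls <- c(mls, multiloop_lengths(pts[[k]]))
  }
  structure(list(
    context_freq = ctx / sum(ctx),
    element_counts = elem / length(seqs),
    pairtype_freq = if (sum(ptf) > 0) ptf / sum(ptf) else ptf,
    multiloop_length_median = if (length(mls)) stats::median(mls) else NA_real_,
    multiloop_lengths = mls,
    n_structures = length(seqs)
  ), class = "structure_stats")
}

#' @export
print.structure_stats <- function(x, ...) {
  cat("structure_stats over", x$n_structures, "structures\n")
  cat("  base context frequencies:\n")
  print(round(x$context_freq, 3))
  cat("  mean element counts per structure:\n")
  print(round(x$element_counts, 3))
  cat("  pair type frequencies:\n")
  print(round(x$pairtype_freq, 3))
  cat("  median multiloop length:", x$multiloop_length_median, "nt\n")
  invisible(x)
}
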