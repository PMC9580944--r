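#' Folding oracles
#'
#' A folding oracle maps an RNA sequence to a pseudoknot-free minimum-free-
#' energy (MFE) secondary structure. Three engines are available:
#'
#' * `"turner"` (default): the built-in nearest-neighbor dynamic-programming
#'   engine with the Turner-2004 core parameter set (stacking, terminal
#'   mismatches, dangles, loop initiations, multiloop model; the special
#'   1x1/2x1/2x2 interior tables are approximated by the generic interior
#'   rule). Deterministic; energies in kcal/mol.
#' * `"nussinov"`: base-pair maximization with minimum hairpin size 3.
#'   A clearly non-thermodynamic fallback, labeled as such.
#' * `"viennarna"`: shells out to an external `RNAfold` binary when one is on
#'   the PATH; otherwise constructing the oracle raises an environment error
#'   naming the built-in fallback.
#'
#' @param engine one of `"turner"`, `"nussinov"`, `"viennarna"`.
#' @param min_hairpin minimum unpaired hairpin size for the fallback engine.
#' @return object of class `folding_oracle` with fields `engine`, `id`.
#' @export
folding_oracle <- function(engine = c("turner", "nussinov", "viennarna"),
                           min_hairpin = 3L) {
  engine <- match.arg(engine)
  id <- switch(engine,
    turner = "synfold-zuker-turner2004-core",
    nussinov = paste0("synfold-nussinov-maxpair-h", min_hairpin, " (non-thermodynamic fallback)"),
    viennarna = {
      if (Sys.which("RNAfold") == "")
        stop("environment error: RNAfold binary not found on PATH; ",
             "use folding_oracle(\"turner\") (built-in) or ",
             "folding_oracle(\"nussinov\") (labeled fallback) instead")
      paste0("RNAfold ", tryCatch(
        system2("RNAfold", "--version", stdout = TRUE)[1L],
        error = function(e) "unknown"))
    })
  structure(list(engine = engine, id = id,
                 min_hairpin = as.integer(min_hairpin),
                 version = as.character(utils::packageVersion("synfold"))),
            class = "folding_oracle")
}

#' @export
print.folding_oracle <- function(x, ...) {
  cat("folding_oracle:", x$id, "\n")
  invisible(x)
}

#' Fold sequences to MFE dot-bracket structures
#'
#' @param seqs character vector of RNA sequences.
#' @param oracle a [folding_oracle()].
#' @return character vector of dot-bracket structures, with attribute
#'   `energy` (kcal/mol; `NA` for the fallback engine).
#' @export
fold_sequences <- function(seqs, oracle = folding_oracle()) {
  seqs <- rna_sequence(seqs)
  switch(oracle$engine,
    turner = {
      r <- .fold_turner_cpp(seqs)
      structure(r$structure, energy = r$energy)
    },
    nussinov = structure(.fold_nussinov_cpp(seqs, oracle$min_hairpin),
                         energy = rep(NA_real_, length(seqs))),
    viennarna = {
      inp <- tempfile(); out <- tempfile()
      writeLines(seqs, inp)
      system2("RNAfold", c("--noPS", "--infile", inp), stdout = out)
      lines <- readLines(out)
      unlink(c(inp, out))
      res <- lines[seq(2L, length(lines), by = 2L)]
      db <- sub(" .*$", "", res)
      en <- as.numeric(gsub("[ ()]", "", sub("^[.()\\[\\]{}<>]+ +", "", res)))
      structure(db, energy = en)
    })
}

#' Fold a set of sequences into a ground-truth dataset bundle
#'
#' @param seqs character vector of sequences.
#' @param oracle a [folding_oracle()].
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @param provenance optional list describing how `seqs` were drawn.
#' @return a [dataset_bundle()].
#' @export
fold_dataset <- function(seqs, oracle = folding_oracle(), split = "train",
                         provenance = list()) {
  db <- fold_sequences(seqs, oracle)
  pts <- lapply(db, parse_dotbracket)
  provenance$oracle_id <- oracle$id
  dataset_bundle(seqs, pts, provenance = provenance, split = split)
}

#' Aligned sequences, ground-truth structures and provenance
#'
#' @param sequences character vector (must be unique within the bundle).
#' @param structures list of `pair_table`s aligned with `sequences`.
#' @param provenance list (sampler spec, composition, seed, oracle id, ...).
#' @param split one of `"train"`, `"validation"`, `"test"`.
#' @export
dataset_bundle <- function(sequences, structures, provenance = list(),
                           split = c("train", "validation", "test")) {
  split <- match.arg(split)
  if (length(sequences) != length(structures))
    stop("sequences and structures must be aligned")
  if (anyDuplicated(sequences)) stop("duplicate sequences within bundle")
  ok <- vapply(seq_along(sequences),
               function(k) nchar(sequences[k]) == structures[[k]]$n, logical(1L))
  if (!all(ok)) stop("sequence/structure length mismatch at index ", which(!ok)[1L])
  structure(list(sequences = sequences, structures = structures,
                 provenance = provenance, split = split),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  lens <- nchar(x$sequences)
  cat("dataset_bundle:", length(x$sequences), "sequences (", x$split, "),",
      "lengths", min(lens), "-", max(lens), "\n")
  if (!is.null(x$provenance$oracle_id))
    cat("  oracle:", x$provenance$oracle_id, "\n")
  invisible(x)
}

#' @export
length.dataset_bundle <- function(x) length(x$sequences)
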