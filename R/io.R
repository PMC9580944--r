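#' Read and write FASTA sequence files
#'
#' Thin wrappers around plain-text FASTA. Sequences may span multiple lines.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  names(seqs) <- sub("^>\\s*", "", lines[hdr])[as.integer(names(seqs))]
  seqs
}

#' @param seqs named character vector.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Read and write dot-bracket (.dbn) structure files
#'
#' Three-line records: `>id`, sequence, structure.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `sequence`, `structure`.
#' @export
read_dbn <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 3L != 0L || !all(grepl("^>", lines[seq(1L, length(lines), 3L)])))
    stop("malformed .dbn file (expected 3-line >id/sequence/structure records): ", path)
  data.frame(id = sub("^>\\s*", "", lines[seq(1L, length(lines), 3L)]),
             sequence = lines[seq(2L, length(lines), 3L)],
             structure = lines[seq(3L, length(lines), 3L)],
             stringsAsFactors = FALSE)
}

#' @param x data.frame as returned by `read_dbn`, or a `dataset_bundle`.
#' @rdname read_dbn
#' @export
write_dbn <- function(x, path) {
  if (inherits(x, "dataset_bundle")) {
    x <- data.frame(id = paste0("seq", seq_along(x$sequences)),
                    sequence = x$sequences,
                    structure = vapply(x$structures, write_dotbracket, ""))
  }
  writeLines(paste0(">", x$id, "\n", x$sequence, "\n", x$structure), path)
  invisible(path)
}

#' Read and write bpseq structure files
#'
#' One record per file: lines of `index residue partner` triples, 1-based,
#' partner 0 meaning unpaired.
#'
#' @param path file path.
#' @return list with `sequence` (string; may contain N) and `structure`
#'   (a [pair_table()]).
#' @export
read_bpseq <- function(path) {
  tab <- utils::read.table(path, col.names = c("i", "res", "j"),
                           colClasses = c("integer", "character", "integer"))
  n <- nrow(tab)
  if (!identical(tab$i, seq_len(n)))
    stop("bpseq indices must be 1..n without gaps: ", path)
  if (any(tab$j < 0L | tab$j > n)) stop("bpseq partner index out of range: ", path)
  partner <- ifelse(tab$j == 0L, NA_integer_, tab$j)
  list(sequence = paste(toupper(tab$res), collapse = ""),
       structure = pair_table(as.integer(partner), n))
}

#' @param seq sequence string.
#' @param pt matching `pair_table`.
#' @rdname read_bpseq
#' @export
write_bpseq <- function(seq, pt, path) {
  if (nchar(seq) != pt$n) stop("sequence and structure lengths differ")
  p <- pt$partner
  p[is.na(p)] <- 0L
  writeLines(paste(seq_len(pt$n), strsplit(seq, "")[[1L]], p), path)
  invisible(path)
}

#' Write a dataset bundle manifest (JSON lines)
#'
#' One JSON object per line with id, sequence, structure and shared
#' provenance fields, so a bundle can be reconstructed byte-identically.
#'
#' @param bundle a `dataset_bundle`.
#' @param path output path.
#' @export
write_bundle_manifest <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- list(type = "bundle_header", split = bundle$split,
                 n = length(bundle$sequences), provenance = bundle$provenance)
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE), con)
  for (k in seq_along(bundle$sequences)) {
    rec <- list(id = paste0("seq", k), sequence = bundle$sequences[k],
                structure = write_dotbracket(bundle$structures[[k]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a dataset bundle manifest written by [write_bundle_manifest()]
#' @param path manifest path.
#' @export
read_bundle_manifest <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  recs <- lapply(lines[-1L], jsonlite::fromJSON)
  dataset_bundle(vapply(recs, `[[`, "", "sequence"),
                 lapply(recs, function(r) parse_dotbracket(r$structure)),
                 provenance = header$provenance, split = header$split)
}
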