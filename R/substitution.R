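#' Shift a substitution matrix to non-negative scores
#'
#' Adds a constant to every entry of a square, symmetric score matrix so that
#' its minimum element is exactly zero. The alignment engines assume
#' non-negative substitution scores with all gap costs expressed as
#' subtracted penalties; the shift applied is recorded so scores on the
#' original scale can be recovered.
#'
#' @param raw square symmetric numeric matrix with identical row and column
#'   names (residue one-letter codes).
#' @return the shifted matrix with class `substitution_matrix` and an
#'   `offset` attribute holding the constant that was added.
#' @examples
#' m <- shift_matrix(blosum62())
#' attr(m, "offset") # 4 for BLOSUM62
#' @export
shift_matrix <- function(raw) {
  raw <- as.matrix(raw)
  if (nrow(raw) != ncol(raw)) abort("substitution matrix must be square")
  if (!isTRUE(all.equal(raw, t(raw), check.attributes = FALSE)))
    abort("substitution matrix must be symmetric")
  offset <- -min(raw)
  if (offset < 0) offset <- 0
  out <- raw + offset
  attr(out, "offset") <- offset
  class(out) <- c("substitution_matrix", class(out))
  out
}

#' BLOSUM62 restricted to the 20 standard residues
#'
#' Returns the standard BLOSUM62 matrix (as distributed with Biostrings)
#' restricted to the 20 canonical amino acids, unshifted.
#'
#' @return 20 x 20 integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
}

#' @rdname blosum62
#' @details `blosum62_shifted()` is the default scoring matrix of the
#'   aligners: BLOSUM62 with +4 added so its minimum entry is 0 (W/W then
#'   scores 15).
#' @export
blosum62_shifted <- function() {
  shift_matrix(blosum62())
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix format used by the NCBI tools
#' (`#` comment lines, a header row of residue letters, one labelled row per
#' residue). Only the 20 standard residues are retained.
#'
#' @param path file path.
#' @return square numeric matrix with residue dimnames, unshifted.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  labs <- vapply(rows, `[`, character(1), 1)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(length(header))))
  dimnames(vals) <- list(labs, header)
  keep <- intersect(AA_ALPHABET, intersect(labs, header))
  vals[keep, keep]
}

ensure_shifted <- function(sm) {
  if (inherits(sm, "substitution_matrix")) return(sm)
  shift_matrix(sm)
}
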