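# FASTA and manifest I/O, via Biostrings.

#' Read sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a pairwise reference alignment from aligned FASTA
#'
#' The file must hold exactly two records of equal gapped length; the first
#' record is taken as the template row.
#'
#' @param path aligned-FASTA file with `-` gap symbols.
#' @return a [reference_alignment()].
#' @export
read_alignment_fasta <- function(path) {
  s <- read_fasta(path)
  if (length(s) != 2) abort("aligned FASTA must contain exactly two records")
  reference_alignment(s[[1]], s[[2]], names(s)[1], names(s)[2])
}

#' Write an alignment as aligned FASTA
#'
#' @param aln a `pairwise_alignment`, `reference_alignment` or `msa_result`.
#' @param path output file.
#' @export
write_alignment_fasta <- function(aln, path) {
  rows <- if (inherits(aln, "msa_result")) aln$rows
  else if (inherits(aln, "pairwise_alignment"))
    setNames(c(aln$row_template, aln$row_target), c("template", "target"))
  else setNames(c(aln$row_a, aln$row_b), c(aln$id_a, aln$id_b))
  write_fasta(rows, path)
}

#' Read a fitting corpus from a manifest
#'
#' Tab-separated manifest with columns `template_fasta`, `track`,
#' `target_fasta`, `reference` (paths, relative to the manifest's
#' directory), one row per pair.
#'
#' @param path manifest TSV.
#' @return corpus list consumable by [fit_gap_parameters()].
#' @export
read_corpus_manifest <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  base <- dirname(path)
  rel <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  purrr::map(seq_len(nrow(df)), function(i) {
    list(template = unname(read_fasta(rel(df$template_fasta[i]))[1]),
         track = read_track(rel(df$track[i])),
         target = unname(read_fasta(rel(df$target_fasta[i]))[1]),
         reference = read_alignment_fasta(rel(df$reference[i])))
  })
}

#' Write a simulated corpus to disk
#'
#' Writes per-pair template/target FASTA, accessibility track TSV and
#' reference aligned-FASTA files plus a manifest TSV consumable by
#' [read_corpus_manifest()].
#'
#' @param corpus a [simulate_corpus()] result.
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map(seq_along(corpus), function(i) {
    p <- corpus[[i]]
    tf <- sprintf("pair%03d_template.fasta", i)
    qf <- sprintf("pair%03d_target.fasta", i)
    kf <- sprintf("pair%03d_track.tsv", i)
    rf <- sprintf("pair%03d_ref.fasta", i)
    write_fasta(setNames(p$template, "template"), file.path(dir, tf))
    write_fasta(setNames(p$target, "target"), file.path(dir, qf))
    write_track(tibble(residue = seq_along(p$track),
                       aa = strsplit(p$template, "")[[1]],
                       acc = p$track), file.path(dir, kf))
    write_alignment_fasta(p$reference, file.path(dir, rf))
    data.frame(template_fasta = tf, track = kf, target_fasta = qf,
               reference = rf)
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(dplyr::bind_rows(rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest)
}
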