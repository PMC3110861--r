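# ---- pairwise alignment container ------------------------------------------

# ai, bi: per-column 1-based residue indices (0 = gap) from the C engines
new_pairwise_alignment <- function(a, b, ai, bi, score, method, params) {
  a_chars <- strsplit(a, "")[[1]]
  b_chars <- strsplit(b, "")[[1]]
  row_a <- ifelse(ai == 0, "-", a_chars[pmax(ai, 1)])
  row_b <- ifelse(bi == 0, "-", b_chars[pmax(bi, 1)])
  pairs <- tibble(template = ai[ai > 0 & bi > 0], target = bi[ai > 0 & bi > 0])
  structure(
    list(template = a, target = b,
         row_template = paste(row_a, collapse = ""),
         row_target = paste(row_b, collapse = ""),
         ai = ai, bi = bi,
         pairs = pairs,
         segments = alignment_segments_impl(ai, bi),
         score = score, method = method, params = params),
    class = "pairwise_alignment")
}

# maximal gap runs: deletion-of-template (gap in target row) and
# insertion-into-template (gap in template row, located at an inter-residue
# position of the template)
alignment_segments_impl <- function(ai, bi) {
  n_col <- length(ai)
  type <- ifelse(bi == 0, "deletion", ifelse(ai == 0, "insertion", "match"))
  r <- rle(type)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values != "match"
  if (!any(keep)) {
    return(tibble(type = character(), position = integer(),
                  t_start = integer(), t_end = integer(),
                  q_start = integer(), q_end = integer(),
                  length = integer()))
  }
  out <- purrr::map(which(keep), function(k) {
    s <- starts[k]; e <- ends[k]
    if (r$values[k] == "deletion") {
      tibble(type = "deletion",
             position = NA_integer_,
             t_start = ai[s], t_end = ai[e],
             q_start = NA_integer_, q_end = NA_integer_,
             length = e - s + 1L)
    } else {
      # template inter-residue position: number of template residues
      # consumed before the run
      pos <- if (s == 1) 0L else max(ai[1:(s - 1)])
      tibble(type = "insertion",
             position = pos,
             t_start = NA_integer_, t_end = NA_integer_,
             q_start = bi[s], q_end = bi[e],
             length = e - s + 1L)
    }
  })
  dplyr::bind_rows(out)
}

#' @export
print.pairwise_alignment <- function(x, width = 60, ...) {
  cat(sprintf("Pairwise global alignment (%s), score %.4f\n", x$method, x$score))
  n <- nchar(x$row_template)
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    cat("T ", substr(x$row_template, s, e), "\n", sep = "")
    cat("Q ", substr(x$row_target, s, e), "\n", sep = "")
    if (e < n) cat("\n")
  }
  invisible(x)
}

#' Aligned residue-index pairs of an alignment
#'
#' @param x a `pairwise_alignment` or `reference_alignment`.
#' @return tibble with columns `template`, `target` (1-based residue
#'   indices), one row per aligned (gap-free) column, strictly increasing in
#'   both coordinates.
#' @export
alignment_pairs <- function(x) {
  rows <- as_alignment_rows(x)
  ai <- row_indices(rows[1])
  bi <- row_indices(rows[2])
  tibble(template = ai[ai > 0 & bi > 0], target = bi[ai > 0 & bi > 0])
}

#' Gap segments of an alignment
#'
#' @inheritParams alignment_pairs
#' @return tibble with one row per maximal gap run: `type`
#'   (`"deletion"` of template residues `t_start..t_end`, or `"insertion"`
#'   into the template at inter-residue `position`, covering target residues
#'   `q_start..q_end`) and `length`.
#' @export
alignment_segments <- function(x) {
  rows <- as_alignment_rows(x)
  alignment_segments_impl(row_indices(rows[1]), row_indices(rows[2]))
}

# per-column residue indices (0 = gap) of one gapped row
row_indices <- function(row) {
  chars <- strsplit(row, "")[[1]]
  idx <- cumsum(chars != "-")
  idx[chars == "-"] <- 0L
  as.integer(idx)
}

# two gapped rows (template first) from any supported alignment object
as_alignment_rows <- function(x) {
  if (inherits(x, "pairwise_alignment")) c(x$row_template, x$row_target)
  else if (inherits(x, "reference_alignment")) c(x$row_a, x$row_b)
  else if (is.character(x) && length(x) == 2) x
  else abort("expected a pairwise_alignment, reference_alignment, or two gapped rows")
}

# ---- aligners ---------------------------------------------------------------

#' Global alignment with an affine gap penalty
#'
#' Needleman–Wunsch/Gotoh three-state global alignment maximising the sum of
#' substitution scores minus gap costs, where a maximal gap run of length L
#' costs `open + ext * (L - 1)`. Traceback is deterministic: on ties, match
#' is preferred over deletion of the first sequence over insertion, and
#' extending a gap run is preferred over opening a new one.
#'
#' @param a,b amino acid sequences (single strings); `a` is the template.
#' @param sm substitution matrix (shifted to non-negative entries if not
#'   already); default shifted BLOSUM62.
#' @param open,ext gap opening and extension penalties. The defaults 13 and
#'   1 are the values optimised against reference structural alignments for
#'   the shifted BLOSUM62.
#' @param free_ends if `TRUE`, terminal gaps are free (semi-global
#'   alignment). Off by default: the template–target modeling use-case
#'   penalises end gaps.
#' @return a `pairwise_alignment`.
#' @examples
#' aln <- align_affine("HEAGAWGHEE", "PAWHEAE")
#' aln$score
#' @export
align_affine <- function(a, b, sm = blosum62_shifted(), open = 13, ext = 1,
                         free_ends = FALSE) {
  sm <- ensure_shifted(sm)
  if (!nzchar(a) || !nzchar(b)) abort("both sequences must be non-empty")
  alph <- rownames(sm)
  ea <- aa_encode(a, alph, "template sequence")
  eb <- aa_encode(b, alph, "target sequence")
  res <- align_affine_cpp(ea, eb, sm, open, ext, free_ends)
  new_pairwise_alignment(a, b, res$ai, res$bi, res$score, "affine",
                         list(sm = sm, open = open, ext = ext,
                              free_ends = free_ends))
}

#' Global alignment with accessibility-dependent gap opening
#'
#' Aligns a target sequence against a template whose per-residue relative
#' solvent accessibility is known. Gap openings are position dependent:
#' * a deletion of template span `i..j` opens at
#'   `G(mean accessibility over i..j)` — the full segment average is used
#'   inside the dynamic program, which therefore explores all span ends
#'   (O(n^2 m); `max_del_span` bounds the span length if needed);
#' * an insertion into the template at inter-residue position `p` opens at
#'   `G` of the mean accessibility of the flanking residues (single flank at
#'   the termini).
#' Extensions cost `model$ext` per additional gapped position. All possible
#' opening penalties are precomputed before the dynamic program runs.
#'
#' With a constant track the method reduces exactly to [align_affine()] with
#' `open = G(a0)`; with `alpha = 0` it reduces to `open = beta`.
#'
#' @param template template amino acid sequence (single string).
#' @param track accessibility track for the template (numeric vector in
#'   \[0, 1\] or a track tibble), same length as the template.
#' @param target target amino acid sequence.
#' @param sm substitution matrix, shifted if needed.
#' @param model a [gap_penalty_model()].
#' @param max_del_span maximum deletion span explored (0 = unlimited).
#' @param free_ends if `TRUE`, terminal gaps are free.
#' @return a `pairwise_alignment`.
#' @export
align_accessibility <- function(template, track, target,
                                sm = blosum62_shifted(),
                                model = gap_penalty_model(),
                                max_del_span = 0, free_ends = FALSE) {
  sm <- ensure_shifted(sm)
  if (!nzchar(template) || !nzchar(target))
    abort("both sequences must be non-empty")
  acc <- track_values(track)
  if (length(acc) != nchar(template))
    abort(sprintf("track length (%d) does not match template length (%d)",
                  length(acc), nchar(template)))
  alph <- rownames(sm)
  ea <- aa_encode(template, alph, "template sequence")
  eb <- aa_encode(target, alph, "target sequence")
  gm <- build_gap_matrices(acc, model)
  res <- align_acc_cpp(ea, eb, sm, acc, model$alpha, model$beta, model$ext,
                       gm$open_ins, as.integer(max_del_span), free_ends)
  new_pairwise_alignment(template, target, res$ai, res$bi, res$score,
                         "accessibility",
                         list(sm = sm, model = model, acc = acc,
                              max_del_span = max_del_span,
                              free_ends = free_ends))
}

#' Recompute an alignment's score from its columns
#'
#' Re-derives the total score of a `pairwise_alignment` from its aligned
#' pairs and maximal gap runs under the penalty scheme stored in the object,
#' independently of the dynamic program's accumulator. Used to verify score
#' consistency.
#'
#' @param x a `pairwise_alignment` produced by [align_affine()] or
#'   [align_accessibility()].
#' @return numeric score.
#' @export
recompute_score <- function(x) {
  stopifnot(inherits(x, "pairwise_alignment"))
  p <- x$params
  sm <- p$sm
  ea <- aa_encode(x$template, rownames(sm))
  eb <- aa_encode(x$target, rownames(sm))
  subs <- sum(sm[cbind(ea[x$pairs$template], eb[x$pairs$target])])
  seg <- x$segments
  if (nrow(seg) == 0) return(subs)
  ends_free <- isTRUE(p$free_ends)
  n_col <- length(x$ai)
  terminal <- logical(nrow(seg))
  if (ends_free) {
    # a run is terminal if it touches either end of the alignment
    type <- ifelse(x$bi == 0, "d", ifelse(x$ai == 0, "i", "m"))
    r <- rle(type)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    gaps <- which(r$values != "m")
    terminal <- starts[gaps] == 1 | ends[gaps] == n_col
  }
  cost <- 0
  if (x$method != "affine") gm <- build_gap_matrices(p$acc, p$model)
  for (k in seq_len(nrow(seg))) {
    if (terminal[k]) next
    L <- seg$length[k]
    if (x$method == "affine") {
      cost <- cost + p$open + p$ext * (L - 1)
    } else {
      if (seg$type[k] == "deletion") {
        cost <- cost + gm$del_open(seg$t_start[k], seg$t_end[k]) +
          p$model$ext * (L - 1)
      } else {
        cost <- cost + gm$open_ins[seg$position[k] + 1] +
          p$model$ext * (L - 1)
      }
    }
  }
  subs - cost
}
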