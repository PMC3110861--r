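# Evaluation of a test alignment against a reference structural alignment.
# Insertions are runs of target residues aligned to gaps in the template
# row; their "point" is the template inter-residue position where they
# occur.

check_same_sequences <- function(test, ref) {
  rt <- as_alignment_rows(test)
  rr <- as_alignment_rows(ref)
  if (gsub("-", "", rt[1]) != gsub("-", "", rr[1]) ||
      gsub("-", "", rt[2]) != gsub("-", "", rr[2]))
    abort("test and reference alignments are over different sequences")
  invisible(TRUE)
}

#' Q-score of an alignment against a reference
#'
#' Fraction of the reference alignment's aligned residue pairs that the
#' test alignment reproduces: correctly aligned pairs divided by the number
#' of aligned pairs in the reference. Between 0 and 1.
#'
#' @param test,ref alignments over the same two ungapped sequences
#'   (`pairwise_alignment`, `reference_alignment`, or two gapped rows,
#'   template first).
#' @return numeric scalar in \[0, 1\].
#' @export
q_score <- function(test, ref) {
  check_same_sequences(test, ref)
  tp <- alignment_pairs(test)
  rp <- alignment_pairs(ref)
  if (nrow(rp) == 0) abort("reference alignment has no aligned pairs")
  mean(paste(rp$template, rp$target) %in% paste(tp$template, tp$target))
}

insertion_runs <- function(x) {
  seg <- alignment_segments(x)
  seg[seg$type == "insertion", , drop = FALSE]
}

#' Insertion segment precision
#'
#' A predicted insertion segment (maximal run of target residues aligned
#' against template gaps) is correct iff it overlaps some reference
#' insertion segment by at least one target residue. Each prediction is
#' judged independently. `I_s = TP / (TP + FP)`; with zero predicted
#' segments `I_s` is `NA` (flagged) and the counts are still returned.
#'
#' @inheritParams q_score
#' @return list with `score` (`I_s`) and `counts` (tibble `tp`, `fp`,
#'   `n_real`).
#' @export
insertion_segment_score <- function(test, ref) {
  check_same_sequences(test, ref)
  pred <- insertion_runs(test)
  real <- insertion_runs(ref)
  correct <- vapply(seq_len(nrow(pred)), function(k) {
    any(pred$q_start[k] <= real$q_end & pred$q_end[k] >= real$q_start)
  }, logical(1))
  tp <- sum(correct); fp <- nrow(pred) - tp
  list(score = if (nrow(pred) > 0) tp / nrow(pred) else NA_real_,
       counts = tibble(tp = tp, fp = fp, n_real = nrow(real)))
}

#' Insertion point precision
#'
#' A predicted insertion point (the template inter-residue position of an
#' insertion run) is correct iff it lies within a `window`-residue window
#' centred on some reference insertion point (default window 3: offsets of
#' at most one template residue). `I_p = TP / (TP + FP)`.
#'
#' @inheritParams q_score
#' @param window window size in residues (odd; default 3).
#' @return list with `score` (`I_p`) and `counts`.
#' @export
insertion_point_score <- function(test, ref, window = 3) {
  check_same_sequences(test, ref)
  stopifnot(window >= 1, window %% 2 == 1)
  half <- (window - 1) / 2
  pred <- insertion_runs(test)$position
  real <- insertion_runs(ref)$position
  correct <- vapply(pred, function(p) any(abs(p - real) <= half), logical(1))
  tp <- sum(correct); fp <- length(pred) - tp
  list(score = if (length(pred) > 0) tp / length(pred) else NA_real_,
       counts = tibble(tp = tp, fp = fp, n_real = length(real)))
}

#' Over/under-assignment coordinates of gap predictions
#'
#' Maps assignment counts to the evaluation plane:
#' `x = ln(FP / TP)` — negative iff correct assignments outnumber incorrect
#' ones (the desirable regime) — and `y = ln((TP + FP) / N_real)` — positive
#' indicates over-assignment of gaps, zero means as many assigned as real.
#' Sentinels: `TP = 0` gives `x = +Inf`; `TP + FP = 0` gives `y = -Inf`.
#'
#' @param counts tibble or list with `tp`, `fp`, `n_real` as produced by
#'   [insertion_segment_score()] or [insertion_point_score()].
#' @return tibble with columns `x`, `y`.
#' @export
xy_scores <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; n_real <- counts$n_real
  stopifnot(tp >= 0, fp >= 0)
  if (n_real == 0) abort("reference has no insertion segments: plane undefined")
  x <- if (tp == 0) Inf else log(fp / tp)   # log(0) = -Inf when fp = 0
  y <- if (tp + fp == 0) -Inf else log((tp + fp) / n_real)
  tibble(x = x, y = y)
}

#' All evaluation scores of one alignment
#'
#' Convenience wrapper computing the Q-score, the insertion segment and
#' point precisions and their over/under-assignment coordinates in one
#' tidy row.
#'
#' @inheritParams insertion_point_score
#' @return one-row tibble: `q`, `i_s`, `i_p`, `x_s`, `y_s`, `x_p`, `y_p`,
#'   `tp_s`, `fp_s`, `tp_p`, `fp_p`, `n_real`.
#' @export
score_alignment <- function(test, ref, window = 3) {
  q <- q_score(test, ref)
  ss <- insertion_segment_score(test, ref)
  ps <- insertion_point_score(test, ref, window)
  xs <- if (ss$counts$n_real > 0) xy_scores(ss$counts) else tibble(x = NA, y = NA)
  xp <- if (ps$counts$n_real > 0) xy_scores(ps$counts) else tibble(x = NA, y = NA)
  tibble(q = q, i_s = ss$score, i_p = ps$score,
         x_s = xs$x, y_s = xs$y, x_p = xp$x, y_p = xp$y,
         tp_s = ss$counts$tp, fp_s = ss$counts$fp,
         tp_p = ps$counts$tp, fp_p = ps$counts$fp,
         n_real = ss$counts$n_real)
}
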