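# Independent brute-force alignment oracle: enumerates every global
# alignment (no column may pair two gaps) and scores it with the
# maximal-run gap convention. Exponential; only for sequences of length
# <= ~7. Deliberately shares no code with the dynamic programming engines.
#
# ea, eb: encoded sequences; sm: score matrix;
# open_ins: length n+1 vector, opening of an insertion at template
#   inter-residue position p (index p+1);
# del_pen: function(s, e) -> opening of a deletion of template span s..e;
# ext: extension penalty per additional gapped position.
brute_force_best <- function(ea, eb, sm, open_ins, del_pen, ext) {
  n <- length(ea); m <- length(eb)
  best <- -Inf
  rec <- function(i, j, score, state, del_start, run_len) {
    # close an open run before branching into a different move
    close_run <- function(next_state) {
      if (state == "D" && next_state != "D") {
        score - del_pen(del_start, i) - ext * (i - del_start)
      } else if (state == "I" && next_state != "I") {
        score - open_ins[i + 1] - ext * (run_len - 1)
      } else score
    }
    if (i == n && j == m) {
      final <- close_run("end")
      if (final > best) best <<- final
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, close_run("M") + sm[ea[i + 1], eb[j + 1]],
          "M", NA, 0)
    if (i < n) {
      if (state == "D") rec(i + 1, j, score, "D", del_start, run_len + 1)
      else rec(i + 1, j, close_run("D"), "D", i + 1, 1)
    }
    if (j < m) {
      if (state == "I") rec(i, j + 1, score, "I", del_start, run_len + 1)
      else rec(i, j + 1, close_run("I"), "I", NA, 1)
    }
  }
  rec(0, 0, 0, "start", NA, 0)
  best
}

oracle_affine <- function(a, b, sm, open, ext) {
  ea <- match(strsplit(a, "")[[1]], rownames(sm))
  eb <- match(strsplit(b, "")[[1]], rownames(sm))
  brute_force_best(ea, eb, sm, rep(open, length(ea) + 1),
                   function(s, e) open, ext)
}

oracle_accessibility <- function(a, acc, b, sm, model) {
  ea <- match(strsplit(a, "")[[1]], rownames(sm))
  eb <- match(strsplit(b, "")[[1]], rownames(sm))
  n <- length(ea)
  flank <- if (n == 1) c(acc, acc) else
    c(acc[1], (acc[-n] + acc[-1]) / 2, acc[n])
  open_ins <- model$beta * exp(-model$alpha * flank)
  del_pen <- function(s, e)
    model$beta * exp(-model$alpha * mean(acc[s:e]))
  brute_force_best(ea, eb, sm, open_ins, del_pen, model$ext)
}

random_aa <- function(n) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], n, replace = TRUE),
        collapse = "")
}
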