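# Minimal progressive multiple alignment: Kimura-distance guide tree
# (UPGMA), leaves-to-root profile merging, accessibility-dependent gap
# penalty whenever a structure-bearing sequence participates.

#' Kimura's evolutionary distance from fractional identity
#'
#' With `p = 1 - identity`, the distance is `-ln(1 - p - p^2/5)`; it is 0 at
#' identity 1 and grows as identity falls, diverging near the formula's
#' domain boundary (identity about 0.146).
#'
#' @param identity fraction of identical residues among aligned pairs,
#'   in (0, 1].
#' @return numeric distance(s).
#' @export
kimura_distance <- function(identity) {
  if (any(identity <= 0) || any(identity > 1))
    abort("identity must lie in (0, 1]")
  p <- 1 - identity
  arg <- 1 - p - p^2 / 5
  if (any(arg <= 0))
    abort("identity too low: Kimura distance undefined (log argument <= 0)")
  -log(arg)
}

#' Build a UPGMA guide tree from a distance matrix
#'
#' Agglomerative average-linkage (UPGMA) clustering with deterministic
#' tie-breaking: among equally close cluster pairs, the pair whose smallest
#' member identifiers sort first (by the matrix's dimnames) is joined.
#'
#' @param distances symmetric numeric matrix with zero diagonal and
#'   identical row/column names.
#' @return object of class `guide_tree`: a nested list of joins (leaves are
#'   identifier strings; internal nodes are `list(left, right, height)`),
#'   plus `leaves` in left-to-right order.
#' @export
build_guide_tree <- function(distances) {
  d <- as.matrix(distances)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), check.attributes = FALSE)))
    abort("distance matrix must be symmetric")
  ids <- rownames(d) %||% as.character(seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) abort("need at least two sequences")
  nodes <- as.list(ids)
  sizes <- rep(1, n)
  reps <- ids # lexicographically smallest member id per cluster, for ties
  active <- rep(TRUE, n)
  dm <- d
  for (step in seq_len(n - 1)) {
    best <- NULL
    idx <- which(active)
    for (a in idx) for (b in idx) {
      if (a >= b) next
      better <- is.null(best) || dm[a, b] < best$d - 1e-12 ||
        (abs(dm[a, b] - best$d) <= 1e-12 &&
           (reps[a] < best$ra || (reps[a] == best$ra && reps[b] < best$rb)))
      if (better) best <- list(a = a, b = b, d = dm[a, b],
                               ra = reps[a], rb = reps[b])
    }
    a <- best$a; b <- best$b
    nodes[[a]] <- list(left = nodes[[a]], right = nodes[[b]],
                       height = best$d / 2)
    # UPGMA size-weighted distance update
    for (k in idx) {
      if (k == a || k == b) next
      dm[a, k] <- dm[k, a] <-
        (sizes[a] * dm[a, k] + sizes[b] * dm[b, k]) / (sizes[a] + sizes[b])
    }
    sizes[a] <- sizes[a] + sizes[b]
    reps[a] <- min(reps[a], reps[b])
    active[b] <- FALSE
  }
  root <- nodes[[which(active)]]
  structure(list(root = root, leaves = tree_leaves(root), ids = ids),
            class = "guide_tree")
}

tree_leaves <- function(node) {
  if (is.character(node)) return(node)
  c(tree_leaves(node$left), tree_leaves(node$right))
}

#' Newick serialisation of a guide tree
#' @param tree a `guide_tree`.
#' @return single Newick string (with node heights as branch lengths).
#' @export
guide_tree_newick <- function(tree) {
  rec <- function(node, parent_h) {
    if (is.character(node)) return(sprintf("%s:%.6g", node, parent_h))
    sprintf("(%s,%s):%.6g",
            rec(node$left, node$height), rec(node$right, node$height),
            max(parent_h - node$height, 0))
  }
  node <- tree$root
  paste0("(", rec(node$left, node$height), ",",
         rec(node$right, node$height), ");")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("UPGMA guide tree:", guide_tree_newick(x), "\n")
  invisible(x)
}

# ---- progressive alignment --------------------------------------------------

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from pairwise identities (affine baseline
#' alignments, Kimura distances, UPGMA) and merges profiles from the leaves
#' to the root, following "once a gap, always a gap". When a
#' structure-bearing sequence (one with an accessibility track)
#' participates in a merge, the accessibility-dependent gap penalty is
#' used; otherwise the fixed affine penalty. Identities below the Kimura
#' formula's domain are assigned a capped distance of 10.
#'
#' At internal (profile) merges, columns are scored by the mean pairwise
#' shifted substitution score (gap-residue pairs contribute 0) and gap
#' openings use the flank-average accessibility of the first track-bearing
#' member; full segment-average deletion openings apply at the pairwise
#' leaf merges only. This module is a deliberately reduced-scope
#' convenience around the pairwise aligner.
#'
#' @param seqs named character vector of at least 2 sequences.
#' @param tracks optional named list of accessibility tracks (numeric
#'   vectors or track tibbles) for the subset of sequences with known
#'   structure.
#' @param sm substitution matrix.
#' @param model [gap_penalty_model()] for structure-bearing merges.
#' @param open,ext affine penalties for structure-free merges.
#' @return object of class `msa_result`: `rows` (named character vector of
#'   equal-length gapped rows, input order), `tree` (the `guide_tree`).
#' @export
progressive_align <- function(seqs, tracks = NULL, sm = blosum62_shifted(),
                              model = gap_penalty_model(), open = 13,
                              ext = 1) {
  if (length(seqs) < 2) abort("need at least 2 sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- paste0("seq", seq_along(seqs))
  sm <- ensure_shifted(sm)
  ids <- names(seqs)
  tracks <- tracks %||% list()
  get_track <- function(id) if (id %in% names(tracks)) track_values(tracks[[id]])
  pair_align <- function(ida, idb) {
    ta <- get_track(ida); tb <- get_track(idb)
    if (!is.null(ta))
      align_accessibility(seqs[[ida]], ta, seqs[[idb]], sm, model)
    else if (!is.null(tb)) {
      aln <- align_accessibility(seqs[[idb]], tb, seqs[[ida]], sm, model)
      # swap rows back to (ida, idb) order
      list(row_a = aln$row_target, row_b = aln$row_template, score = aln$score)
    } else align_affine(seqs[[ida]], seqs[[idb]], sm, open, ext)
  }
  # guide tree from pairwise identities
  n <- length(seqs)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
    aln <- pair_align(ids[a], ids[b])
    rows <- if (inherits(aln, "pairwise_alignment"))
      c(aln$row_template, aln$row_target) else c(aln$row_a, aln$row_b)
    ca <- strsplit(rows[1], "")[[1]]; cb <- strsplit(rows[2], "")[[1]]
    both <- ca != "-" & cb != "-"
    identity <- if (any(both)) mean(ca[both] == cb[both]) else 0
    p <- 1 - identity
    dm[a, b] <- dm[b, a] <-
      if (identity > 0 && (1 - p - p^2 / 5) > 0) kimura_distance(identity)
      else 10
  }
  tree <- build_guide_tree(dm)
  merge_node <- function(node) {
    if (is.character(node)) return(setNames(seqs[node], node))
    left <- merge_node(node$left)
    right <- merge_node(node$right)
    if (length(left) == 1 && length(right) == 1) {
      aln <- pair_align(names(left), names(right))
      rows <- if (inherits(aln, "pairwise_alignment"))
        c(aln$row_template, aln$row_target) else c(aln$row_a, aln$row_b)
      return(setNames(rows, c(names(left), names(right))))
    }
    merge_profiles(left, right, tracks, sm, model, open, ext)
  }
  rows <- merge_node(tree$root)
  rows <- rows[ids[ids %in% names(rows)]]
  structure(list(rows = rows, tree = tree), class = "msa_result")
}

#' @export
print.msa_result <- function(x, width = 60, ...) {
  n <- nchar(x$rows[1])
  nm <- formatC(names(x$rows), width = max(nchar(names(x$rows))))
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    for (k in seq_along(x$rows))
      cat(nm[k], " ", substr(x$rows[k], s, e), "\n", sep = "")
    if (e < n) cat("\n")
  }
  invisible(x)
}

# profile-profile affine alignment with optional position-specific opening
merge_profiles <- function(left, right, tracks, sm, model, open, ext) {
  alph <- rownames(sm)
  prof_mat <- function(rows) {
    do.call(rbind, lapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      ifelse(ch == "-", 0L, match(ch, alph))
    }))
  }
  A <- prof_mat(left); B <- prof_mat(right)
  n <- ncol(A); m <- ncol(B)
  # column score: mean over member pairs; gaps contribute 0
  col_score <- function() {
    S <- matrix(0, n, m)
    for (i in seq_len(n)) {
      ai <- A[, i]
      for (j in seq_len(m)) {
        bj <- B[, j]
        tot <- 0
        for (u in seq_along(ai)) for (v in seq_along(bj))
          if (ai[u] > 0 && bj[v] > 0) tot <- tot + sm[ai[u], bj[v]]
        S[i, j] <- tot / (length(ai) * length(bj))
      }
    }
    S
  }
  S <- col_score()
  # position-specific opening from the first track-bearing member
  open_a <- rep(open, n + 1) # opening for gaps placed relative to profile A
  open_b <- rep(open, m + 1)
  track_member <- function(rows) {
    ids <- names(rows)
    hit <- ids[ids %in% names(tracks)]
    if (length(hit)) hit[1] else NULL
  }
  col_open <- function(rows, id) {
    acc <- track_values(tracks[[id]])
    ch <- strsplit(rows[[id]], "")[[1]]
    colacc <- rep(NA_real_, length(ch))
    colacc[ch != "-"] <- acc
    # flank-average over nearest non-gap neighbours
    filled <- colacc
    for (k in which(is.na(filled))) {
      lo <- which(!is.na(colacc[seq_len(k)])); lo <- if (length(lo)) max(lo) else NA
      hi <- which(!is.na(colacc)); hi <- hi[hi > k]; hi <- if (length(hi)) min(hi) else NA
      filled[k] <- mean(colacc[c(lo, hi)], na.rm = TRUE)
    }
    nn <- length(filled)
    flank <- if (nn == 1) c(filled, filled) else
      c(filled[1], (filled[-nn] + filled[-1]) / 2, filled[nn])
    gap_open_penalty(pmin(1, pmax(0, flank)), model)
  }
  ta <- track_member(left); tb <- track_member(right)
  if (!is.null(ta)) {
    open_a <- col_open(left, ta)
    open_b <- rep(NA, m + 1) # openings follow profile A's positions
  } else if (!is.null(tb)) {
    open_b <- col_open(right, tb)
    open_a <- rep(NA, n + 1)
  }
  # three-state DP; gaps in B (consuming A columns) open at A's position
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); D <- M; I <- M
  pM <- matrix(0L, n + 1, m + 1); pD <- pM; pI <- pM
  oa <- if (!is.null(ta)) open_a else if (!is.null(tb)) NULL else rep(open, n + 1)
  ob <- if (!is.null(tb)) open_b else if (!is.null(ta)) NULL else rep(open, m + 1)
  gap_open_d <- function(i, j) { # gap in B row-block, consuming A col i
    if (!is.null(oa)) oa[min(i, n) + 1] else ob[min(j, m) + 1]
  }
  gap_open_i <- function(i, j) { # gap in A row-block, consuming B col j
    if (!is.null(oa)) oa[min(i, n) + 1] else ob[min(j, m) + 1]
  }
  M[1, 1] <- 0
  for (i in seq_len(n)) {
    D[i + 1, 1] <- -(gap_open_d(i, 0) + ext * (i - 1))
    pD[i + 1, 1] <- if (i == 1) 0L else 1L
  }
  for (j in seq_len(m)) {
    I[1, j + 1] <- -(gap_open_i(0, j) + ext * (j - 1))
    pI[1, j + 1] <- if (j == 1) 0L else 2L
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    cands <- c(M[i, j], D[i, j], I[i, j])
    s <- which.max(cands)
    M[i + 1, j + 1] <- cands[s] + S[i, j]
    pM[i + 1, j + 1] <- s - 1L
    od <- gap_open_d(i, j)
    cands <- c(D[i, j + 1] - ext, M[i, j + 1] - od, I[i, j + 1] - od)
    s <- which.max(cands)
    D[i + 1, j + 1] <- cands[s]
    pD[i + 1, j + 1] <- c(1L, 0L, 2L)[s]
    oi <- gap_open_i(i, j)
    cands <- c(I[i + 1, j] - ext, M[i + 1, j] - oi, D[i + 1, j] - oi)
    s <- which.max(cands)
    I[i + 1, j + 1] <- cands[s]
    pI[i + 1, j + 1] <- c(2L, 0L, 1L)[s]
  }
  s <- which.max(c(M[n + 1, m + 1], D[n + 1, m + 1], I[n + 1, m + 1])) - 1L
  i <- n; j <- m
  cols_a <- integer(0); cols_b <- integer(0) # 0 = gap column
  while (i > 0 || j > 0) {
    if (s == 0) {
      cols_a <- c(i, cols_a); cols_b <- c(j, cols_b)
      s <- pM[i + 1, j + 1]; i <- i - 1; j <- j - 1
    } else if (s == 1) {
      cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b)
      s <- pD[i + 1, j + 1]; i <- i - 1
    } else {
      cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b)
      s <- pI[i + 1, j + 1]; j <- j - 1
    }
  }
  expand <- function(rows, cols) {
    vapply(rows, function(r) {
      ch <- strsplit(r, "")[[1]]
      paste(ifelse(cols == 0, "-", ch[pmax(cols, 1)]), collapse = "")
    }, character(1))
  }
  c(expand(left, cols_a), expand(right, cols_b))
}
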