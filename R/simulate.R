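# Synthetic template/target pairs with accessibility-biased indels, plus
# toy PDB structures with analytically checkable geometry. These generators
# define the benchmark conditions used throughout the test-suite.

# conditional substitution kernel p(b | a) ~ exp(lambda * S(a, b)), b != a,
# on the raw BLOSUM62 scale (lambda = ln(2)/2, the matrix's half-bit unit):
# substitutions are conservative, as in real divergence, so that homologous
# mismatch columns still score above the gap-detour break-even
substitution_kernel <- function(lambda = log(2) / 2) {
  B <- blosum62()
  K <- exp(lambda * B)
  diag(K) <- 0
  K / rowSums(K)
}

#' Simulate a template/target pair with accessibility-biased indels
#'
#' Draws a template sequence with per-residue relative accessibilities,
#' then derives a target by (i) substituting each site with probability
#' `sub_rate`, replacements drawn from a BLOSUM62-conditional kernel
#' (`p(b|a) ~ exp(S(a,b) * ln(2)/2)` over `b != a`, i.e. conservative
#' substitutions as in real divergence) and
#' (ii) placing indel events whose locations follow the empirical gap law:
#' deletion spans of the template are chosen with probability proportional
#' to `exp(law_slope * sum(acc over span))` (so each residue's inclusion
#' odds scale as `exp(law_slope * acc)`, the residue-wise law), and
#' insertions into the template are placed at inter-residue positions with
#' probability proportional to `exp(law_slope * mean(flank acc))`. The true
#' alignment is recorded as the reference. `law_intercept` is absorbed by
#' the normalisation of placement probabilities and only documents the law.
#'
#' The number of indel events is Poisson with mean `indel_rate * n`, split
#' evenly between deletions and insertions; event lengths are geometric
#' with mean `indel_mean_len`.
#'
#' @param n ancestor (template) length (default 150).
#' @param sub_rate per-site substitution probability (default 0.65; the
#'   resulting ~35% identity sits in the twilight zone the method targets).
#' @param indel_rate expected indel events per residue (default 0.02).
#' @param indel_mean_len mean indel length (geometric; default 3).
#' @param law_slope,law_intercept coefficients of the gap placement law
#'   (defaults 1.55 and -0.50, the fitted log-linear gap odds law).
#' @param acc_beta optional length-2 shape parameters: accessibilities are
#'   drawn Beta(a, b) instead of uniform.
#' @param seed optional integer seed (full determinism when fixed).
#' @return list with `template` (string), `track` (numeric accessibilities),
#'   `target` (string), `reference` ([reference_alignment()], template row
#'   first), and `events` (tibble of the indel events).
#' @export
simulate_pair <- function(n = 150, sub_rate = 0.65, indel_rate = 0.02,
                          indel_mean_len = 3, law_slope = 1.55,
                          law_intercept = -0.50, acc_beta = NULL,
                          seed = NULL) {
  stopifnot(n >= 2, sub_rate >= 0, sub_rate <= 1, indel_rate >= 0,
            indel_rate <= 1, indel_mean_len >= 1)
  with_seed(seed, {
    acc <- if (is.null(acc_beta)) runif(n) else rbeta(n, acc_beta[1], acc_beta[2])
    template <- sample(AA_ALPHABET, n, replace = TRUE)
    target_res <- template
    K <- substitution_kernel()
    subbed <- runif(n) < sub_rate
    target_res[subbed] <- vapply(template[subbed], function(a)
      sample(AA_ALPHABET, 1, prob = K[a, ]), character(1))
    n_ev <- rpois(1, indel_rate * n)
    is_del <- runif(n_ev) < 0.5
    lens <- rgeom(n_ev, 1 / indel_mean_len) + 1
    deleted <- rep(FALSE, n)
    events <- list()
    # deletions: spans weighted by exp(slope * sum(acc)), non-overlapping
    for (k in which(is_del)) {
      L <- min(lens[k], n - 1)
      if (L < 1) next
      starts <- seq_len(n - L + 1)
      ok <- vapply(starts, function(s) !any(deleted[s:(s + L - 1)]), logical(1))
      starts <- starts[ok]
      if (length(starts) == 0) next
      wsum <- vapply(starts, function(s) sum(acc[s:(s + L - 1)]), numeric(1))
      w <- exp(law_slope * wsum)
      s <- if (length(starts) == 1) starts else
        sample(starts, 1, prob = w / sum(w))
      if (sum(!deleted) - L < 2) next # keep the target non-empty
      deleted[s:(s + L - 1)] <- TRUE
      events[[length(events) + 1]] <-
        tibble(type = "deletion", position = s, length = L)
    }
    # insertions: inter-residue positions weighted by flank-average law
    flank <- c(acc[1], (acc[-n] + acc[-1]) / 2, acc[n]) # positions 0..n
    ins_at <- vector("list", n + 1)
    for (k in which(!is_del)) {
      L <- lens[k]
      w <- exp(law_slope * flank)
      p <- sample(0:n, 1, prob = w / sum(w))
      ins_at[[p + 1]] <- c(ins_at[[p + 1]],
                           list(sample(AA_ALPHABET, L, replace = TRUE)))
      events[[length(events) + 1]] <-
        tibble(type = "insertion", position = p, length = L)
    }
    # build the true alignment rows
    row_a <- character(0); row_b <- character(0)
    emit_ins <- function(p) {
      for (res in ins_at[[p + 1]]) {
        row_a <<- c(row_a, rep("-", length(res)))
        row_b <<- c(row_b, res)
      }
    }
    emit_ins(0)
    for (i in seq_len(n)) {
      if (deleted[i]) {
        row_a <- c(row_a, template[i]); row_b <- c(row_b, "-")
      } else {
        row_a <- c(row_a, template[i]); row_b <- c(row_b, target_res[i])
      }
      emit_ins(i)
    }
    ref <- reference_alignment(paste(row_a, collapse = ""),
                               paste(row_b, collapse = ""),
                               "template", "target")
    list(template = paste(template, collapse = ""), track = acc,
         target = ref$seq_b, reference = ref,
         events = if (length(events)) dplyr::bind_rows(events) else
           tibble(type = character(), position = integer(), length = integer()))
  })
}

#' Simulate a corpus of template/target pairs
#'
#' @inheritParams simulate_pair
#' @param count number of pairs.
#' @param seed integer seed for the whole corpus.
#' @param ... passed to [simulate_pair()].
#' @return list of [simulate_pair()] results.
#' @export
simulate_corpus <- function(count, seed = NULL, ...) {
  with_seed(seed, lapply(seq_len(count), function(i) simulate_pair(...)))
}

#' Toy PDB structures with analytically checkable geometry
#'
#' Emits minimal valid PDB text for surface-area test cases:
#' `single_atom` (one carbon at the origin: isolated-sphere area),
#' `coincident_pair` (two carbons at the same point: full occlusion),
#' `cap_pair` (two carbons at distance `d`: spherical-cap closed form),
#' `extended_tripeptide` (Ala-Ala-Ala with idealised extended backbone
#' coordinates, for cross-implementation checks).
#'
#' @param case one of the case names above.
#' @param d centre distance in Angstroms for `cap_pair` (default 2).
#' @return character vector of PDB lines.
#' @export
make_toy_pdb <- function(case = c("single_atom", "coincident_pair",
                                  "cap_pair", "extended_tripeptide"),
                         d = 2.0) {
  case <- match.arg(case)
  atom <- function(serial, name, resname, resno, x, y, z, element) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, resname, resno, x, y, z, element)
  }
  lines <- switch(case,
    single_atom = atom(1, " CA ", "ALA", 1, 0, 0, 0, "C"),
    coincident_pair = c(atom(1, " CA ", "ALA", 1, 0, 0, 0, "C"),
                        atom(2, " CB ", "ALA", 1, 0, 0, 0, "C")),
    cap_pair = c(atom(1, " CA ", "ALA", 1, 0, 0, 0, "C"),
                 atom(2, " CA ", "ALA", 2, d, 0, 0, "C")),
    extended_tripeptide = {
      # idealised extended chain: residue i offset by 3.6 A along x
      res <- function(i, x0) c(
        atom(4 * i - 3, " N  ", "ALA", i, x0 + 0.0, 0.3, 0, "N"),
        atom(4 * i - 2, " CA ", "ALA", i, x0 + 1.4, 0.9, 0, "C"),
        atom(4 * i - 1, " C  ", "ALA", i, x0 + 2.6, 0.1, 0, "C"),
        atom(4 * i - 0, " O  ", "ALA", i, x0 + 2.7, -1.1, 0, "O"))
      c(res(1, 0), res(2, 3.6), res(3, 7.2))
    })
  c(lines, "END")
}
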