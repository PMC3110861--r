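sm <- blosum62_shifted()

test_that("matrix shifting zeroes the minimum and records the offset", {
  raw <- blosum62()
  shifted <- shift_matrix(raw)
  expect_equal(min(shifted), 0)
  expect_equal(attr(shifted, "offset"), 4)
  expect_equal(shifted["W", "W"], 15)
  expect_true(isSymmetric(unclass(shifted)))
  # already non-negative -> unchanged, offset 0
  nn <- matrix(c(1, 2, 2, 3), 2, 2, dimnames = list(c("A", "R"), c("A", "R")))
  s2 <- shift_matrix(nn)
  expect_equal(unclass(s2)[1:2, 1:2], nn, ignore_attr = TRUE)
  expect_equal(attr(s2, "offset"), 0)
  # asymmetric input rejected
  bad <- nn; bad[1, 2] <- 9
  expect_error(shift_matrix(bad), "symmetric")
})

test_that("the NCBI-format matrix file reproduces BLOSUM62", {
  path <- system.file("extdata", "BLOSUM62.txt", package = "accalign")
  m <- read_substitution_matrix(path)
  expect_equal(m, blosum62(), ignore_attr = TRUE)
  expect_equal(min(m), -4)
})

test_that("gap opening penalty follows the exponential decay", {
  m <- gap_penalty_model(2.1, 32.8, 1)
  expect_equal(gap_open_penalty(0, m), 32.8)
  expect_equal(gap_open_penalty(1, m), 32.8 * exp(-2.1), tolerance = 1e-12)
  expect_equal(gap_open_penalty(1, m), 4.016, tolerance = 1e-3)
  expect_gt(gap_open_penalty(0.3, m), gap_open_penalty(0.6, m))
  expect_error(gap_open_penalty(1.2, m), "\\[0, 1\\]")
  expect_error(gap_open_penalty(-0.1, m), "\\[0, 1\\]")
})

test_that("gap matrices implement flank and segment averaging", {
  m <- gap_penalty_model(2.1, 32.8, 1)
  # constant track: every entry equals G(a0)
  gm <- build_gap_matrices(rep(0.4, 5), m)
  expect_true(all(abs(gm$open_ins - gap_open_penalty(0.4, m)) < 1e-12))
  expect_equal(gm$del_open(2, 4), gap_open_penalty(0.4, m))
  # flanks 0.2 / 0.4 -> insertion open G(0.3); span (0.1, 0.5) -> G(0.3)
  gm2 <- build_gap_matrices(c(0.2, 0.4), m)
  expect_equal(gm2$open_ins[2], gap_open_penalty(0.3, m))
  gm3 <- build_gap_matrices(c(0.1, 0.5), m)
  expect_equal(gm3$del_open(1, 2), gap_open_penalty(0.3, m))
  expect_equal(gm3$del_open(1, 2), gm2$open_ins[2])
  # termini use the single flanking residue
  expect_equal(gm2$open_ins[1], gap_open_penalty(0.2, m))
  expect_equal(gm2$open_ins[3], gap_open_penalty(0.4, m))
  # single-residue deletion equals G(acc of that residue)
  tr <- c(0.13, 0.77, 0.35)
  gm4 <- build_gap_matrices(tr, m)
  for (i in 1:3) expect_equal(gm4$del_open(i, i), gap_open_penalty(tr[i], m))
  # prefix-sum segment mean agrees with a direct mean
  expect_equal(gm4$del_open(1, 3), gap_open_penalty(mean(tr), m))
})

test_that("identical sequences align gapless with the diagonal score", {
  a <- "MKVLAW"
  aln <- align_affine(a, a, sm)
  expect_equal(nrow(aln$segments), 0)
  ea <- match(strsplit(a, "")[[1]], rownames(sm))
  expect_equal(aln$score, sum(sm[cbind(ea, ea)]))
  expect_equal(aln$row_template, a)
})

test_that("contracts reject empty sequences and unknown symbols", {
  expect_error(align_affine("A", "", sm), "non-empty")
  expect_error(align_affine("", "A", sm), "non-empty")
  expect_error(align_affine("AXB", "AAB", sm), "position 2")
  expect_error(align_accessibility("AC", c(0.5), "AC", sm), "track length")
})

test_that("affine scores equal brute-force enumeration on short pairs", {
  set.seed(101)
  for (r in 1:120) {
    a <- random_aa(sample(1:6, 1)); b <- random_aa(sample(1:6, 1))
    open <- runif(1, 1, 20); ext <- runif(1, 0.2, 3)
    aln <- align_affine(a, b, sm, open, ext)
    expect_equal(aln$score, oracle_affine(a, b, sm, open, ext),
                 tolerance = 1e-9)
    expect_equal(recompute_score(aln), aln$score, tolerance = 1e-9)
  }
})

test_that("affine alignment score is symmetric in its arguments", {
  set.seed(7)
  for (r in 1:25) {
    a <- random_aa(sample(4:20, 1)); b <- random_aa(sample(4:20, 1))
    expect_equal(align_affine(a, b, sm)$score, align_affine(b, a, sm)$score)
  }
})

test_that("accessibility-dependent scores equal brute-force enumeration", {
  set.seed(202)
  for (r in 1:120) {
    na <- sample(1:6, 1); nb <- sample(1:6, 1)
    a <- random_aa(na); b <- random_aa(nb)
    acc <- runif(na)
    mo <- gap_penalty_model(runif(1, 0, 4), runif(1, 5, 40), runif(1, 0.2, 3))
    aln <- align_accessibility(a, acc, b, sm, mo)
    expect_equal(aln$score, oracle_accessibility(a, acc, b, sm, mo),
                 tolerance = 1e-9)
    expect_equal(recompute_score(aln), aln$score, tolerance = 1e-9)
  }
})

test_that("a constant track reduces exactly to the affine aligner", {
  set.seed(303)
  for (r in 1:30) {
    na <- sample(3:25, 1); nb <- sample(3:25, 1)
    a <- random_aa(na); b <- random_aa(nb)
    a0 <- runif(1)
    mo <- gap_penalty_model(2.1, 32.8, 1)
    x <- align_accessibility(a, rep(a0, na), b, sm, mo)
    y <- align_affine(a, b, sm, open = gap_open_penalty(a0, mo), ext = 1)
    expect_equal(x$score, y$score, tolerance = 1e-9)
    expect_identical(x$row_template, y$row_template)
    expect_identical(x$row_target, y$row_target)
  }
})

test_that("alpha = 0 reduces to the affine aligner with open = beta", {
  set.seed(404)
  for (r in 1:20) {
    na <- sample(3:25, 1); nb <- sample(3:25, 1)
    a <- random_aa(na); b <- random_aa(nb)
    mo <- gap_penalty_model(0, 13, 1)
    x <- align_accessibility(a, runif(na), b, sm, mo)
    y <- align_affine(a, b, sm, open = 13, ext = 1)
    expect_equal(x$score, y$score, tolerance = 1e-9)
    expect_identical(x$row_target, y$row_target)
  }
})

test_that("a deletion is steered to the exposed template residue", {
  # template one residue longer than the target; a single exposed residue
  # makes that deletion far cheaper than any alternative
  template <- "MKVAWLE"
  target <- "MKVWLE" # residue 4 (A) missing
  acc <- c(0.05, 0.05, 0.05, 0.95, 0.05, 0.05, 0.05)
  aln <- align_accessibility(template, acc, target, sm)
  expect_equal(nrow(aln$segments), 1)
  expect_equal(aln$segments$type, "deletion")
  expect_equal(aln$segments$t_start, 4)
  expect_equal(aln$segments$t_end, 4)
})

test_that("alignments reconstruct both input sequences exactly", {
  set.seed(505)
  for (r in 1:20) {
    a <- random_aa(sample(5:40, 1)); b <- random_aa(sample(5:40, 1))
    acc <- runif(nchar(a))
    for (aln in list(align_affine(a, b, sm), align_accessibility(a, acc, b, sm))) {
      expect_equal(gsub("-", "", aln$row_template), a)
      expect_equal(gsub("-", "", aln$row_target), b)
      p <- aln$pairs
      if (nrow(p) > 1) {
        expect_true(all(diff(p$template) > 0))
        expect_true(all(diff(p$target) > 0))
      }
    }
  }
})

test_that("a deletion span cap bounds segment lengths", {
  set.seed(606)
  a <- random_aa(40); b <- random_aa(20)
  acc <- runif(40)
  aln <- align_accessibility(a, acc, b, sm, max_del_span = 3)
  dels <- aln$segments[aln$segments$type == "deletion", ]
  expect_true(all(dels$length <= 3))
})

test_that("free end gaps leave terminal overhangs unpenalised", {
  aln <- align_affine("WWKVLAWWW", "KVLA", sm, free_ends = TRUE)
  ea <- match(strsplit("KVLA", "")[[1]], rownames(sm))
  expect_equal(aln$score, sum(sm[cbind(ea, ea)]))
  expect_equal(gsub("-", "", aln$row_target), "KVLA")
  acc <- rep(0.5, 9)
  aln2 <- align_accessibility("WWKVLAWWW", acc, "KVLA", sm, free_ends = TRUE)
  expect_equal(aln2$score, aln$score)
})
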