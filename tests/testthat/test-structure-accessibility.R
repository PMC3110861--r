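test_that("minimal ATOM records parse into residues and atoms", {
  s <- read_structure(make_toy_pdb("single_atom"))
  expect_s3_class(s, "protein_structure")
  expect_equal(nrow(s$residues), 1)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$element, "C")
  expect_equal(structure_sequence(s), "A")
})

test_that("alternate locations keep the highest-occupancy atom", {
  lines <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40  0.00           C",
    "END")
  s <- read_structure(lines)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 0)
  expect_equal(s$atoms$occ, 0.6)
  # the B location wins when its occupancy is higher
  lines2 <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.70  0.00           C",
    "END")
  s2 <- read_structure(lines2)
  expect_equal(s2$atoms$x, 5)
  expect_equal(s2$atoms$occ, 0.7)
  # occupancy ties resolve to the alphabetically first altloc
  lines3 <- c(
    "ATOM      1  CA BALA A   1       5.000   0.000   0.000  0.50  0.00           C",
    "ATOM      2  CA AALA A   1       0.000   0.000   0.000  0.50  0.00           C",
    "END")
  expect_equal(read_structure(lines3)$atoms$x, 0)
})

test_that("waters, heteroatoms and hydrogens are excluded", {
  het_only <- c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END")
  expect_error(read_structure(het_only), "no residues")
  with_h <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA A   1       1.000   0.000   0.000  1.00  0.00           H",
    "HETATM    3  O   HOH A   2       9.000   0.000   0.000  1.00  0.00           O",
    "END")
  s <- read_structure(with_h)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$element, "C")
})

test_that("malformed coordinates are reported with their line number", {
  lines <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       bad..   0.000   0.000  1.00  0.00           C")
  expect_error(read_structure(lines), "line 2")
})

test_that("isolated sphere area matches the closed form within 1%", {
  s <- read_structure(make_toy_pdb("single_atom"))
  a <- atom_asa(s, probe_radius = 1.4, n_points = 960)
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 0.01)
  # golden-spiral weights are uniform, so an isolated sphere is exact
  expect_equal(a, 4 * pi * 3.1^2, tolerance = 1e-9)
})

test_that("coincident equal atoms fully occlude each other", {
  s <- read_structure(make_toy_pdb("coincident_pair"))
  expect_equal(atom_asa(s), c(0, 0))
})

test_that("two-sphere areas match the spherical-cap closed form within 1%", {
  R <- 1.7 + 1.4
  for (d in c(1.0, 2.0, 3.0, 5.0)) {
    s <- read_structure(make_toy_pdb("cap_pair", d = d))
    a <- atom_asa(s, n_points = 960)
    h <- R - d / 2                       # cap height buried on each sphere
    expected <- 4 * pi * R^2 - 2 * pi * R * h
    expect_equal(a[1], expected, tolerance = 0.01)
    expect_equal(a[2], expected, tolerance = 0.01)
  }
})

test_that("sphere-point refinement converges on the cap case", {
  s <- read_structure(make_toy_pdb("cap_pair", d = 2.0))
  R <- 3.1
  expected <- 4 * pi * R^2 - 2 * pi * R * (R - 1)
  err <- vapply(c(92, 960), function(np)
    abs(atom_asa(s, n_points = np)[1] - expected), numeric(1))
  expect_lt(err[2] / expected, 0.01)
  expect_lte(err[2], err[1] + 1e-9)
})

test_that("adding an atom never increases another atom's area", {
  base <- read_structure(make_toy_pdb("cap_pair", d = 2.0))
  extra <- c(make_toy_pdb("cap_pair", d = 2.0)[1:2],
             "ATOM      3  CA  ALA A   3       1.000   2.000   0.000  1.00  0.00           C",
             "END")
  grown <- read_structure(extra)
  a0 <- atom_asa(base)
  a1 <- atom_asa(grown)
  expect_true(all(a1[1:2] <= a0 + 1e-9))
})

test_that("accessibility is invariant under rigid motion", {
  s <- read_structure(make_toy_pdb("extended_tripeptide"))
  t0 <- residue_accessibility(s)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% rot
  s2 <- s
  s2$atoms$x <- xyz[, 1] + 11.3
  s2$atoms$y <- xyz[, 2] - 4.2
  s2$atoms$z <- xyz[, 3] + 0.9
  t1 <- residue_accessibility(s2)
  expect_equal(t1$acc, t0$acc, tolerance = 1e-6)
})

test_that("relative accessibility normalises and clamps correctly", {
  # fully occluded residue -> 0
  s0 <- read_structure(make_toy_pdb("coincident_pair"))
  expect_equal(residue_accessibility(s0)$acc, 0)
  # isolated residue whose summed area equals its reference maximum -> 1
  s1 <- read_structure(make_toy_pdb("single_atom"))
  area <- atom_asa(s1)
  expect_equal(residue_accessibility(s1, reference_areas = c(A = area))$acc, 1)
  # clamped at 1 when the reference is smaller than the sum
  expect_equal(residue_accessibility(s1, reference_areas = c(A = area / 2))$acc, 1)
  # missing residue type errors
  expect_error(residue_accessibility(s1, reference_areas = c(G = 104)),
               "missing")
})

test_that("tripeptide central-residue accessibility matches an independent implementation", {
  # frozen oracle: biotite 1.4.0 structure.sasa on the identical toy PDB
  # (probe 1.4 A, 960 points, single-atom radii) gives 83.25 A^2 for the
  # central residue -> 83.25 / 129 = 0.6454
  s <- read_structure(make_toy_pdb("extended_tripeptide"))
  tr <- residue_accessibility(s)
  expect_equal(tr$acc[2], 0.6454, tolerance = 0.05)
})

test_that("track round-trips through the tab-separated format", {
  s <- read_structure(make_toy_pdb("extended_tripeptide"))
  tr <- residue_accessibility(s)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_track(tr, path)
  back <- read_track(path)
  expect_equal(back$acc, tr$acc, tolerance = 1e-12)
  expect_equal(back$aa, tr$aa)
})
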