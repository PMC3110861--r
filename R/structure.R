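# ---- reference tables -------------------------------------------------------

#' Van der Waals radii used by the surface-area calculator
#'
#' Element-keyed radii in Angstroms (a single published consensus set).
#' Replace entries to change the convention.
#'
#' @return named numeric vector.
#' @export
vdw_radii_default <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90, H = 1.20,
    D = 1.20)
}

#' Per-residue-type maximum accessible surface areas
#'
#' Theoretical maximum ASA of residue X in an extended Gly-X-Gly context
#' (Tien et al. 2013, "theoretical" column), in square Angstroms, used to
#' normalise summed atomic ASA to relative accessibility in \[0, 1\]. The
#' reference convention is a documented configuration knob: supplying a
#' different table (e.g. an empirical max-ASA set) rescales the
#' accessibility axis.
#'
#' @return named numeric vector over the 20 one-letter residue codes.
#' @export
max_reference_asa <- function() {
  c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223, G = 104,
    H = 224, I = 197, L = 201, K = 236, M = 224, F = 240, P = 159, S = 155,
    T = 172, W = 285, Y = 263, V = 174)
}

# ---- PDB parsing ------------------------------------------------------------

#' Read a template structure from PDB text
#'
#' Parses ATOM records of one chain (first model only for multi-model
#' files). Hydrogens, waters and heteroatoms are excluded; for alternate
#' locations the highest-occupancy atom is kept (ties: first altloc code in
#' alphabetical order). Residue order follows file order.
#'
#' @param pdb a file path, or PDB-format text (single string or character
#'   vector of lines).
#' @param chain chain identifier; default: the first chain with ATOM
#'   records.
#' @return an object of class `protein_structure`: list with `chain`,
#'   `atoms` (tibble: `residue` sequential 1-based index, `resno`, `aa`,
#'   `elety`, `element`, `x`, `y`, `z`, `occ`) and `residues` (tibble:
#'   `residue`, `resno`, `aa`).
#' @export
read_structure <- function(pdb, chain = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  atom_lines <- grep("^ATOM  |^ATOM\t", lines)
  for (ln in atom_lines) {
    xyz <- suppressWarnings(as.numeric(c(
      substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
      substr(lines[ln], 47, 54))))
    if (anyNA(xyz))
      abort(sprintf("malformed coordinate field on line %d", ln))
  }
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  pdbobj <- tryCatch(
    suppressWarnings({
      out <- utils::capture.output(
        p <- bio3d::read.pdb(tf, verbose = FALSE, rm.alt = FALSE))
      p
    }),
    error = function(e) abort(paste("PDB parse error:",
                                    conditionMessage(e))))
  at <- pdbobj$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[!is.na(at$chain) & at$chain == chain, , drop = FALSE]
  # standard residues only, no hydrogens
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  keep <- aa1 %in% AA_ALPHABET
  elem <- toupper(trimws(ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  keep <- keep & !(elem %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  aa1 <- aa1[keep]; elem <- elem[keep]
  if (nrow(at) == 0) abort(sprintf("no residues found for chain '%s'", chain))
  # alternate locations: highest occupancy, ties by altloc code
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert), at$elety)
  ord <- order(-occ, alt)
  first <- !duplicated(key[ord])
  sel <- sort(ord[first])
  at <- at[sel, , drop = FALSE]
  aa1 <- aa1[sel]; elem <- elem[sel]; occ <- occ[sel]
  rkey <- paste(at$resno, ifelse(is.na(at$insert), "", at$insert))
  residue <- match(rkey, unique(rkey))
  atoms <- tibble(residue = as.integer(residue), resno = at$resno, aa = aa1,
                  elety = trimws(at$elety), element = elem,
                  x = at$x, y = at$y, z = at$z, occ = occ)
  residues <- dplyr::distinct(atoms, .data$residue, .data$resno, .data$aa)
  structure(list(chain = chain, atoms = atoms, residues = residues),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Protein structure: chain %s, %d residues, %d atoms\n",
              x$chain, nrow(x$residues), nrow(x$atoms)))
  cat(structure_sequence(x), "\n")
  invisible(x)
}

#' One-letter sequence of a parsed structure
#' @param s a `protein_structure`.
#' @return single string.
#' @export
structure_sequence <- function(s) {
  paste(s$residues$aa, collapse = "")
}

# ---- Shrake-Rupley ASA ------------------------------------------------------

# deterministic golden-section spiral point set on the unit sphere
golden_spiral_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# intrinsic molecular frame (orthonormal, proper): axis 1 points from the
# centroid to the first atom, axis 2 is the Gram-Schmidt residual of the
# first non-collinear atom, axis 3 their cross product. Expressing the
# sphere points in this frame makes areas exactly invariant under
# rigid-body motion (for non-degenerate geometry); degenerate cases fall
# back to the laboratory frame.
molecular_frame <- function(coords) {
  eye <- diag(3)
  if (nrow(coords) < 2) return(eye)
  ctr <- colMeans(coords)
  v1 <- coords[1, ] - ctr
  if (sqrt(sum(v1^2)) < 1e-8) return(eye)
  v1 <- v1 / sqrt(sum(v1^2))
  v2 <- NULL
  for (k in 2:nrow(coords)) {
    w <- coords[k, ] - ctr
    w <- w - sum(w * v1) * v1
    if (sqrt(sum(w^2)) > 1e-6) { v2 <- w / sqrt(sum(w^2)); break }
  }
  if (is.null(v2)) return(eye)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

#' Per-atom accessible surface area (Shrake-Rupley)
#'
#' Places a deterministic golden-section spiral of test points on each
#' atom's solvent-expanded sphere (radius = van der Waals + probe) and
#' counts the points not buried inside any neighbouring expanded sphere:
#' `area = exposed fraction * 4 * pi * (r_vdw + probe)^2`. The fixed point
#' set makes areas exactly reproducible, and the points are expressed in an
#' intrinsic molecular frame so that areas are invariant under rigid-body
#' motion of the coordinates (up to floating point, for non-degenerate
#' geometries).
#'
#' @param s a `protein_structure`.
#' @param probe_radius probe radius in Angstroms (default 1.4, water).
#' @param n_points number of test points per atom (>= 92; default 960, at
#'   which an isolated sphere is exact to well under 1%).
#' @param vdw_radii named element-to-radius table.
#' @return numeric vector of areas (A^2), one per atom, in atom order.
#' @export
atom_asa <- function(s, probe_radius = 1.4, n_points = 960,
                     vdw_radii = vdw_radii_default()) {
  stopifnot(inherits(s, "protein_structure"),
            probe_radius > 0, n_points >= 92)
  a <- s$atoms
  radii <- vdw_radii[a$element]
  if (anyNA(radii)) {
    bad <- which(is.na(radii))
    abort(sprintf("no van der Waals radius for element(s): %s (atom rows %s)",
                  paste(unique(a$element[bad]), collapse = ", "),
                  paste(head(bad, 5), collapse = ", ")))
  }
  coords <- cbind(a$x, a$y, a$z)
  if (any(!is.finite(coords))) abort("non-finite atom coordinates")
  R <- as.numeric(radii) + probe_radius
  pts <- golden_spiral_points(n_points) %*% t(molecular_frame(coords))
  n_atoms <- nrow(coords)
  area <- numeric(n_atoms)
  tol <- 1e-9
  for (i in seq_len(n_atoms)) {
    d2 <- colSums((t(coords) - coords[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n_atoms) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- (p[, 1] - coords[j, 1])^2 + (p[, 2] - coords[j, 2])^2 +
        (p[, 3] - coords[j, 3])^2
      exposed <- exposed & (dj > R[j]^2 + tol)
      if (!any(exposed)) break
    }
    area[i] <- mean(exposed) * 4 * pi * R[i]^2
  }
  area
}

#' Relative solvent accessibility per residue
#'
#' Sums atomic accessible surface area within each residue and divides by
#' the residue type's reference maximum, clamping to \[0, 1\] so the track is
#' a valid relative-accessibility axis. Missing atoms are tolerated (the sum
#' runs over the atoms present).
#'
#' @inheritParams atom_asa
#' @param reference_areas named per-residue-type maximum ASA table
#'   (default [max_reference_asa()]).
#' @return an accessibility track: tibble of class `accessibility_track`
#'   with columns `residue`, `resno`, `aa`, `acc`.
#' @export
residue_accessibility <- function(s, reference_areas = max_reference_asa(),
                                  probe_radius = 1.4, n_points = 960,
                                  vdw_radii = vdw_radii_default()) {
  missing_aa <- setdiff(unique(s$residues$aa), names(reference_areas))
  if (length(missing_aa) > 0)
    abort(sprintf("residue type(s) missing from reference table: %s",
                  paste(missing_aa, collapse = ", ")))
  area <- atom_asa(s, probe_radius, n_points, vdw_radii)
  per_res <- tapply(area, s$atoms$residue, sum)
  out <- s$residues
  out$acc <- pmin(1, pmax(0, as.numeric(per_res[as.character(out$residue)]) /
                               reference_areas[out$aa]))
  out <- as_tibble(out)
  class(out) <- c("accessibility_track", class(out))
  out
}

#' Write / read an accessibility track as tab-separated text
#'
#' Columns: residue index, residue type (one-letter), accessibility.
#'
#' @param track an accessibility track tibble.
#' @param path file path.
#' @export
write_track <- function(track, path) {
  df <- data.frame(residue = track$residue %||% seq_along(track$acc),
                   aa = track$aa, acc = track$acc)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @return `read_track()` returns an `accessibility_track` tibble.
#' @export
read_track <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  out <- tibble(residue = as.integer(df$residue), aa = df$aa,
                acc = as.numeric(df$acc))
  if (any(out$acc < 0 | out$acc > 1)) abort("accessibility outside [0, 1]")
  class(out) <- c("accessibility_track", class(out))
  out
}
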