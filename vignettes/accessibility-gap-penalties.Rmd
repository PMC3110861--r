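---
title: "Accessibility-dependent gap penalties: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accessibility-dependent gap penalties: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accalign)
```

## The problem and the model

In template-based comparative modeling the template's 3D structure is known
by definition, yet standard pairwise aligners ignore it when placing gaps.
Insertions and deletions survive evolution mostly on the protein surface:
binned over reference structural alignments, the odds that a residue is
aligned against a gap grow approximately exponentially with its relative
solvent accessibility, while a linear trend fits the same data clearly
worse. `accalign` turns that observation into a position-dependent
gap-opening penalty

$$G(a) \;=\; \beta\, e^{-\alpha a}, \qquad a \in [0,1],$$

with defaults $\alpha = 2.1$, $\beta = 32.8$ and extension penalty $1$ per
additional gapped position, on the scale of a BLOSUM62 matrix shifted by
+4 so all substitution scores are non-negative. A maximal gap run of
length $L$ costs $G + \mathrm{ext}\,(L-1)$; the first gapped position
carries only the opening (the convention is internal to the package — the
alternative of charging one extension on the first position is absorbed by
rescaling $\beta$).

Two accessibility conventions coexist deliberately:

* **statistics convention** — each residue aligned against a gap
  contributes its own accessibility (no averaging); this is what
  `gap_accessibilities()` emits and what the odds-ratio analysis bins;
* **penalty convention** — a deletion of template span $i..j$ is charged
  $G(\overline{a_{i..j}})$ (mean over the deleted residues, whose structure
  is known), and an insertion into the template is charged
  $G$ of the mean accessibility of the two flanking template residues
  (single flank at a terminus), because the inserted residues' structure is
  unknown.

The deletion rule makes the gap cost non-decomposable across columns, so
the dynamic program uses a generalized three-state recursion whose deletion
state maximises over all span starts ($O(n^2 m)$ worst case; a
`max_del_span` cap bounds it, off by default). All opening penalties are
precomputed before the recursion runs (flank averages as a vector, segment
averages via prefix sums). Tie-breaking is deterministic: match is
preferred over deletion over insertion, and extending a run over opening a
new one. With a constant track the method reduces *exactly* — identical
alignments, not just scores — to the affine aligner with
$\mathrm{open} = G(a_0)$, which is both a correctness check and the bridge
to the affine baseline ($\mathrm{open} = 13$, $\mathrm{ext} = 1$, the
optimum of the same scoring system against structural alignments).

Global alignment with penalised terminal gaps is the default, matching the
modeling use-case where the full template span must be accounted for; a
`free_ends` flag provides semi-global behaviour.

## Accessibility from structure

`atom_asa()` implements the Shrake–Rupley construction: test points on each
atom's solvent-expanded sphere (van der Waals radius + 1.4 Å probe), a
point counting as buried when it falls inside any neighbouring expanded
sphere. Three numerical choices matter:

* **Deterministic point set.** A golden-section spiral (default 960
  points) replaces random sampling, so areas are exactly reproducible; an
  isolated sphere is exact at any point count, and the two-sphere
  spherical-cap case is within 1% at 960 points.
* **Intrinsic frame.** The point cloud is expressed in a molecular frame
  built from the centroid, the first atom, and the first non-collinear
  atom. Because the frame co-rotates with the coordinates, accessibility is
  invariant under rigid-body motion to floating-point precision (a fixed
  laboratory-frame cloud would wobble by ~0.5% under rotation). Degenerate
  geometries (single atoms, collinear chains) fall back to the laboratory
  frame.
* **Boundary rule.** A test point exactly on a neighbour's surface counts
  as buried (tolerance $10^{-9}$), so coincident equal spheres report zero
  area rather than an arbitrary half.

Residue accessibility is the summed atomic area divided by a per-residue-type
maximum (the theoretical Gly-X-Gly extended-state values of Tien *et al.*
2013), clamped to $[0,1]$. The reference table is a configuration knob —
an empirical max-ASA set rescales the accessibility axis and hence the
effective steepness of $G$ — and `vdw_radii_default()` likewise. Missing
atoms are tolerated (the sum runs over atoms present); missing residues are
not, since the penalty needs a complete track over the aligned span.

## Gap statistics

`bin_gap_odds()` bins gap and residue accessibilities into width-0.05 bins
(half-open, top bin closed so $a = 1$ is in range) and reports
$g_i = N_i/\sum N$, $f_i = A_i/\sum A$ and the odds ratio $g_i/f_i$; bins
without residues have undefined odds and are flagged `NA` rather than
dropped silently. Bootstrap errors resample whole protein pairs with
replacement — the pair, not the residue, is the exchangeable unit, which
preserves within-pair correlation. Regression (`fit_odds_regression()`)
fits odds or $\ln$ odds on bin midpoints by ordinary least squares;
"residual error" is defined here as the root-mean-square residual in the
fitted space, a definition the package fixes explicitly because the
headline residuals of the motivating analysis cannot be recomputed without
its full dataset. Natural logarithms are used throughout. Whether residue
counts $A_i$ pool both proteins of a pair or one is controlled by which
tracks the caller supplies; both-sided counting is the default convention.

## Evaluation scores

Against a reference structural alignment: Q-score is the fraction of
reference residue pairs reproduced. An insertion segment (run of target
residues aligned against template gaps) is counted correct if it overlaps a
reference segment by at least one residue; an insertion point (the template
inter-residue position of such a run) is correct within a three-residue
window (±1 position). Each prediction is judged independently — two
predictions hitting one real segment are both true positives; no one-to-one
matching is imposed. The over/under-assignment plane is
$x = \ln(\mathrm{FP}/\mathrm{TP})$ (negative when correct assignments
dominate) and $y = \ln((\mathrm{TP}+\mathrm{FP})/N_\mathrm{real})$
(positive = over-assignment, zero = as many assigned as real). The sign
semantics of $y$ follow the over/under-assignment reading; infinite
sentinels ($\mathrm{TP} = 0 \Rightarrow x = +\infty$; no predictions
$\Rightarrow y = -\infty$) are reported explicitly, never dropped.

## Parameter fitting

`fit_gap_parameters()` is an honest brute-force grid search: align every
corpus pair at each $(\alpha, \beta)$, score against the references, take
the pooled objective (total correct pairs over total reference pairs; a
per-pair mean is available), then refine on a window around the coarse
optimum (defaults: coarse $1 \le \alpha, \beta \le 39$ step 1; fine step
0.1 in a $\pm 1 \times \pm 2$ window). Ties break towards the smallest
$\alpha$, then $\beta$, so results are order-independent and deterministic.

## The simulator: what it emulates, and what it does not

`simulate_pair()` generates the benchmark conditions used by the test
suite: template length 150, per-residue accessibilities i.i.d. uniform (a
Beta option exists), substitutions at rate 0.65 drawn from a
BLOSUM62-conditional kernel $p(b\,|\,a) \propto e^{\lambda S(a,b)}$ with
$\lambda = \ln 2/2$ (the matrix's half-bit unit), indel events Poisson at
0.02 per residue split evenly between deletions and insertions, geometric
lengths (mean 3), and gap placement following the empirical law: deletion
spans weighted by $e^{1.55 \sum a_i}$ (so each residue's inclusion odds
scale as $e^{1.55 a_i}$, and the binned log-odds of the emitted gap
accessibilities recover the slope), insertions at inter-residue positions
weighted by $e^{1.55 \bar a_\mathrm{flank}}$. The conservative substitution
kernel matters: uniform random replacement makes mismatch columns score
like noise, below the cost of a gap detour, which no real homologous pair
resembles. The expected identity (~35%) sits in the twilight zone the
method targets.

What the simulator does **not** emulate is just as important for reading
the test results. Real accessibility tracks are autocorrelated along the
chain (loops and cores come in blocks), gaps segregate near-deterministically
into loops jointly with locally weakened conservation, and reference gap
placement comes from structure superposition rather than from the
generative process itself. Under the site-independent slope-1.55 law the
exploitable placement signal is worth about $1.55$ natural-log units
(≈ 4.5 score units) across the accessibility range, whereas
$G(a) = 32.8\,e^{-2.1 a}$ swings by ≈ 29 score units — an implied prior
far steeper than the simulated law. Consequently, on this synthetic
benchmark the grid fit recovers a *shallower* optimum (α near the low edge
of the grid, β ≈ 20; its Q-score does exceed the affine baseline's),
while the published steep parameter set (2.1, 32.8) scores slightly below
the affine optimum. The corresponding acceptance check records that
ordering as measured. Passing the remaining tests therefore demonstrates
the correctness of the machinery (exact oracle equivalence, reductions,
closed forms, law recovery), not that the steep penalty wins on data this
simple; its advantage on real structural alignments rides on the
correlated loop/core structure listed above.

## Progressive MSA (reduced scope)

The multiple aligner is a deliberately minimal convenience: pairwise
identities from baseline affine alignments, Kimura distances
$-\ln(1 - p - p^2/5)$ (identities below the formula's domain are assigned a
capped distance of 10, in the tradition of progressive aligners), a UPGMA
guide tree with ties broken by identifier order, and leaves-to-root merging
under "once a gap, always a gap". When a structure-bearing sequence
participates, the accessibility-dependent penalty is used — exactly (via
the pairwise engines) at leaf joins, and through position-specific openings
from the first track-bearing member's flank averages at profile joins,
where columns are scored by the mean pairwise substitution score with gaps
contributing zero. Iterative refinement, consistency scoring and profile
HMMs are out of scope.

## Degenerate inputs and numerics

Alignment requires non-empty sequences over the 20-residue alphabet;
unknown symbols are reported with their position. Scores are doubles;
score consistency between the DP accumulator and a recomputation from the
emitted columns is maintained to $10^{-9}$. Bin membership uses half-open
intervals with a closed top bin, so edge values are deterministic. The
bootstrap and the simulator take explicit seeds and leave the caller's RNG
state untouched.

## Known limitations

* The accessibility scale depends on the max-ASA reference convention;
  fitted $(\alpha, \beta)$ values are only meaningful relative to the
  table and substitution-matrix shift they were fitted with.
* The generalized deletion recursion is $O(n^2 m)$; for very long
  templates set `max_del_span` (deletions longer than ~30 residues are
  vanishingly rare in practice).
* Insertion openings use flank averages only — no model of the inserted
  residues' own (unknown) structure.
* The simulator's i.i.d. accessibility field understates the spatial
  coherence of real surface patches; conclusions about the *relative*
  merit of steep accessibility penalties on real data cannot be drawn
  from it (see above).
* NMR multi-model files use model 1 only; ASA is computed on the single
  conformer.
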