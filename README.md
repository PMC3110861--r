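# accalign

Pairwise global alignment of a *target* amino acid sequence against a
*template* of known 3D structure, with a gap-opening penalty that depends on
the template's residue solvent accessibility. The package is aimed at
comparative modeling, where the residue–residue correspondence between
template and target decides where loops and indels end up in the model, and
where misplacing a gap by a few residues can bury an insertion in the
protein core.

## The model

Insertions and deletions accumulate on the protein surface: across reference
structural alignments, the odds of finding a residue aligned against a gap
grow roughly exponentially with its relative solvent accessibility
(`ln(odds) ≈ 1.55 · acc − 0.50`). The gap-opening penalty is taken as the
inverse of that trend,

```
G(acc) = β · exp(−α · acc),          α = 2.1,  β = 32.8,  ext = 1
```

in the units of a BLOSUM62 matrix shifted to non-negative entries. Opening a
gap in a buried stretch costs `G(0) = β`; at a fully exposed position it
costs only `β·e^(−α)` ≈ 4. A deletion of template residues `i..j` opens at
`G` of the mean accessibility over the span (the dynamic program explores
all span ends, so the segment average is exact); an insertion into the
template opens at `G` of the mean accessibility of the two flanking
residues. Gap runs extend at `ext` per additional position. The classical
affine penalty (`open = 13`, `ext = 1`, the optimum for shifted BLOSUM62
against structural alignments) is the baseline.

Relative accessibility comes from a Shrake–Rupley accessible-surface-area
calculation (deterministic golden-spiral test points, probe 1.4 Å)
normalised by per-residue-type maximum areas and clamped to [0, 1].

Around the aligner the package provides the supporting analyses: binned gap
odds ratios with bootstrap errors and linear/log-linear regressions;
alignment evaluation against reference structural alignments (Q-score,
insertion segment/point precision `I_s`/`I_p`, and the over/under-assignment
coordinates `x = ln(FP/TP)`, `y = ln(assigned/real)`); brute-force grid
fitting of `(α, β)`; a minimal progressive MSA with a Kimura-distance UPGMA
guide tree; and a synthetic template/target simulator with
accessibility-biased indel placement for benchmarking.

## Worked example

```r
library(accalign)

# a simulated template/target pair in the twilight zone (~35% identity),
# with indels placed preferentially at exposed template positions
p <- simulate_pair(n = 60, seed = 14)

aln <- align_accessibility(p$template, p$track, p$target)
aln
#> Pairwise global alignment (accessibility), score 320.9648
#> T HYCMRYCIWSFQLAYYLTMPPEVVCRKPQILRGVGHYD-KEHE-IMHHSVFVGDTSSIPQ
#> Q YGPMEWCYWHYQLSYRCSMPPH---RISQILNGA-HYEGEVHKDILKSSMSVGDTKSTTA
#> ...

score_alignment(aln, p$reference)
#>       q   i_s   i_p   x_s   y_s  ...
#> 1 0.821   0.5   0.5     0 0.693  ...

aff <- align_affine(p$template, p$target)   # open = 13, ext = 1
score_alignment(aff, p$reference)
#>       q   i_s   i_p   x_s  y_s  ...
#> 1 0.804     0     0   Inf    0  ...
```

Here the accessibility-dependent penalty recovers more of the reference
residue pairs (Q-score 0.82 vs 0.80) and places one of the two gap runs
correctly (`I_s = 0.5` vs 0; `x_s = 0` means correct and incorrect
assignments balance, and `y_s = ln 2` flags the over-assignment of one
extra run).

Accessibility from a structure, and the gap statistics:

```r
s <- read_structure("template.pdb", chain = "A")
track <- residue_accessibility(s)     # tibble: residue, resno, aa, acc

corpus <- simulate_corpus(50, seed = 7)
gaps <- unlist(lapply(corpus, function(p)
  gap_accessibilities(p$reference, track_a = p$track)))
res <- unlist(lapply(corpus, function(p) p$track))
bt <- bin_gap_odds(gaps, res, w = 0.1)
fit_odds_regression(bt, "log-linear")
#> log-linear fit over 10 bins: ln(odds) = 1.3386 * acc + -0.7678 (rms residual 0.1648)
```

The recovered slope (1.34 on 50 pairs) tracks the generating law's 1.55;
`autoplot(bt)` draws the odds curve and `tidy()`/`glance()` give the fit as
tibbles. A thin command-line front end (`exec/accalign`) exposes
`track`, `align`, `eval`, `simulate`, `fit` and `msa` subcommands over the
same functions.

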