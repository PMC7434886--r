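---
title: "Methods: dyad profiling, tandem GAT spacing, and nucleosome motif geometry"
author: "nucpioneer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyad profiling, tandem GAT spacing, and nucleosome motif geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`nucpioneer` analyses how a pioneer transcription factor of the GATA
family meets its binding sites in chromatin. It implements three linked
computations:

1. **Motif-anchored dyad profiling.** Mono-nucleosome MNase fragments are
   reduced to their midpoints, which estimate nucleosome dyads. At each
   GATA-bound locus the WGATAR consensus hit (W = A/T, R = A/G) closest to
   the peak summit anchors a coordinate frame, and midpoints are counted
   by offset from the motif center, pooled per locus class, normalized
   against a sonicated control, and summarized as a log2 heatmap over
   ±75 bp.
2. **Tandem 5'-GAT-3' spacing statistics.** GATA zinc fingers read the
   5'-GAT-3' half-site, so 200-bp peak-center windows are scanned for
   pairs of GAT trinucleotides at spacers 0–10 bp, same-strand
   (GAT·N~x~·GAT) or convergent on opposite strands (GAT·N~x~·ATC).
   Observed counts are compared against a closed-form iid expectation, a
   Monte Carlo null built from random genomic windows, and between locus
   classes by 2×2 chi-squared contrasts.
3. **Nucleosome rotational geometry.** Positions on nucleosomal DNA are
   expressed as superhelical location (SHL), helical turns from the dyad.
   A rotational-phase model classifies each GAT center as presenting its
   major groove to solvent or to the histone surface, classifies tandem
   pairs (consecutive exposed grooves vs. partially or fully buried), and
   designs 145-bp nucleosome constructs: motif insertions around SHL2 and
   SHL5, a tandem-layout construct with GATs at SHL5, SHL5.5 and SHL6.5,
   and single-GAT knockouts.

The three locus classes carry the biology: G1 loci are remodeled
productively after factor expression, G2 loci are pre-accessible, G3 loci
bind the factor but stay closed.

# Coordinate and counting conventions

* All coordinates are 0-based, half-open (native BED); 1-based numbers
  never enter data structures.
* A fragment `[start, end)` has midpoint `start + floor((len − 1)/2)`;
  the even-length tie is broken to the left-of-center base so results are
  reproducible. The tie-break is not stated by any convention we know of;
  a fixed deterministic rule is the requirement.
* Fragments outside a mono-nucleosome band of 120–200 bp are discarded
  before profiling. Size selection is experimental (gel-based) and has no
  published numeric bounds; the band is a documented, configurable
  default around the canonical 147 bp.
* Tandem-pair scanning reads only the plus strand, for exactly three
  patterns: GAT·N~x~·GAT and ATC·N~x~·ATC (same-strand class, "GG") and
  GAT·N~x~·ATC (convergent class, "GA"). This pattern set is closed under
  reverse complement, so every physical pair is counted exactly once and
  the counts are strand-symmetric. The divergent arrangement ATC·N~x~·GAT
  is a distinct physical geometry and is excluded by default
  (`include_divergent = TRUE` enables it for exploration). Overlapping
  and nested matches all count; per-locus presence/absence feeds the
  chi-squared contrasts, since per-pair counts would let a single
  repeat-rich locus dominate.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| profile half-width `K` | 150 | bp | covers a nucleosome on either side of the motif; the heatmap span (±75) is fixed by the method, the metaplot span is presentation |
| heatmap half-width | 75 | bp | dyads within ±75 bp place the motif on that nucleosome |
| normalization pseudocount | 0.5 | counts | keeps ratios finite at sparse offsets; applied in count space per the normalization formula below |
| smoothing sigma | 15 | bp | browser-style display of nucleosome-scale structure; `0` disables |
| mono-nucleosome band | 120–200 | bp | documented guess around 147 bp |
| peak window | 200 | bp | analysis window centered on the peak |
| max spacer | 10 | bp | one helical turn separates consecutive grooves; 0–10 spans it |
| helical period | 10.4 | bp/turn | nucleosomal twist varies (~10.0–10.6); a parameter, not a constant |
| wrap length / dyad index | 145 / 72 | bp | 145-bp template with a centered dyad |
| Monte Carlo replicates | ≥ 99 (1000 typical) | – | resolution of the empirical p floor, `1/(R+1)` |

Normalization: with pseudocount ε,
`ratio_i = ((s_i + ε)/Σ(s + ε)) / ((c_i + ε)/Σ(c + ε))`. Because ε is
added in count space, the ratio is exactly depth-invariant only at
ε = 0; at the default ε = 0.5 the perturbation is below 3% at the depths
used here. Both profiles all-zero is a degenerate-input error.

Pooling: metaplots pool raw counts across loci by default. A
`per_locus = TRUE` option first normalizes each locus to unit mass so
deep loci do not dominate; both behaviors are supported because the
aggregation convention of published metaplots is rarely stated.

# The geometry model

`shl_of(p) = (p − dyad_index)/period` is linear in position. The
rotational phase is the fractional part of |SHL|; a center is called
solvent-exposed when `|phase − 0.5| < 0.25` (half-integer SHLs) and
histone-facing otherwise, with the boundary assigned to the histone face
— a deterministic tie-break, chosen because the known exposed positions
(SHL5.5, SHL6.5) and buried positions (SHL5, integer SHLs) sit well away
from it. A tandem pair is `dual_exposed_consecutive` when both GAT
centers are exposed and their SHL separation is 0.7–1.3 turns; a 6-bp
spacer (centers 9 bp apart, ~0.87 turns at 10.4 bp/turn) satisfies this
for any period in 10.0–10.6 when anchored at SHL5.5, which is why that
spacing uniquely supports simultaneous engagement of both zinc fingers
in consecutive major grooves. Motif "position" is always the center base
of the GAT trinucleotide — an unambiguous single-base anchor.

## Construct design

`design_insertion()` overwrites template bases with the 11-bp GATA motif
AGATA·N·CATCT so the first GAT center lands on the base pair nearest the
target SHL (N keeps the template base). The rotational series (suffixes
a–e) steps the target by 0.2 SHL (~2 bp), sampling one helical turn.
`knockout_gat()` substitutes the middle base of a GAT/ATC (preference
C > G > T > A) subject to not recreating a GAT/ATC within 4 bp — the
minimal-edit rule; the substitutions used in published mutant constructs
are defined by their supplementary sequences and may differ.

## The synthetic 145-bp template

The package does not embed any published template sequence.
`make_widom601_synthetic()` builds a deterministic stand-in for a
strongly positioning 145-bp template: a seeded random sequence scrubbed
of all GAT/ATC and WGATAR occurrences, then given exactly three
intrinsic GAT elements (guard-flanked so junctions cannot create
additional sites) at geometry-relevant positions, including one whose
center sits in the SHL6.5 major groove. `design_shl5e()` adds GATs at
SHL5 and SHL5.5 on top of it, reproducing the tandem layout in which the
SHL5.5 and SHL6.5 GATs are spaced by 6 bp in consecutive exposed grooves
while the SHL5 GAT faces the histone surface. These constructs reproduce
GAT content and layout, not base composition or positioning strength,
and are labelled synthetic throughout.

# The Monte Carlo null

The observed statistic is the total tandem-pair count over all peak
windows. Each replicate re-draws the same number of windows uniformly
over all placements that fit a chromosome, contain no N, and (by
default) avoid the peak windows, mimicking coordinate shuffling against
an exclusion set. The empirical p-value is
`(1 + #{null ≥ observed})/(1 + R)`, never zero, exactly 1 for a minimal
observation. When the "peaks" are themselves random windows — the
calibration setting — exclusion would remove the observed windows'
positions from the null space and break exchangeability, so
`exclude_peaks = FALSE` is used there; with it, the p-value is exactly
super-uniform by symmetry. The sampler is genome-uniform; it does not
match windows by chromosome or GC content, which real-genome
applications may want.

# What the generator emulates, and what it does not

`sim_config()` defaults encode the study conditions: 200-bp windows; G1
windows carry a convergent GAT–{3,4}bp–ATC tandem, G3 a same-strand
GAT–6bp–GAT tandem, G2 a single WGATAR; dyad offsets are Gaussian
mixtures at ±21 bp (sd 3) for G1 before expression — SHL2 at 10.4
bp/turn — and ±130 bp (sd 15) after; uniform-excluding-±80 bp for G2;
uniform before and ±52 bp (sd 3, SHL5) after for G3; fragment lengths
147 ± 10 bp truncated to the band; sonicated controls uniform over the
window ± 100 bp. Offsets were chosen once by converting the reported
"two"/"five helical turns" through the geometry module's period, and
"beyond 100 bp" to a ±130 mixture. Gaussian mixtures are the minimal
stand-in for reported modal positions with controllable sharpness.

The generator does **not** emulate MNase sequence bias, linker
histones, copy-number or mappability structure, GC-content
heterogeneity, read-level errors, or inter-locus depth variation.
Passing tests therefore demonstrate that the estimators recover planted
structure under clean sampling noise — not that they are robust to the
systematic biases of real capture MNase-seq.

Determinism: the whole simulation is a pure function of the
configuration. Every stage draws from `derive_seed(seed, stage_name)`,
so stages reproduce independently of execution order, and all derived
seeds stay inside R's 32-bit integer range.

# Numerical choices and degenerate inputs

* Gaussian smoothing truncates the kernel at 3σ and renormalizes per
  source position at the boundaries, so total mass is conserved to
  rounding error; σ = 0 is the identity.
* Chi-squared contrasts use the uncorrected Pearson form, df = 1 — at
  the effect sizes of interest the continuity correction is immaterial,
  but the choice is fixed for reproducibility. Degenerate 2×2 margins
  are an error for class contrasts and a warned `p = 1` for per-spacer
  scans (where empty cells occur routinely).
* Ties in closest-motif selection go to the smaller start; ties in the
  even-length midpoint go left; the groove-face boundary phase goes to
  the histone face. All tie-breaks are deterministic and documented.
* Peak windows extending past a chromosome end are clipped with a
  warning; a window shorter than 6 bp scans to an empty hit list rather
  than an error.

# Problem sizes

The test suite and the acceptance script run on synthetic data sized for
a laptop-class single core: a 1 Mb genome with 300 peaks and 1000 Monte
Carlo replicates for enrichment (~10 s), 100 loci × 200 fragments for
profile recovery, 1000 random 200-mers for scanning oracles, and 200
repetitions × 99 replicates for p-value calibration. These sizes were
chosen so each statistical check has comfortable power at 4σ-style
bounds while the full suite completes in about a minute.

# Known limitations

* The anchor for "strongest ChIP-seq signal" is the summit field of the
  peak table; the package does not recompute ChIP coverage.
* The published smoothing algorithm used for browser tracks of
  nucleosome positions is replaced by a generic Gaussian smoother; only
  figure cosmetics depend on it.
* The in-vivo frequency tables and chi-squared statistics from the
  original MDA-MB-231 data require the deposited sequencing data and are
  out of scope; the synthetic pipeline checks recover the same
  qualitative structure (spacer-6 same-strand enrichment in G3,
  spacer-3/4 convergent enrichment in G1) at desk scale.
* The synthetic template stands in for the published 145-bp positioning
  sequence; analyses that depend on the real sequence's thermodynamics
  or exact base identities must supply it as a FASTA.
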