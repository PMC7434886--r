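# nucpioneer

Nucleosome dyad profiling and tandem GAT motif geometry at
pioneer-factor binding sites.

Pioneer transcription factors such as GATA3 can engage their motifs on
nucleosomal DNA. Whether binding opens the locus, finds it already
open, or changes nothing depends on where the motif sits on the
nucleosome and how its 5'-GAT-3' half-sites are spaced and oriented.
`nucpioneer` provides the computational side of that analysis for
genomics and chromatin-biochemistry researchers:

* **Dyad profiling** — mono-nucleosome MNase fragment midpoints
  (dyads) counted by offset from the WGATAR motif (W = A/T, R = A/G)
  closest to each peak summit, pooled per locus class (G1 productively
  remodeled / G2 pre-accessible / G3 non-productive), normalized by a
  sonicated control, and rendered as a log2 heatmap over ±75 bp.
* **Tandem GAT spacing statistics** — same-strand (GAT·N<sub>x</sub>·GAT)
  and convergent (GAT·N<sub>x</sub>·ATC) pairs at spacers 0–10 bp in
  200-bp peak windows, with a closed-form iid expectation (same-strand
  pairs are exactly twice as probable as convergent ones under a uniform
  base model), a Monte Carlo null from random genomic windows, and
  chi-squared class contrasts.
* **Nucleosome rotational geometry** — superhelical location
  (SHL = bp from the dyad ÷ helical period), rotational phase, and
  groove-face calls (half-integer SHLs solvent-exposed, integer SHLs
  histone-facing); classification of tandem pairs as consecutive
  exposed major grooves vs. buried; and design of 145-bp nucleosome
  constructs (SHL2a–e/SHL5a–e insertion series, a tandem-layout
  construct with GATs at SHL5/SHL5.5/SHL6.5, single-GAT knockouts).
* **A seeded synthetic-data generator** producing genomes, class-labeled
  peaks, fragments and controls with the statistical structure above, so
  the entire pipeline is testable without external data.

See `vignettes/nucleosome-motif-geometry.Rmd` for the model,
conventions, parameter defaults and limitations.

## Worked example

The numbered drivers under `analysis/` run the full workflow on a
simulated study (1 Mb genome, 300 peaks, 200 fragments per locus and
condition) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_dyad_profiles.R
Rscript analysis/03_motif_spacing.R
Rscript analysis/04_nucleosome_geometry.R
```

`02_dyad_profiles.R` prints the modal dyad offset per class and
condition:

```
G1 pre  n_loci=100  modal dyad offset +20 bp
G2 pre  n_loci=100  modal dyad offset +83 bp
G3 pre  n_loci=100  modal dyad offset +20 bp
G1 post n_loci=100  modal dyad offset +128 bp
G2 post n_loci=100  modal dyad offset +83 bp
G3 post n_loci=100  modal dyad offset -50 bp
```

G1 loci start with dyads ~two helical turns (±21 bp, SHL2) from the
motif and are pushed beyond 100 bp after factor expression; G2 dyads
stay away from the motif throughout; G3 dyads, unpositioned at first,
settle ~five turns out (±52 bp, SHL5). `03_motif_spacing.R` recovers
the planted spacing structure and its enrichment:

```
G1 GA: top spacer 4 (fold 6.2, p 6.6e-12)
G3 GG: top spacer 6 (fold 4.6, p 2.9e-23)
Monte Carlo enrichment: observed 782, null mean 464.1, p 0.000999
G3 vs G2 (GG): chi2 45.4, p 1.61e-11
G1 vs G2 (GA): chi2 81.7, p 1.59e-19
```

The convergent 3–4-bp spacing marks productively remodeled (G1) loci;
the same-strand 6-bp spacing marks non-productive (G3) loci, and the
Monte Carlo p-value (floor 1/1001 at 1000 replicates) shows tandem GATs
concentrated at peak centers relative to random windows.
`04_nucleosome_geometry.R` classifies every planted G3 tandem
(spacer 6, anchored at SHL5.5) as `dual_exposed_consecutive` — two
solvent-exposed major grooves 0.87 turns apart — while the G1 spacer-3/4
pairs place one GAT against the histone surface, and prints the
construct layout:

```
SHL5e GAT positions (nearest half-integer SHL): -3, 2, 5, 5.5, 6.5
SHL5.5-SHL6.5 spacer: 6 bp
```

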