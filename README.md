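# ifnsynergy

Downstream analysis of interferon-induced STAT1 binding: distinguishing
GAF from ISGF3 binding events, linking them to gene regulation, and
quantifying the synergy between the two transcription factors.

## The scientific problem

Type I interferon (IFN-β) activates two STAT1-containing transcription
factors. ISGF3 (STAT1–STAT2–IRF9) binds interferon-stimulated response
elements (ISRE, consensus `AGTTTCN{2}TTTC`); GAF (the STAT1 homodimer)
binds gamma-activated sequences (GAS, consensus `TTCN{2,4}GAA`). The two
factors differ in binding kinetics (GAF early, ISGF3 late), in dose
sensitivity (GAF binding requires high-dose IFN-β), and — strikingly — in
transcriptional consequence: in epithelial cells GAF binding alone does
not induce nearby genes, yet the combination of GAF and ISGF3 activation
super-additively enhances a subset of interferon-stimulated genes (ISGs).

This package implements the analysis pipeline that establishes and
quantifies those distinctions from standard genomics readouts:

1. **Motif classification** — peaks are scanned on both strands with
   consensus models (GAS, the Irf1-promoter variant GAS
   `GATTTCCCCGAATG`, and ISRE; user PWMs optionally) and categorized
   GAS / ISRE / BOTH / NO_MOTIF from family presence.
2. **Inducible peaks and kinetics** — a peak is inducible when its
   pseudocounted signal ratio over basal reaches 2-fold in ≥ 2
   timepoints; row-scaled log2 time courses are k-means clustered with
   silhouette-selected k, labels canonicalized early = 1.
3. **Dose sensitivity** — one-sided Wilcoxon rank-sum tests of high- vs
   low-dose induced log2 fold-changes per motif category.
4. **Peak–gene linking** — each peak is linked to the closest expressed
   gene by TSS distance; promoter = strand-aware −1000..+100 bp; one
   link per gene with promoter precedence, then nearest.
5. **Expression analysis** — CPM/RPKM with TMM library-size adjustment,
   a 2-CPM expressed filter, ISG calling at FDR < 0.05 (Welch t on
   log2(RPKM+1), BH-adjusted) and fold-change > 2, induced fractions per
   linked category.
6. **Enhancement score** — for the mixing experiment (low-dose IFN-β,
   low-dose IFN-γ, their mixture), per-gene synergy is

   `ES = (RPKM_mixed + 1) / ((RPKM_beta + 1) + (RPKM_gamma + 1))`

   with 1-RPKM pseudocounts per term, so an additive response scores ≈ 1
   and ES > 1 is supra-additive. Top/bottom quartiles (ceiling(n/4)
   genes each) are compared for basal expression, promoter GC content
   (−300..+300 bp) and promoter-peak presence (Fisher exact).

A synthetic-data generator (`simulate_dataset()`) plants all of this
structure — motif categories in a motif-free background genome, early/late
kinetic classes, dose-gated GAS binding, ISG induction, and multiplicative
synergy — with full ground-truth tables, so every stage is testable end to
end without any download.

## Worked example

```r
library(ifnsynergy)
sim <- simulate_dataset(simulation_params(n_peaks = 120, n_background_peaks = 25,
  n_genes = 600, n_isgs = 60, n_multipeak_genes = 12, seed = 42))
run <- run_ifn_pipeline(sim)
summary(run)
```

```
Interferon STAT1 pipeline run
  peaks: 145 input, 120 inducible
  categories: BOTH=26, GAS=47, ISRE=33, NO_MOTIF=14
  kinetic clusters: k = 2 (sizes 54, 66)
  expressed genes: 597; ISGs: 60
  uniquely linked genes: 94 (28 promoter, 66 distal)
  enhancement quartiles: 15 genes per tail
  induced > 2-fold among BOTH-linked genes: 8/22 (36%)
  induced > 2-fold among GAS-linked genes: 0/42 (0%)
  induced > 2-fold among ISRE-linked genes: 15/30 (50%)
  dose gate: GAS high>low p = 3.46e-17; ISRE high>low p = 0.454
Top vs bottom enhancement quartiles
  basal RPKM: median top 51.35 vs bottom 499.38, rank-sum p = 3.39e-06
  promoter GC: median top 0.405 vs bottom 0.607, rank-sum p = 3.33e-06
  promoter peak: 5/15 (33%) top vs 2/15 (13%) bottom, Fisher p = 0.39
```

Reading the output: of 145 input peaks, 120 pass the two-fold/two-timepoint
induction rule; their motif categories and two kinetic clusters (cluster 1
early/GAF-like, cluster 2 late/ISGF3-like) follow. Genes linked to
GAS-only peaks show no induction (0%) while ISRE- and BOTH-linked genes
are induced (50%, 36%) — the epithelial-mode hallmark — and GAS binding is
dose-gated (high ≫ low dose, p ≈ 3e-17) while ISRE binding is not
(p ≈ 0.45). Top-enhancement genes have lower basal expression and lower
promoter GC than bottom-enhancement genes.

`evaluate_against_truth(run, sim)` compares every stage against the
planted labels; on this dataset all recovery metrics equal 1.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ifnsynergy-cli.R` (subcommands `simulate`,
`classify-peaks`, `inducible`, `link`, `isg`, `run-all`).

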