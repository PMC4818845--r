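---
title: "Linking transposable-element content to chromatin-contact frequency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking transposable-element content to chromatin-contact frequency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alucontact)
```

## The question and the model

Hi-C experiments summarise the 3D organisation of a genome as normalised
contact frequencies between pairs of fixed-size bins (here 40 kb).
Megabase-scale topological domains concentrate contacts internally, and
contacts *within* a domain are the ones most likely to reflect genuine
regulatory interactions — enhancer–promoter loops above all. This package
asks a sequence-composition question of those contacts: do loci with high
intra-domain contact frequency carry more transposable-element sequence, and
if so, which families, and with what consequences for GC content, CpG supply,
methylation and regulatory-element density?

The analysis is deliberately simple and transparent:

1. **Stratify and threshold.** A pair is *intra-domain* only if both 40-kb
   bins lie wholly inside one domain. The mean frequency of non-intra pairs
   is the lower retention threshold — inter-domain contacts are modelled as
   background noise, so intra pairs weaker than that background are
   uninformative. The upper threshold is the left edge of the first empty
   width-1 window of the intra frequency histogram: beyond it contacts are
   scattered singletons, treated as outliers. Retention is `lower ≤ f <
   upper`; the lower bound is inclusive, and boundary pairs (a bin straddling
   a domain edge) are excluded from both strata.
2. **Per-pair TE metrics.** For a selector (family, class, or Alu subfamily
   group) the pair region (80 kb) yields coverage (merged covered bases /
   80 kb), an enrichment score (copy count by the midpoint rule), and density
   — count divided by the maximum possible number of same-family copies,
   `80 kb / mean family length`. Density, not coverage, is the headline
   metric: it normalises families of very different copy lengths onto one
   scale. Copy membership uses midpoints so a copy on a bin edge is counted
   exactly once; coverage clips to the region.
3. **Binned correlation.** Retained pairs are grouped into 50 equal-width
   frequency bins; per-bin mean frequency and mean metric give one summary
   point, and the Pearson r over these points (two-sided t, df = n − 2) is
   the association measure. 20 and 100 bins serve as robustness checks; the
   per-bin mean frequency (not the bin midpoint) is the x value so sparse
   bins are placed where their pairs actually sit. Empty bins are dropped,
   never imputed. Correlations between strata are compared with the Fisher z
   transform.
4. **Origin partition.** Each pair's 80 kb is split into Alu,
   SINE/non-Alu and non-SINE bases, with precedence Alu > SINE/non-Alu >
   non-SINE where annotations overlap; a CpG site belongs to the class of its
   C position. Per class the pipeline counts bases, G/C bases, CpG sites and
   methylated CpG sites, giving GC contributions (which sum exactly to the
   background GC), CpG densities (per G/C base) and methylation densities
   (per CpG site). `N` bases count toward length but never toward GC.
5. **Regulatory elements.** Active enhancers are the merged per-base
   intersection of H3K4me1 and H3K27ac peaks; active TSSs are
   H3K4me3-supported transcription starts, one per gene (most supporting
   peaks, then largest summed signal, then 5′-most). Element counts per pair
   use the same midpoint rule as TE counts. Genome bins are ranked by Alu
   coverage into five equal-count groups; per-group mean element counts are
   correlated against mean coverage. Enhancers whose reference point (summit,
   else midpoint) lies in an Alu copy are *Alu-derived*; the Alu coverage of
   40-kb windows around them is compared with seeded random genome windows by
   a one-sided binomial tail (success = window above the background mean,
   null rate = the background's own exceedance fraction), with a permutation
   test on the window-mean as a cross-check. Peak sets from different sources
   are matched as "the same element" by mutual-nearest reference points
   closer than 250 bp.

## The synthetic-data generator

The real inputs (genome-wide Hi-C lists, RepeatMasker tracks, a whole-genome
methylome) are far too large for routine testing, so the package treats the
generator as a first-class module: it fabricates every input file at desk
scale with known, planted structure, and the test suite checks that the
pipeline recovers exactly that structure.

Defaults (all overridable through `default_config()`):

| parameter | default | meaning |
|---|---|---|
| `n_chrom`, `chrom_length` | 2 × 8 Mb | genome size (400 bins of 40 kb) |
| `domain_length_mean`, log-sd | 1 Mb, 0.5 | lognormal domain lengths, snapped to the bin grid, tiling each chromosome |
| `inter_freq_mean` | 2.0 | exponential inter-domain frequencies |
| `intra_freq_base`, `decay`, `noise_sd` | 16.3, 0.65/Mb, 0.55 | distance-decaying lognormal intra frequencies, mean ≈ 15 |
| `activity_sd` | 0.45 | spread of the bounded per-bin contact propensity |
| `alu_rate_intercept`, `alu_rate_slope` | 2, 0.4 | Alu copies per bin ~ Poisson(2 + 0.4 f̄) |
| `alu_length_mean`, sd | 300, 30 bp | modern Alu length |
| `subfamily_mix` | J 0.25 / S 0.55 / Y 0.20 | AluS the most abundant group |
| `l1_rate`, `ltr_rate`, `dna_rate`, `mir_rate` | 7, 6, 3, 5 | frequency-independent families, copies per bin scaled to real-genome abundances |
| `gc_background`, `gc_alu` | 0.41, 0.60 | target GC of background and Alu sequence |
| `cpg_rate_background`, `cpg_rate_alu` | 0.01, 0.06 | CpG implants per position |
| `meth_rate` | J 0.92 / S 0.90 / Y 0.78; promoter 0.20, gene body 0.70, other 0.75 | per-context methylation probabilities |
| `enhancer_rate_intercept/slope` | 0.3, 0.1 | enhancer events per bin vs f̄ |
| `enhancer_alu_fraction` | 0.6 | fraction of events placed inside an Alu copy |
| `tss_rate_intercept/slope` | 0.1, 0.12 | H3K4me3 events per bin vs f̄ |
| `liftover_drop_fraction` | 0.0668 | bins removed to emulate coordinates lost in an assembly remap |

Design choices that deserve explanation:

- **Frequencies.** No distributional form is established for normalised
  contact frequencies, so the generator's choice — a lognormal with distance
  decay, a bounded per-bin propensity, and pair-level noise — is its own and
  is recorded in the truth manifest. The per-bin propensity is uniform
  (bounded) rather than Gaussian so that no single bin dominates the top
  frequency strata. The base/decay/noise values were fixed by simulating the
  generative model and choosing the combination that gives the stated intra
  mean (≈ 15) and keeps the binned estimator well behaved (next section).
- **Planted couplings.** Alu placement reads the coupling directly from the
  bin's mean intra-domain frequency f̄; SINE inherits a positive coupling
  because Alu dominates it. L1, LTR, DNA and MIR counts are Poisson draws
  independent of f̄ — their true binned correlation is zero. Enhancer events
  are Poisson in f̄; each event spawns an overlapping H3K4me1/H3K27ac pair
  plus unpaired noise peaks of both marks. The Alu-derived fraction of
  events selects its host copy uniformly over *all* Alu copies, so those
  enhancers concentrate where Alus are dense — the structure the enrichment
  test is designed to detect — while the rest sit uniformly in their bin.
- **Sequence.** The genome is literal: background bases are drawn iid, every
  incidental CG is scrubbed (G→A), and CpG sites are implanted at the
  configured per-position rate, so the set of CG dinucleotides is exactly the
  implanted set; Alu intervals are overwritten with sequence generated the
  same way at Alu parameters. The iid base GC is solved analytically from the
  target so that the *final* GC (after scrubbing and implanting) hits
  `gc_background` / `gc_alu`; recovery is tested to ±0.02. Methylation calls
  are Bernoulli per CpG with the rate of the site's context
  (Alu subfamily > promoter (TSS ± 1 kb) > gene body > other).
- **Remap loss.** A seeded 6.68% of bins is dropped (with every pair touching
  them) before the bin-pair list is written, emulating coordinates lost in a
  genome-assembly liftover; the analysis never sees those bins.

What the generator does *not* emulate: matrix-balancing artefacts, read-level
noise, repeat-sequence divergence structure (subfamily labels are drawn, not
evolved), strand effects, CpG islands, and real gene architecture. Passing
recovery tests therefore demonstrates that the pipeline's estimators measure
what they claim on data with known structure — not that the biological
findings replicate on real data.

## Behaviour of the binned estimator at desk scale

One property of the binned-correlation design matters greatly when the
genome is small. The per-bin metric values are shared between all pairs that
touch the bin, so the 50 binned points are not independent: with only 400
genome bins, replicated simulations with iid per-bin noise show the null
distribution of the binned r has a standard deviation of roughly 0.2 —
whereas at the scale of a real genome (tens of thousands of bins) it is an
order of magnitude tighter. Individual desk-scale replicates of an
*uncoupled* family can therefore show |r| of 0.3–0.5 without any planted
effect, and this is a property of the estimator, not a bug in the pipeline.
Two consequences:

- a planted Alu coupling of 0.4 copies per unit frequency is recovered with
  r ≈ 0.7–0.9 and a stable sign across 20/50/100 bins, comfortably clear of
  the null; but
- single-replicate null correlations should be read against the Monte-Carlo
  replicate band from `planted_binned_correlation()`, not against an
  intuition that "null means r ≈ 0".

The design frontier was mapped explicitly: every change that tightens the
null band (weaker per-bin propensity, stronger distance decay, flattened
frequency marginal) also weakens the recoverable Alu signal, because both are
carried by the same bin-level propensity variance. The defaults sit at the
point that keeps the planted Alu recovery strong while keeping the null as
tight as the scale allows.

## Numerical and procedural choices

- Coordinates are 0-based half-open everywhere internally; RepeatMasker
  `.out` (1-based inclusive) is converted on read. Lengths are always
  `end − start`.
- Self pairs (`start_i = start_j`) are rejected: the density normalisation
  assumes an 80-kb pair region.
- Merging is used for coverage only; counts always use raw records.
- The retained-pair bounds are inclusive below and exclusive above; on dense
  data the upper window is empty so the choice is immaterial, and it is fixed
  for determinism. At very small sample sizes the first-empty-window rule can
  degenerate (an isolated low-frequency pair below a gap); the Monte-Carlo
  band helper falls back to no upper cut when the detected upper threshold
  does not exceed the lower one.
- Undefined ratios (CpG density with zero G/C, methylation with zero CpG)
  are `NA`, never 0, and propagate by being dropped from binned means.
- The binomial enrichment test defines success as "window coverage above the
  background mean" with the background's own exceedance fraction as null
  rate; this makes the null calibration exact when observed windows are drawn
  from the background, and a 10,000-resample permutation test on the window
  mean ships alongside as a cross-check. Both p-values are reported.
- Peak matching is mutual-nearest with a strict `< 250 bp` rule, which makes
  shared counts symmetric and deterministic; the reference point is the
  summit when present, else the midpoint.
- The per-Myr methylation-rate operation is the plain difference quotient
  `(d_old − d_young)/(age_old − age_young)` with the standard subfamily ages
  (AluJ 81 Myr, AluS 36 Myr); on the default bundle it evaluates to
  ≈ 4 × 10⁻⁴ per Myr (0.04 % per Myr).
- Problem sizes: the default bundle is two 8-Mb chromosomes (≈ 17,000 pairs,
  ≈ 3,500 Alu copies, ≈ 200,000 CpG sites); the test suite uses a 4-Mb
  single-chromosome bundle for unit tests and the full default bundle for
  recovery checks, with 20-seed replicate panels run without sequence
  generation.

## Limitations

The generator's couplings are linear and single-cause; real Alu density
co-varies with GC isochores, replication timing and gene density in ways the
model collapses into one propensity. The methylation model is a per-site
Bernoulli with no read-level uncertainty. The enhancer model plants marks
as clean interval pairs, so peak-calling noise is out of scope. And the
desk-scale null width discussed above means single-seed null correlations
are only interpretable jointly with the replicate band.
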