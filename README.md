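# alucontact

Transposable elements — above all the ~300-bp, primate-specific **Alu**
repeats — are not scattered uniformly through the human genome. Inside the
megabase-scale *topological domains* seen in Hi-C maps, genomic loci that
contact each other frequently in 3D carry systematically more Alu sequence,
more GC, more CpG dinucleotides and more active regulatory elements than loci
with few contacts. `alucontact` implements the full analysis that establishes
and dissects this association, for people working on chromatin organisation
and repeat biology: it takes 40-kb Hi-C bin-pair frequency lists, topological
domain calls, RepeatMasker annotation, a genome FASTA, per-CpG methylation
calls and histone-mark peak sets, and quantifies how TE content, sequence
composition and enhancer/promoter density change with contact frequency.

## The analysis

For a bin-pair (two 40-kb bins with normalised contact frequency *f*), pairs
are stratified by domain membership: **intra-domain** (both bins inside one
domain), **non-intra-domain**, or boundary. The mean non-intra frequency is
the lower retention threshold (inter-domain contacts are treated as
background noise); the upper threshold is the left edge of the first empty
integer window of the intra-domain frequency histogram (step 1), discarding
scattered outliers.

Per retained pair and TE selector the package computes three metrics over the
80-kb pair region:

- **coverage** — covered bases / 80 kb;
- **enrichment score** — copy count (midpoint rule);
- **density** — count / maximum possible copies, i.e.
  `count × mean family length / 80 kb`.

Retained pairs are grouped into 50 equal-width frequency bins (20 and 100 as
robustness checks); per bin the mean frequency (x) and mean metric (y) give a
summary point, and the Pearson correlation *r* with a two-sided t test
(df = n − 2) measures the association. Two correlations are compared with the
Fisher z test, `z = (atanh r₁ − atanh r₂) / √(1/(n₁−3) + 1/(n₂−3))`.

Each pair's bases are also partitioned by origin — Alu, SINE/non-Alu,
non-SINE — and per class the pipeline tracks GC content (G/C per base), CpG
density (CpG sites per G/C base), and methylation density (methylated
fraction of CpG sites), plus per-subfamily (AluJ/AluS/AluY) methylation.
Active enhancers are H3K4me1 ∩ H3K27ac regions; active TSSs are H3K4me3-
supported transcription starts; enhancer windows are tested for Alu-coverage
enrichment against random genome windows with a binomial tail (plus a
permutation cross-check).

Because the original inputs are tens of gigabytes, the package ships a seeded
synthetic-data generator (`sim_bundle()` / `simulate_all()`) that emulates
every input file at desk scale with *planted* couplings — Alu copies per bin
Poisson with mean `2 + 0.4 f`, frequency-independent L1/LTR/DNA/MIR, elevated
GC and CpG inside Alu insertions, subfamily-specific methylation rates
(AluJ 0.92, AluS 0.90, AluY 0.78) — and a truth manifest, so every stage can
be tested for recovery of known effects.

## Worked example

```r
library(alucontact)

bundle <- sim_bundle(default_config())      # seeded 16-Mb synthetic inputs
strat  <- stratify_and_filter(bundle$binpairs, bundle$domains)
strat$lower_threshold
#> [1] 1.995246
strat$upper_threshold
#> [1] 56
nrow(strat$intra)
#> [1] 5145

prof <- family_profile(strat$intra, bundle$repeats, n_bins = 50)
dplyr::filter(prof, selector %in% c("SINE", "Alu", "SINE_non_Alu", "L1"))
#> # A tibble: 4 × 7
#>   selector     kind    n_bins absent     n      r        p
#>   <chr>        <chr>    <dbl> <lgl>  <int>  <dbl>    <dbl>
#> 1 SINE         density     50 FALSE     49  0.738 1.42e- 9
#> 2 Alu          density     50 FALSE     49  0.808 2.25e-12
#> 3 SINE_non_Alu density     50 FALSE     49 -0.115 4.32e- 1
#> 4 L1           density     50 FALSE     49 -0.179 2.19e- 1

sm <- subfamily_methylation(bundle$cpg, bundle$repeats)
sm
#> # A tibble: 3 × 3
#>   group n_sites meth_density
#>   <chr>   <int>        <dbl>
#> 1 AluJ    12857        0.919
#> 2 AluS    28451        0.899
#> 3 AluY    10483        0.785
```

The Alu density correlation (r = 0.81, p ≈ 2 × 10⁻¹²) recovers the planted
`0.4` copies-per-unit-frequency coupling, SINE follows because Alu dominates
it, the uncoupled SINE/non-Alu and L1 are null, and the per-subfamily
methylation densities recover the planted rates to within 0.01, in the
old-to-young order (AluJ > AluS > AluY) expected if host methylation
accumulates with element age. `plot_family_profile(prof)` and
`plot_frequency_profile()` draw the standard figures;
`run_all(sim = default_config())` executes every stage and returns a single
report.

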