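# sigbind

Mutational processes write recognisable 96-class single-base-substitution
signatures into tumour genomes; regression models trained on
protein-binding microarrays predict how every single-nucleotide change at
the centre of an 11-mer alters a transcription factor's binding affinity
(a score, positive = stronger binding, with a p-value that decreases
strictly in |score|). `sigbind` integrates the two to ask, for every
TF × signature pair: does this mutational process preferentially **create**
binding sites for this TF, or **destroy** them?

It is aimed at regulatory-genomics and cancer-genomics analysts who have
a signature catalog (COSMIC-style), per-experiment score/p-value tables
(QBiC-style downloads), and optionally tumour mutation calls, exposures,
PWMs and gene sets — and want the full analysis stack as composable,
pipe-friendly R functions over tibbles.

## The statistic

For a score table with per-class distributions `D_mu`, a signature
`sigma` induces the weighted mixture

    D'_sigma = sum_mu sigma_mu * D_mu    (mass sigma_mu / 4^(w-3) per change)

against the equal-frequency baseline `D` (mass `1 / (96 * 4^(w-3))`).
A single threshold `T` — the smallest |score| passing Benjamini–Hochberg
FDR < 0.1 over the table's p-values — cuts both distributions into
positive and negative tails, and

    GR = area(D'_Pos) / area(D_Pos)      LR = area(D'_Neg) / area(D_Neg)

`GR > 1`: the process is enriched for binding-site-creating mutations;
`LR > 1`: for site-destroying ones. Significance comes from a seeded
resampling test against uniformly random mutations (add-one empirical
p-values); TFs assayed several times are summarised by median GR/LR.
Supporting analyses: promoter-restricted mutation spectra from VCF-like
calls (TSS ± 2000 bp, with signature-dominated tumour selection and
major-class filtering), AT/GC PWM classification with expected
base-composition-entropy changes, complete-linkage clustering of the
GR/LR matrix, and Fisher-exact/BH gene-set enrichment of gain- and
loss-of-binding TF sets. A seeded synthetic generator produces every
input type at toy scale for end-to-end validation.

## Worked example

```r
library(sigbind)

tab <- synth_qbic_table(synth_motif("TAAT"), name = "HOMEO_pbm1",
                        tf = "HOMEO", seed = 1)
sigs <- dplyr::bind_rows(
  synth_signature(c("C>T" = 0.95, "C>A" = 0.05), name = "ct_dominated"),
  synth_signature(c("T>C" = 0.9,  "T>G" = 0.1),  name = "tc_dominated"),
  uniform_signature()
)
fit <- gain_loss_analysis(tab, sigs, seed = 7)
dplyr::select(tidy(fit), tf, signature, gr, lr, p_gain, p_loss, gain, loss)
#> # A tibble: 3 × 8
#>   tf    signature       gr    lr   p_gain   p_loss gain  loss
#>   <chr> <chr>        <dbl> <dbl>    <dbl>    <dbl> <lgl> <lgl>
#> 1 HOMEO ct_dominated  2.05  0    0.000999 1        TRUE  FALSE
#> 2 HOMEO tc_dominated  0     2.07 1        0.000999 FALSE TRUE
#> 3 HOMEO uniform       1     1    0.503    0.463    FALSE FALSE
```

A C>T-dominated process (it converts C/G into A/T) doubles the expected
mass of significant binding-gaining mutations for this AT-motif TF
(GR 2.05, resampling p ≈ 0.001) and leaves essentially none on the losing
tail (LR 0); a T>C-dominated process mirrors the pattern; the uniform
signature sits exactly at GR = LR = 1 and is the fixed point of the
method. `glance(fit)` gives the one-row summary, `autoplot(fit)` the
clustered GR/LR heatmap, and `run_analysis()` writes the full artefact
set (long results, wide matrices, Newick dendrograms, enrichment tables,
JSON manifest). A thin CLI over the same functions ships at
`inst/cli/sigbind.R` (`gr-lr`, `spectrum`, `entropy`, `enrich`, `synth`,
`demo`).

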