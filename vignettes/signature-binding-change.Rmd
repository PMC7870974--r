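---
title: "How mutational signatures reshape transcription-factor binding: the model behind sigbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How mutational signatures reshape transcription-factor binding: the model behind sigbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigbind)
library(dplyr)
```

## The question

Somatic mutational processes are not uniform over sequence space. Each
process leaves a characteristic *single-base-substitution signature*: a
multinomial distribution $\sigma$ over the 96 strand-collapsed mutation
classes $\mu$ (a substitution of a central pyrimidine in its trinucleotide
context, written `TCA>TTA` for a C>T flanked by T and A). At the same
time, the effect of any single-nucleotide change on a transcription
factor's binding affinity can be predicted from protein-binding-microarray
regression models, which assign every change at the centre of every 11-mer
a *score* (positive = stronger binding) and a p-value for the null
hypothesis of no intensity change, with the p-value a strictly decreasing
function of |score|.

`sigbind` joins the two: for a TF assay and a signature it asks whether
the mutations that the process actually generates are enriched, relative
to uniformly random mutations, among the changes that significantly
*create* binding sites (Gain Ratio) or significantly *destroy* them (Loss
Ratio).

## The statistic

Write $D_\mu$ for the set of score-table rows whose central trinucleotide
change is $\mu$; with $w$-mers there are $4^{w-3}$ rows per class
($65{,}536$ at the assay width of 11, i.e. $6{,}291{,}456$ rows in all).
The signature-weighted distribution puts mass

$$D'_\sigma = \sum_{\mu \in M} \sigma_\mu \cdot D_\mu, \qquad
  \text{mass per change} = \frac{\sigma_\mu}{4^{w-3}},$$

while the equal-frequency baseline puts $1 / (96 \cdot 4^{w-3})$ on every
change. A single score-magnitude threshold $T$ is obtained by applying
Benjamini–Hochberg jointly to all p-values of the table at FDR $< 0.1$ and
taking the smallest passing $|score|$; because p decreases strictly in
$|score|$, the passing set is exactly $\{|score| \ge T\}$. Then

$$GR = \frac{area(D'_{Pos})}{area(D_{Pos})}, \qquad
  LR = \frac{area(D'_{Neg})}{area(D_{Neg})},$$

the ratios of signature-weighted to baseline mass in the positive and
negative tails cut at the same $T$. Both tails contain the same changes
under every signature; only their masses differ. Areas are exact weighted
sums over changes — histograms are presentation only. The uniform
signature gives $GR = LR = 1$ identically, and because $area(D'_{Pos})$ is
linear in $\sigma$, ratios mix linearly over signature mixtures; both
properties are enforced in the test suite, the former exactly (the
baseline is computed through the same dot-product path as the weighted
area, so the identity holds to the last bit).

Two conventions deserve a note. First, the tails are *inclusive*
(`score >= T`, `score <= -T`): with $T$ defined as the smallest passing
|score|, an exclusive cut would drop the boundary change from the very set
the FDR criterion selected. Second, BH is applied jointly to the whole
table rather than separately per score sign, which yields one symmetric
threshold for both tails; this is the minimal consistent reading of a
threshold defined through p-values that depend only on |score|. A
per-sign variant would change $T$ only through the tails' relative sizes
and is intentionally not offered.

### Significance by resampling

Whether $area(D'_{Pos}) - area(D_{Pos}) > 0$ could arise by chance is
assessed against a null of random mutations with equal class frequencies:
each replicate draws `n_mutations` class labels from the uniform
multinomial over 96 classes, normalises the counts into a
pseudo-signature, and recomputes the tail-area difference. The one-sided
p-value uses the add-one estimator $(1 + \#\{ \text{replicate} \ge
\text{observed}\}) / (n_{reps} + 1)$, so it is never 0 and never smaller
than $1/(n_{reps}+1)$. Defaults are `n_mutations = 10000` and
`n_reps = 1000` with a mandatory seed; the replicate set is shared across
the signatures of one call, which makes p-values comparable across
signatures and reproducible. `n_mutations` controls the granularity of
the null (the multinomial noise of a pseudo-signature at that sample
size); if you know the mutation burden of the tumours you care about, set
it to that.

A (TF, signature) pair is called *gain-of-binding* when
`p_gain < alpha` (default 0.05), *loss-of-binding* when `p_loss < alpha`;
a pair may be neither. TFs assayed in several PBM experiments are
summarised by the standard median of their per-experiment GR and LR.

## Promoter spectra as a consistency check

Ratios can be computed either from a signature profile alone or from the
mutations actually observed in tumours dominated by that signature
(exposure fraction $\ge 0.4$), restricted to proximal promoters (2000 bp
5' to 2000 bp 3' of a TSS, 4001 reference bases; the TSS of a minus-strand
gene is its annotated end). `build_spectrum()` assigns each SNV its
canonical class from the ±1 bp reference context, dropping records whose
stated reference allele mismatches the genome and counting a mutation
once even when promoters overlap (mutations are counted, not
mutation-region pairs). To minimise interference from co-occurring
processes, analysis can be restricted to the substitution types that
collectively contribute more than 90% of the signature
(`major_mutation_types()`, strict threshold, ties broken in canonical
type order). `compare_gr_lr()` then reports the squared Pearson
correlation between spectrum-based and signature-based ratios, pooled
over GR and LR per signature. Promoter regions are deliberately
strand-agnostic (TSS ± 2000 on the reference): mutation classes are
strand-collapsed, so flipping the region strand cannot change a spectrum,
and gene-level TSSs are used as given — transcripts sharing a TSS should
be deduplicated upstream if transcript-level annotation is supplied.

## AT/GC motifs and composition entropy

Signatures dominated by "+AT" mutations (C>A, C>T — they convert C/G into
A/T) tend to push already AT-rich sequence toward lower base-composition
entropy, and conversely for "−AT" mutations (T>C, T>G). `entropy_change()`
is the Shannon entropy (bits by default; the base is an argument) of the
mutated k-mer's base-composition frequency vector minus the reference's —
a function of the composition multisets only. `expected_entropy_change()`
averages it under a signature, optionally restricted to AT-rich
(reference AT fraction > 0.6) or GC-rich (< 0.4) k-mers, spreading each
class's mass uniformly over its eligible changes and renormalising over
the filtered set; classes with no eligible k-mer are skipped with a
message. The sum is computed exactly by enumerating flank base
*compositions* with multinomial multiplicities, so the full width-11
space is covered without materialising 6.3 million strings. No numeric
agreement with any published entropy medians is claimed: the published
account does not state the entropy base or the normalisation behind its
MAD values, so the summaries here (`tail_stats_by_filter()`, plain
`constant = 1` MAD by default) are defined self-consistently instead.

TFs are classified from their PWMs: AT percent is the mean over positions
of $P(A) + P(T)$, the median over a TF's PWMs when it was assayed several
times, with strict labels AT-PWM (> 0.6) and GC-PWM (< 0.4).

## Gene-set enrichment

`enrich()` is a local, exact reimplementation of the usual
Fisher/BH enrichment: a one-sided Fisher exact p per gene set from the
2×2 table (query∩set, query∖set, set∖query, rest of background), BH
q-values across sets, significance at q < 0.005. The background defaults
to the union of the collection's sets, but when the query is a set of
assayed TFs the right universe is the assayed-TF panel — pass it
explicitly. Symbols are matched exactly after case-folding; no alias
resolution is attempted.

## What the synthetic generator emulates — and what it does not

All validation runs on data from `synth_*()`:

* `synth_qbic_table()` builds a score table from an explicit energy
  model: binding of a k-mer is the best log-odds sum of a motif over all
  offsets and both strands, floored at a nonspecific-binding baseline;
  the score of a change is the binding difference plus seeded Gaussian
  noise (`noise_sd = 1`), and p-values are the two-sided normal tail of
  `score / p_scale`. The floor matters: without it almost every central
  change shifts some alignment window and half the table looks
  "significant". With the defaults (`match = 2`, `mismatch = -6`, cell
  jitter 1.5, `p_scale = 2`) a few percent of changes pass BH FDR < 0.1,
  keeping both tails non-degenerate, and the scores form a continuum
  rather than a lattice, so the BH threshold lands stably.
* `synth_signature()` spreads chosen substitution-type masses uniformly
  (or with seeded random proportions) over each type's 16 classes — a
  C>T-dominated signature emulates the APOBEC-like structure, equal type
  masses give a flat signature.
* `synth_cohort()` writes a random uniform-composition genome whose
  TSS ± 2000 promoters tile it end to end, then draws mutations by
  sampling a class from the signature and a uniform genomic position
  realising its context. Every mutation therefore lies in a promoter and
  the promoter-restricted spectrum is exactly multinomial in the
  generating signature — which is precisely the condition under which the
  spectrum round trip (chi-square goodness of fit at $n = 10^5$, ratio
  agreement $R^2 > 0.99$) is a sharp test of the machinery.

The generator reproduces the *statistical structure* the method assumes —
score/p monotonicity, complete change space, signature-multinomial
mutations — and none of the biology it does not: real genome composition,
regional mutation-rate variation, selection, overlapping mutational
processes, linked assays of one TF. Passing tests therefore validate the
computation, not the biological claims; analyses of real tumours need the
real catalogs, score tables and annotations as inputs.

## Problem sizes and numerical choices

The default synthetic width is 7 (24,576 changes; `width = 11` gives the
full 6,291,456-change space through the same code paths), resampling uses
999–1,000 replicates, the spectrum round trip uses $10^5$ mutations over
a 100 kb genome, and enrichment calibration uses a few hundred shuffled
queries — sizes chosen so the whole validation suite runs in about a
minute while every estimate is still well inside its asymptotic regime.
Other numerical conventions: probabilities renormalised on load with a
warning beyond 1e-6; p-values must lie in (0, 1] and violations of
p-vs-|score| monotonicity beyond 1e-9 are warned about and monotonized
(smallest nonincreasing majorant); missing ratios propagate as `NA`,
never 0 or 1, and are imputed as 1 (no effect) only inside clustering,
with a message; clustering is complete-linkage on Euclidean distance over
the concatenated GR and LR profiles, deterministic given input order;
written score tables use `%.17g` and are re-read through `strtod`, so
they round-trip bit-exactly.

## A worked miniature

```{r example, eval = FALSE}
tables <- list(
  synth_qbic_table(synth_motif("TAAT"), name = "HOMEO_pbm1",
                   tf = "HOMEO", seed = 1),
  synth_qbic_table(synth_motif("GCCGC"), name = "GCBOX_pbm1",
                   tf = "GCBOX", seed = 2)
)
sigs <- dplyr::bind_rows(
  synth_signature(c("C>T" = 0.95, "C>A" = 0.05), name = "ct_dominated"),
  synth_signature(c("T>C" = 0.9, "T>G" = 0.1), name = "tc_dominated"),
  uniform_signature()
)
fit <- gain_loss_analysis(tables, sigs, seed = 7)
tidy(fit)      # per-TF medians with gain/loss calls
glance(fit)    # one-row summary
autoplot(fit)  # clustered GR/LR heatmap
```

An AT-recognising TF gains binding sites under a C>T-dominated process
(GR > 1, significant `p_gain`, LR < 1) and loses them under a
T>C-dominated one — the anti-correlation of gain and loss that the method
is designed to expose.

## Known limitations

* Only single-base substitutions are modelled; indel, doublet and
  clustered signatures are out of scope.
* The score tables are consumed, not fitted: refitting the underlying
  PBM regression is a separate problem.
* Resampling p-values are bounded below by $1/(n_{reps}+1)$; multiple
  testing across (TF, signature) pairs is left to the caller.
* The entropy analysis is descriptive; its published numeric summaries
  are not reproduced for the reasons above.
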