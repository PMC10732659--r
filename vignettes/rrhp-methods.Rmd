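---
title: "Methods: differential hydroxymethylation from RRHP tag counts"
author: "rrhp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential hydroxymethylation from RRHP tag counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrhp)
```

## The measurement model

Reduced-representation 5hmC profiling (RRHP) converts hydroxymethylation
into sequence: glucosylation protects 5hmC-containing MspI sites from
re-digestion, so only tags anchored at hydroxymethylated CCGG positions
survive library construction, and every informative read begins with
CCGG. Two consequences shape the whole analysis:

1. **The unit of measurement is the CCGG site.** CCGG is its own reverse
   complement, so a site observed on either strand is the same physical
   locus. `extract_sites()` therefore collapses both strands onto the
   forward-strand coordinate of the motif (plus-strand tags anchor at
   their alignment start, minus-strand tags at alignment end − 3); an
   optional stranded mode keeps the tag strand in the site key for users
   who want per-strand counts. Whether the original study collapsed
   strands is not documented; collapsing halves sparsity and makes
   coordinates unambiguous, which is why it is the default.
2. **Library size is informative, not a nuisance.** Samples with more
   5hmC genuinely produce more tags, so the total accepted tag count per
   sample (the column sum at matrix construction) is both the model's
   normalisation constant and a crude per-sample 5hmC load that can be
   correlated with phenotypes (`phenotype_correlation()`). Library
   sizes are fixed when the matrix is built and are deliberately *not*
   recomputed after filtering: the filters select sites, they do not
   change how deeply a sample was sequenced.

## The two-stage low-signal filter

`filter_low_signal()` removes sites that cannot support inference:

- **Stage 1** drops a site when `k_zero` or more samples have a zero
  count. The default `k_zero = floor(n/2) + 1` is the
  majority-of-samples rule — 6 of 10 in the two-groups-of-five design —
  which guarantees that a dropped site was near-absent in at least one
  full group plus one more sample, i.e. uninformative in both.
- **Stage 2** computes one scalar median *M* over **all entries** of the
  stage-1-retained matrix and drops sites with `k_below` or more samples
  strictly below *M*. "Below" is strict, so ties at the median survive;
  with discrete counts this is the only reading under which a matrix of
  identical values keeps all its sites. Using a single global median
  (rather than per-sample medians) follows from the design in which one
  scalar threshold is reported for the whole matrix.

`filter_report()` keeps the cascade arithmetic explicit:
`n_retained = n_input − n_removed_stage1 − n_removed_stage2`, always.

## Transform, weights, and the fitted model

Counts are transformed to log2 counts-per-million with half-count and
unit-library offsets,
$y_{ij} = \log_2\!\big((c_{ij} + 0.5)/(L_j + 1)\times 10^6\big)$,
which keeps zeros finite and makes $y$ bit-reproducible. Count noise is
strongly mean-dependent on this scale, so an unweighted two-group fit
per site supplies residual standard deviations whose square roots are
regressed on the site's mean log2 count by LOWESS (span 0.5, 3
robustifying iterations — the established default for this trend; the
span only smooths the weights and has no sharp optimum). The trend
evaluated at each observation's fitted log2 count, raised to the −4th
power, is that observation's precision weight. The trend prediction is
floored at 10⁻¹⁰ so weights stay finite and positive even under extreme
extrapolation.

`wls_fit()` then fits $y \sim \mu + \beta\,[\text{fast}]$ by weighted
least squares per site. With a single binary covariate the solution is
the difference of weighted group means, the residual variance $s_i^2$
has $d = n - 2$ degrees of freedom, and the unscaled standard error is
$u_i = (1/S_{w,\text{fast}} + 1/S_{w,\text{slow}})^{1/2}$ with $S_w$
the group weight sums. Positive $\beta$ means more 5hmC in the
fast-growing group. Each group must contribute at least two samples,
otherwise $s^2$ is undefined.

## Empirical-Bayes moderation

With few samples, per-site variances are noisy; `ebayes_moderate()`
shrinks them toward a prior estimated from all sites by moment matching
on the log scale. Under the scaled-F model,
$e_i = \log s_i^2 - \psi(d/2) + \log(d/2)$ has mean
$\log s_0^2 - \psi(d_0/2) + \log(d_0/2)$ and excess variance
$\psi'(d_0/2)$ beyond the sampling term $\psi'(d/2)$, so the prior df
solves $\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d/2)$ (Newton inversion
of the trigamma function) and $s_0^2$ follows from the mean of $e$.
When the observed spread does not exceed the sampling spread the prior
df is infinite and every posterior variance equals the common prior,
taken as the mean observed variance — so a degenerate set of identical
variances is returned unchanged. The moderated statistic
$t_i = \beta_i/(u_i\,s_{\text{post},i})$ is referred to a t
distribution on $d + d_0$ df, or the normal when $d_0 = \infty$.
Sample variances of exactly zero are offset to $10^{-5}\times$ the
median before logs are taken. Forcing `prior_df = 0` recovers the
ordinary per-site t test; `prior_df = Inf` the fully pooled limit —
both limits are pinned in the test suite, and the whole chain
(transform, weights, fit, moderation) is cross-checked there against an
independent reference implementation to ~10⁻⁸.

p values are two-sided: the group contrast has no privileged direction
at a single site, even though the study design predicts that most
differential sites will be hyper in the fast group. BH adjustment is
the classical step-up $q_{(i)} = \min_{j\ge i} p_{(j)} m/j$ clipped to
1, and a site is a DhmC when $|\beta| > 1$ (twofold) and $q < 0.05$.

## What the simulator emulates — and what it does not

`sim_genome()`, `sim_hmc_truth()`, `sim_tag_counts()` and
`sim_fullsib_genotypes()` reproduce the *statistical structure* of the
study design with known ground truth:

- two groups of 5 samples with fast-group library sizes about 3× the
  slow group (the assay's enrichment bias, mirroring the ~3:1 ratio of
  uniquely mapped reads per group in the motivating design);
- CCGG sites at a requested mean spacing (default 100 bp; planting
  density is corrected for the 1/256 per-bp chance rate in random
  sequence), with the catalogue defined as the exhaustive scan of the
  emitted sequence, so it is exact by construction;
- per-site base rates drawn log-normally (sdlog 1) with mean calibrated
  to 1/n sites, so the default library depths give mean counts of a few
  tens per site — the regime the global-median filter was designed for.
  The real per-site 5hmC rate distribution is unknown; log-normal is a
  modelling choice, not a measured fact;
- counts drawn negative-binomially with variance $\mu + \phi\mu^2$ and
  dispersion $\phi = 0.2$ (Poisson at $\phi = 0$), a realistic
  overdispersion for low-input count libraries;
- an exact `round(frac × n)` subset of sites carrying log2 effects of
  ±2, with 84% hyper in the fast group (the observed hyper:hypo balance
  of the motivating study);
- full-sib genotypes by literal Mendelian segregation from two founders
  (founder MAF 0.3), with group labels independent of genotype — the
  null under which no locus should survive FDR.

Not simulated: bisulphite/glucosylation chemistry, adapter and quality
artefacts, mappability, strand-specific coverage, linkage between loci,
or genome-scale site counts. Passing tests therefore demonstrate that
the *inference machinery* behaves correctly under the design's
statistical structure, not that every property of real RRHP libraries
is captured.

Problem sizes in the test suite and acceptance script (1,000–2,000
sites, 20 simulation replicates, 2,000 loci) were chosen as the
smallest sizes at which the Monte-Carlo assertions are stable.

## Association testing

Loci enter the allelic test only when complete (any missing call drops
the locus — missingness in RRHP-derived genotypes is confounded with
group-specific 5hmC enrichment) and biallelic with both alleles
observed. Each non-missing sample contributes two alleles to a 2×2
group × allele table, tested by 1-df chi-square without continuity
correction when every expected cell exceeds 5 and by the two-sided
Fisher exact test otherwise (probability-mass rule; the strict
threshold keeps the fully separated 10-vs-10-allele table, whose
expected cells are exactly 5, on the exact branch where its p value is
2/C(20,10)). Haplotype tables (k haplotypes × 2 groups) use the
chi-square with k − 1 df or exact enumeration for sparse tables with
k ≤ 4, and reduce exactly to the allelic test at k = 2. BH runs over
all tested loci.

At this sample size the exact tests are strongly discrete: the
attainable p values below 0.01 are few, so the null fraction of loci at
p < 0.01 sits well below the nominal 1% (the test suite's full-sib null
simulations show fractions of roughly a tenth of nominal). This
conservatism is a property of exact tests on 2×10-allele tables, not an
implementation artefact, and it only strengthens the design's headline
negative expectation: zero FDR-significant loci.

## Conserved windows and motifs

`conserved_windows()` consumes a pre-computed pairwise alignment
(producing alignments is out of scope) and measures identity on the
reference coordinate system: a partner gap is a mismatch, reference
gaps contribute no positions. Sliding windows (default 50 bp) at or
above the identity threshold (default 0.7) are merged into maximal
covered intervals and reported when at least `min_len` (default 100 bp)
long, with their recomputed mean identity. The defaults are
configurable because no canonical thresholds exist for "highly
conserved" in this context; window discretisation means a reported
interval's identity can fall below the threshold by at most ~1/window.
`motif_scan()` does exact IUPAC matching on both strands (reverse-hit
coordinates remapped to the forward strand) — position weight matrices
are deliberately out of scope since the use case is reporting the
presence and position of a named binding site. `dhmc_context()` reports
signed distances (positive downstream on the supplied gene strand) and
a conserved-interval flag.

## Annotation conventions

Promoter (−1000..+100) and TTS (−100..+1000) windows are strand-aware
offsets around the TSS and transcription end, the defaults of standard
peak annotators; both are configurable. Classification is total and
single-valued via the priority promoter > TTS > exon > intron >
intergenic; when a site hits equal-priority features of two genes the
smaller absolute TSS distance wins, then the lexicographically smaller
gene id — deterministic by construction. Intergenic sites carry no gene
assignment from classification; `nearest_tss()` provides the separate
nearest-TSS assignment (signed negative upstream) used for intergenic
DhmCs. "Gene body" summaries count all non-intergenic classes,
including promoters, and gene-body plus intergenic shares always sum to
100%.

## Known limitations

- **The DhmC call rule inflates the realised FDR.** Selecting
  $q < 0.05$ *and* $|\log_2 FC| > 1$ is anti-conservative relative to
  the q threshold alone: false positives that reach small q tend to
  have exaggerated fold changes, while the fold threshold removes
  proportionally more weak true positives. In the package's effect
  simulations the realised FDR of the combined rule runs a few points
  above the nominal 5% (and above 10% at the default simulation depth),
  while sensitivity for twofold effects stays around two thirds. Users
  who need calibrated error control at a fold-change boundary should
  test against the boundary directly rather than thresholding
  post hoc; the combined rule is kept because it is the field's
  standard reporting convention.
- **CPM offsets bias weak sites under extreme library imbalance.** With
  small libraries the +0.5/+1 offsets add proportionally more
  pseudo-signal, pulling low-count log fold changes toward the
  small-library group. This is visible in the simulations as an excess
  of spurious hypo calls at low abundance and is inherent to the
  offset-CPM transform.
- **No between-sample normalisation.** Library size is treated as
  signal (see above); compositional normalisations would erase exactly
  the effect the assay is designed to see. Consequently global shifts
  in 5hmC appear as fold changes at many sites, by design.
- The B-statistic/posterior-odds branch of moderated inference and
  dispersion-based count models are intentionally not provided; the
  supported inference path is the transform-weight-moderate chain
  described above.
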