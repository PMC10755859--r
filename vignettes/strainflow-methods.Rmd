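---
title: "Methods: strain typing, community typing, and trial statistics in strainflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain typing, community typing, and trial statistics in strainflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainflow)
```

# Scope

`strainflow` analyses infant-gut shotgun metagenomes from a three-arm
probiotic trial design: a placebo arm (CG) and two arms supplemented with
*Bifidobacterium longum* subsp. *infantis* (Lo-EG, Hi-EG), sampled at a
baseline visit (V1), two on-supplementation visits (V2, V3) and one visit
four weeks after cessation (V4). The package covers five analysis layers —
SNV-based strain typing, longitudinal colonization tracking,
Dirichlet-multinomial-mixture (DMM) community typing, microbial-ecology
statistics, and the trial's non-inferiority growth analysis — plus a
synthetic cohort generator that emits machine-readable ground truth so that
every layer can be validated end to end without access to trial data.

# Strain typing model

Strain identity is resolved from single-nucleotide variants over a catalog
of 100 *B. infantis* signature genes (the same genes used for abundance
profiling). The procedure is:

1. **Consensus calling.** For each sample and catalog position, the
   position is called to base $b$ iff depth $\ge$ `min_depth` and
   $n_b/\mathrm{depth} \ge$ 90% (inclusive). Positions failing either rule
   stay uncalled.
2. **Sample filter.** A sample is typed only with $\ge$ 250 reads mapping
   to $\ge$ 10 signature genes (both inclusive).
3. **Gene exclusion.** A gene is excluded per sample when strictly more
   than 20% of its covered positions have major-allele frequency below
   90%. Exclusion is per-sample because allele frequencies are
   sample-specific.
4. **Profiles and distances.** Called sequences are concatenated with
   coordinates preserved (uncalled positions stay missing), so profiles are
   alignable by catalog position without a multiple-sequence-alignment
   step. The distance between two profiles is the number of differing
   positions among those called in both, normalized by the shared count;
   it is reported as undefined below `min_shared` (default 1000) shared
   positions.
5. **Tree.** A neighbor-joining tree on normalized SNV distances, rooted
   on a *B. longum* subsp. *longum* outgroup. We use NJ rather than
   maximum likelihood because branch lengths proportional to SNV
   differences are the operative signal at this scale; per-gene
   substitution-model selection adds nothing to a distance readout.
   Negative NJ branch lengths are clamped to zero with the deficit moved
   to the sibling branches, preserving tip-to-tip path lengths.
6. **Categorization**, in fixed rule order: `NotDetected` (no
   *B. infantis* in the taxonomic profile) → `UntypedLow` (detected but
   relative abundance < 0.16%) → `UntypedHet` (typing filter failed,
   heterogeneous profile, or too few shared positions) → `LMG11588`
   (normalized distance to the probiotic reference ≤ `probiotic_radius`)
   → `OtherInfantis`.

## Operating thresholds that the published filters do not pin down

* `min_depth = 4` reads: below this an allele-frequency estimate is
  meaningless; the value is configurable and recorded in outputs.
* `probiotic_radius = 0.001` (0.1% of shared positions): the probiotic
  clade has negligible internal variability, about $10^{-4}$
  substitutions/site, an order of magnitude inside the radius, while
  autochthonous strains sit at about $5\times10^{-3}$, an order of
  magnitude outside.
* `min_shared = 1000` positions for a defined distance: with ~90 kb of
  catalog, this requires ~1% of positions to be comparable and keeps
  distance noise (binomial in the shared count) well below the radius.
* **Heterogeneity.** A position is heterogeneous when its major-allele
  frequency is below the calling threshold *and* at least two reads
  support a second allele; a profile is flagged (`UntypedHet`) when more
  than `het_max = 0.002` of covered positions are heterogeneous. The
  two-read condition stops isolated sequencing errors at low depth (where
  a single wrong read among 4–10 drops the major frequency below 90%)
  from mimicking a mixture. The threshold sits an order of magnitude
  above the residual error-driven heterogeneity of pure profiles and
  below the ~0.5% of positions at which two strain lineages differ under
  the generator's defaults, so a 50/50 two-strain mixture is reliably
  flagged. A larger threshold (e.g. 2% of positions) could never fire:
  two lineages at $5\times10^{-3}$ substitutions/site differ at only
  ~0.5% of positions, which bounds the heterogeneous fraction of any
  mixture of them.

# Synthetic cohort generator

The generator emulates the study design rather than any particular
dataset. Defaults are chosen once, from the trial's own design
quantities where available:

* 76 infants per arm, three arms, four visits; feeding mix 58% EBF /
  26% mixed / 16% formula; 2% missing samples per visit.
* Baseline (V1) autochthonous *B. infantis* prevalence 16%, with the
  subclade fixed per infant across visits; per-visit acquisition 3% and
  retention 95% produce the gradual expansion to ~18% by V4.
* Probiotic colonization during the intervention 78.7% in supplemented
  arms; post-cessation persistence 83.9% in EBF and 51.5% otherwise
  (pooling to ~70% at the default feeding mix); 2% per-visit probiotic
  detections in the control arm emulate horizontal transmission.
* Strain genomes: each lineage is mutated at *half* its nominal rate
  from its ancestor so the expected *pairwise* distance between two
  strains is rate × genome length (0.005/site between lineages,
  $10^{-4}$/site within the probiotic clade).
* Read model: per-position depth ~ Poisson(5000 × relative abundance),
  i.e. 50× at 1% abundance; reads per gene ~ Poisson(coverage ×
  length/100 bp); uniform substitution errors at 0.002/base split evenly
  over the three other bases. Uncolonized samples receive no reads.
* Relative abundance of *B. infantis* in colonized samples is lognormal
  (median 2%, log-sd 1.5), which places a realistic minority of samples
  below the 0.16% typing bound.
* Genus tables are drawn from a known 6-component DMM whose components
  are chronologically ordered by construction; infants never colonized
  by *B. infantis* receive tilted mixing weights (more of the
  *Bifidobacterium*+*Escherichia* type early and the
  *Escherichia*+*Streptococcus* type late), reproducing the qualitative
  trajectory difference of that subgroup.
* Biomarkers depend monotonically on log abundance (acetate, AAT,
  calprotectin, sIgA positively; IL-1β, IL-8, IFN-γ negatively) with
  Gaussian noise; weight gain is N(35 + group effect, 7.7²) g/day with
  baseline weight N(3.5, 0.4²) kg. The default group effect is zero — the
  null generator used for calibration.

What the generator does **not** emulate: read-level FASTQ artifacts,
position-dependent error profiles, mismapped reads from related taxa
(so uncolonized samples have exactly zero signature-gene counts),
antibiotic or delivery-mode effects, and compositional coupling between
*B. infantis* abundance and the genus table. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to every artifact of real sequencing data.

A note on reported persistence: the generator plants a *colonization*
persistence probability. The observed category-level persistence is a
few points lower because some persisting V4 samples fall below the
0.16% abundance bound (becoming `UntypedLow`) — the same censoring that
affects any real cohort analysed with these rules.

# Dirichlet-multinomial mixture community typing

Counts $x_i$ for sample $i$ follow a $K$-component DMM:
$p(x_i) = \sum_k \pi_k \,\mathrm{DM}(x_i \mid \alpha_k)$, with the DM
density including its multinomial coefficient. Fitting is by EM:
responsibilities in the E-step; in the M-step, weights are responsibility
means and each $\alpha_k$ is updated by Minka's fixed-point iteration on
the responsibility-weighted DM likelihood (five inner iterations), which
is monotone in the likelihood — the tests assert a non-decreasing EM
trace. Initialization is k-means on the proportion vectors with
moment-matched Dirichlet starts; the best of `n_restarts` (default 10)
random restarts wins. Parameters are floored at $10^{-6}$ to prevent
boundary divergence.

Model choice reports three criteria on a minimize-me scale: AIC
$=-2\ell + 2p$ and BIC $=-2\ell + p\log n$ with $p = KG + (K-1)$, and a
Laplace approximation to the negative log evidence computed from the
block-diagonal analytic Hessian of the weighted negative DM
log-likelihood per component. Two numerical details matter:

* The Hessian is evaluated with respect to $\log\alpha$ — the scale the
  parameters are positive on — including the gradient correction term;
  each block has diagonal-plus-rank-one structure, so its log-determinant
  comes from the matrix determinant lemma in $O(G)$.
* Starved or boundary components yield near-singular blocks whose raw
  log-determinant would spuriously *reward* extra components; each
  block's contribution is therefore floored at a BIC-style
  $G\log(\max(\sum_i r_{ik}, 2))$. The mixture-weight block is omitted.

The Laplace criterion is the primary selector; all three are always
reported. "Ten iterations" of the published fitting protocol is read as
ten random restarts, since ten EM iterations cannot fit a 15-component
mixture. Genus tables given as relative abundances are converted to
counts at a configurable library size (default 10,000) before fitting,
because the DM likelihood needs integers. Components are relabeled
chronologically (ascending mean visit index, ties by descending
prevalence) after fitting; all reported quantities are invariant to the
label permutation.

# Ecology statistics

Standard steps go through the field's standard implementations behind
the package's interfaces: Bray–Curtis via `vegan::vegdist`, PERMANOVA
via `vegan::adonis2` with 1,000 permutations and `by = "margin"` (each
term assessed given all others, add-one p-values), PCoA via
`stats::cmdscale` with negative eigenvalues reported, symmetric
Procrustes with permutation p via `vegan::protest`, Kendall tau-b via
`stats::cor.test`, BH via `stats::p.adjust`. Taxon–biomarker
associations keep taxa with mean relative abundance ≥ 1% plus nominated
*Bifidobacterium* taxa and mark adjusted p < 0.1 as significant. The
biomarker-side ordination for Procrustes is z-scored Euclidean PCA
coordinates, a choice the published analysis leaves open.

# Trial statistics

The primary analysis is an ANCOVA of daily weight gain on group,
baseline weight and sex; adjusted means are least-squares means and
pairwise intervals use the studentized-range (Tukey–Kramer) quantile at
the residual degrees of freedom (via emmeans). Non-inferiority of a
supplemented arm versus control is declared iff the lower bound of the
two-sided 95% CI of the difference strictly exceeds the −3.6 g/day
margin; the one-sided p tests $H_0:\delta \le$ margin from the same
fit. The sample-size formula is the normal-approximation two-group form
$n_0 = 2(z_{1-\alpha}+z_{\mathrm{power}})^2\sigma^2/\Delta^2$, rounded
up and inflated by attrition; with one-sided $\alpha = 0.025$, power
80%, $\sigma = 7.7$, $\Delta = 3.6$ and 3% attrition it gives 72 → 75
per group. The published 76 per group is not exactly reproduced by any
standard rounding at 80% or 90% power, so power is an explicit argument
with no silent default.

The Freeman–Halton exact test is implemented directly: the p-value sums
conditional (fixed-margins) table probabilities no larger than the
observed one, by full enumeration when the candidate-table bound is
within $10^6$ and otherwise by Monte-Carlo over Patefield-sampled
tables with the add-one rule. `stats::fisher.test` serves as an
independent oracle in the tests, never as the implementation.

Biomarker censoring follows the published rules: below-LLD values are
substituted with the LLD when fewer than 10% of values are censored;
analytes with more than 50% of values below the LOD are flagged
`no-model`. The 10–50% gap, which the rules leave open, passes values
through unmodified with a `caution` flag rather than imputing — the
least-surprise default.

# Calibration and test design

The test-suite problem sizes are the package's own choices: typing
recovery runs the full 218-infant × 4-visit design at the default
100-gene catalog; DMM recovery uses 20 seeds of n = 600 samples at
library 5,000; permutation-test calibration uses 300 null replicates of
199-permutation tests, checked against uniformity by Kolmogorov–Smirnov
at p > 0.01; ANCOVA interval coverage uses 1,000 null replicates at the
trial's 76-per-arm size. Null tables for the Freeman–Halton calibration
carry 150 observations because the p-values of exact conditional tests
are intrinsically discrete and super-uniform at small counts — a
property of the test, not a miscalibration.

# Known limitations

* NJ trees degrade gracefully but arbitrarily within clades of
  near-identical tips; only patristic relations, not within-clade
  topology, should be interpreted.
* The Laplace evidence approximation is block-diagonal and drops the
  mixture-weight block; it ranks models well in practice but is not a
  full marginal likelihood.
* `UntypedLow`/`UntypedHet` assignments censor the tracking statistics
  (persistence, replacement) exactly as they would in a real cohort;
  rates are reported with their denominators so the censoring is
  visible.
* The generator's uniform-error, no-mismapping read model means
  specificity against contaminating reads from related *Bifidobacterium*
  taxa is untested.
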