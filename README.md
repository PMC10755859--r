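# strainflow

Strain-level colonization tracking and fecal community typing for
infant probiotic trials analysed by shotgun metagenomics.

## The problem

When a *Bifidobacterium longum* subsp. *infantis* probiotic is given to
infants, species-level profiling can show that *B. infantis* abundance
rises — but not whether the *administered strain* colonized, whether it
persisted after supplementation stopped, or whether it displaced the
autochthonous (naturally acquired) *B. infantis* strains already
circulating in the population. `strainflow` answers those questions
from allele counts over a catalog of ~100 *B. infantis* signature
genes, and couples the strain layer to the surrounding trial analyses:
community typing, ecology statistics, and the non-inferiority growth
endpoint.

## What's inside

* **Strain typing** (`type_strains()` and friends): per-position
  consensus calling at allele frequency ≥ 90%, sample filter of ≥ 250
  reads on ≥ 10 signature genes, per-sample exclusion of genes with
  > 20% low-frequency positions, concatenated profiles, pairwise SNV
  distances, a neighbor-joining tree rooted on a *B. longum* subsp.
  *longum* outgroup, and a five-way categorization per sample:
  `LMG11588` (probiotic clade), `OtherInfantis`, `UntypedLow`
  (*B. infantis* < 0.16% abundance), `UntypedHet` (possible strain
  mixture), `NotDetected`.
* **Longitudinal tracking** (`track_trajectories()`,
  `tracking_summary()`): per-infant trajectories, detection rates,
  colonization during the intervention (V2 and/or V3), persistence
  four weeks after cessation (V4), strain-replacement events, and
  chi-square group tests.
* **Community typing** (`fit_dmm()`, `select_k()`): Dirichlet-
  multinomial mixtures fitted by EM with Minka fixed-point M-steps,
  model choice by Laplace/AIC/BIC, chronological relabeling, transition
  summaries, and trajectory comparisons between colonization groups.
* **Ecology statistics**: Bray–Curtis, PERMANOVA with marginal terms
  and 1,000 permutations, PCoA, symmetric Procrustes with permutation
  p, Kendall taxon–biomarker associations with BH adjustment,
  infant-type bifidobacteria aggregation, pathogen prevalence.
* **Trial statistics**: ANCOVA-adjusted means with Tukey-adjusted
  pairwise CIs, non-inferiority decisions against a −3.6 g/day margin,
  the non-inferiority sample-size formula, relative risk, a
  Freeman–Halton exact/Monte-Carlo test, LLD/LOD censoring rules.
* **A synthetic cohort generator** (`simulate_cohort()`) that emulates
  the trial design (three arms × four visits, probiotic + autochthonous
  strain dynamics, depth scaling with abundance, genus tables from a
  known DMM, biomarkers and growth) and exports full ground truth, so
  every stage is testable end to end.

The non-inferiority decision rule at the package's core: with
$\hat\delta$ the ANCOVA-adjusted difference in daily weight gain
(g/day) between a supplemented arm and control, non-inferiority is
declared iff the lower bound of the two-sided 95% CI of $\hat\delta$
strictly exceeds the margin $M = -3.6$ g/day. The supporting sample
size is $n_0 = 2(z_{1-\alpha}+z_{\beta})^2\sigma^2/M^2$ with
$\sigma = 7.7$ g/day, inflated for attrition.

## Worked example

Simulate a small cohort, type every sample, track colonization, and fit
community types:

```r
library(strainflow)

cfg <- cohort_config(n_per_arm = 20, n_genes = 40,
                     gene_length_range = c(400, 800), seed = 42)
co <- simulate_cohort(cfg)
#> <synthetic_cohort> 60 infants, 235 samples present, seed 42

present <- co$truth$samples[!co$truth$samples$missing, ]
classes <- type_strains(co$pileups,
                        present[, c("sample_id", "abundance")],
                        co$genomes, co$catalog)
table(classes$category)
#>      LMG11588   NotDetected OtherInfantis    UntypedLow
#>            75           140            17             3

traj <- track_trajectories(classes, present)
summ <- tracking_summary(traj)
# probiotic detected during the intervention in the supplemented arms:
100 * summ$intervention_colonization$rate   # 82.5% of 40 infants
# still present four weeks after cessation:
100 * summ$persistence$rate                 # 66.7% of 33 infants
```

Both figures recover the generator's planted design (78.7% colonization;
persistence ~70% pooled over feeding modes, minus the samples censored
below the 0.16% typing bound).

Community typing on the genus tables (the generator plants six
chronologically ordered community types; at this reduced cohort size the
criteria differ, with BIC/AIC selecting the planted six and the less
parsimonious Laplace preferring more):

```r
sel <- select_k(co$genus_counts, k_max = 8, n_restarts = 3, seed = 7)
sel$best
#> $laplace [1] 8   $aic [1] 6   $bic [1] 6
```

The trial's primary endpoint on a full-size cohort with planted group
effects of the magnitude a real supplementation trial reports
(+0.5 / +1.4 g/day):

```r
cfg2 <- cohort_config(group_effect = c(CG = 0, `Lo-EG` = 0.5,
                                       `Hi-EG` = 1.4), seed = 42)
truth <- simulate_cohort_truth(cfg2, seed = 43)
g <- simulate_biomarkers_and_growth(truth$samples, truth$infants,
                                    cfg2, seed = 44)$growth
growth_noninferiority(g, margin = -3.6)$decisions
#>     comparison   estimate     lower    upper non_inferior           p
#> 1 Hi-EG vs. CG -0.1232669 -3.019918 2.773384         TRUE 0.002524720
#> 2 Lo-EG vs. CG -0.5768079 -3.467551 2.313935         TRUE 0.007177844
```

Both lower bounds clear the −3.6 g/day margin, so both arms are
non-inferior to control on daily weight gain, with one-sided p-values
from the same fit.

`run_pipeline(run_config(...))` chains all stages over one
configuration and writes per-stage outputs plus a provenance manifest.

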