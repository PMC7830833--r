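---
title: "Separating genetic from environmental determinants of epigenetic structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genetic from environmental determinants of epigenetic structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcape)
```

## The question

Epigenetic variation in wild populations may track the local environment
(epimutations induced by environmental stress), the genetic background
(epialleles physically linked to alleles, or shared neutral processes such
as drift and gene flow), or both. The two hypotheses make different
predictions about *distance matrices*: if the environment drives the
epigenome, pairwise epigenetic differentiation between sites should
correlate with environmental distance even after genetic differentiation is
controlled for; if the genome drives it, the marginal epigenome-environment
correlation should vanish once genetic differentiation enters the model.

`episcape` implements the full inferential chain for a riverscape sampling
design — multiple sites along a river network, two co-occurring species,
three marker systems per species — and a synthetic-data generator in which
the causal structure is set by explicit dials, so the chain can be validated
against known ground truth.

## From fragment profiles to a four-state matrix

Methylation-sensitive AFLP digests each sample twice, with EcoRI/MspI and
EcoRI/HpaII. Because the isoschizomers differ in methylation sensitivity at
CCGG sites, the joint presence/absence of a fragment in the two profiles
falls into four conditions: I (present/present, unmethylated), II (MspI
only, internal-cytosine methylation), III (HpaII only, external-cytosine
hemimethylation), IV (absent/absent, uninformative: hypermethylation or
restriction-site polymorphism).

`call_presence()` scores a long-format peak table with two filters, both
inclusive and configurable:

* a peak-height threshold of 750 RFU (relative fluorescence units), the
  conventional cut against ambiguous low peaks — a peak at exactly 750
  counts as present;
* a fragment-size window of [150, 500] bp, which limits size homoplasy.

Sizes are assumed to be pre-binned integers: capillary-trace binning and
the manual curation of near-coincident peaks are instrument-side steps that
cannot be reproduced from a peak table, so they are out of scope here.

`code_conditions()` maps presence pairs to conditions, and `filter_loci()`
removes loci whose Condition IV fraction *strictly exceeds* 95% of scored
individuals (a locus at exactly 95% is retained — the rule is "more than").
Condition IV is kept as an informative fourth state everywhere downstream;
a separate `NA` code marks individuals not scored at a locus, and reduces
denominators rather than being conflated with IV. Monomorphic loci can be
dropped with `drop_monomorphic = TRUE`, where "polymorphic" means at least
one scored individual differs.

## One differentiation statistic for three marker systems

The pipeline compares epiloci (haploid treatment: one four-state observation
per individual), codominant diploid microsatellites (allele-copy counting),
and pooled-sequencing SNPs (population-level frequencies only). To compare
them on one scale, `pairwise_gst()` computes the standardized
differentiation

$$G''_{ST} = \frac{k\,(H_T - H_S)}{(k H_T - H_S)\,(1 - H_S)}, \qquad k = 2
\text{ for pairs},$$

with per-locus $H_S$ the mean within-population gene diversity
$1 - \sum_i p_i^2$ and $H_T$ the gene diversity of the pooled mean
frequencies; $H_S$ and $H_T$ are averaged across loci *before* the ratio.
A `per_locus_ratio` mode (mean of per-locus values) is provided for
sensitivity analysis and deliberately differs on heterogeneous loci. Loci
monomorphic within a pair contribute $H_S = H_T = 0$ and stay in the
averages, diluting numerator and denominator symmetrically.

The default `plugin` estimator uses observed frequencies directly, so all
three marker systems — including pools, for which no sample-size correction
is possible — are computed identically. The `nei_unbiased` estimator
applies the classical small-sample correction in sampled gene copies
($\hat H_S = \tilde n/(\tilde n - 1)\, H_S$,
$\hat H_T = H_T + \hat H_S / (\tilde n k)$ with $\tilde n$ the harmonic
mean of copies); it removes the upward bias of plugin $G''_{ST}$ at small
sample sizes and is the right instrument when testing whether
differentiation is absent.

## AMOVA

`amova()` partitions squared inter-individual distances into among- and
within-population components. The distance metrics are deliberately simple
mismatch counts — per-locus 0/1 condition mismatch for epiloci, non-shared
allele copies (0/1/2) for microsatellites — because these are squared
Euclidean on indicator codings, which makes the decomposition identical to
a coordinate-wise nested ANOVA; the test suite exploits exactly this
equivalence as an independent oracle. With missing loci, the mean per-locus
distance over comparable loci is rescaled to the full locus count. SNP
pools are excluded from AMOVA by type: they carry no individual
(within-population) level.

Components follow the standard unbalanced one-way random-effects
expectation with $n_0 = (N - \sum_p n_p^2/N)/(P-1)$. Negative among-group
estimates are reported as computed (a `clamp` option exists for display
only). The permutation test shuffles individual population labels, is
one-tailed on $\Phi_{ST}$ (more structure), and includes the observed
configuration via the $+1$ convention, so $p \in (0, 1]$.

## Environmental ordination

`env_pca()` performs a correlation-matrix PCA by default: the 14 river
variables mix units (m³·s⁻¹, mg·L⁻¹, %, °C), and an unscaled PCA would be
dominated by flow and altitude. Covariance PCA remains available
(`scale = FALSE`). Loading signs are made deterministic by flipping each
column so its largest-magnitude entry is positive. The default retention
rule keeps the three leading axes (`retain_components()`), and
`component_distances()` builds one predictor matrix per axis as the
absolute score difference between sites — axes are kept separate so each
gradient can be tested on its own.

## Mantel and MRM inference

`mantel_test()` correlates lower triangles and permutes rows-and-columns of
one matrix jointly; for up to 7 sites ($N! \le 5040$) the complete
permutation set is enumerated and the p-value is exact. The default
alternative is one-sided positive association, matching the directional
isolation-by-distance/environment question; two-sided is available.
Matrices are aligned by site label, never by position.

`mrm()` regresses the unfolded response triangle on any number of predictor
triangles and permutes the *response matrix only* — the standard scheme for
regression on distance matrices. Coefficient p-values are two-sided on
magnitude (the sidedness convention is recorded in reports), the $R^2$
p-value one-sided. Two properties of this scheme matter for interpretation:
under a global null it is essentially exact (the type-I tests below confirm
this), but for one coefficient in the presence of a strong true effect of
another predictor it is conservative, because permuting the response
destroys the dominant relationship and inflates the permutation spread of
every coefficient. A rejection of the environment term therefore remains
trustworthy evidence; a non-rejection is the expected outcome both under no
effect and under slight under-powering.

## The synthetic riverscape

`simulate_riverscape()` emulates the targeted study design: 13 sites, 24
individuals per site per species, ~260 four-state epiloci, 15
microsatellites with 8 alleles, 1500 pooled SNPs, 14 environmental
variables, and riparian distances as path lengths between leaves of a
random bifurcating river tree (via `ape`), which guarantees metric
distances on a dendritic network.

The environmental table mixes three latent standard-normal site gradients —
eutrophication (loading on oxygen −, conductivity +, nitrite +, nitrate +,
oxygen saturation −, BOD +, temperature +), upstream–downstream (flow,
width, pH +), and altitude/nutrient (orthophosphate, slope, altitude,
suspended matter +) — plus independent noise with SD 0.5 per standardized
variable, which leaves roughly 70% of the standardized variance on the
first three axes, the usual share for this kind of water-quality panel.
Units and locations are set to realistic magnitudes, though the PCA
standardizes them away.

Genetics follow an F-model: per-locus site frequencies are Dirichlet
deviations around ancestral frequencies with concentration
$(1-f_{gen})/f_{gen}$, additionally logit-shifted along a latent site factor
$G = g + \gamma\, z_1$ ($g$ site-level standard normal, $z_1$ the
eutrophication gradient, $\gamma$ = `gamma_env_gen`) with locus-specific
weights scaled by $\sqrt{f_{gen}/(1-f_{gen})}$, so total differentiation
vanishes as $f_{gen} \to 0$. Pool frequencies are exact by default (clean
oracle for pool-based $G''_{ST}$); binomial read noise is opt-in
(`pool_depth`). Defaults — $f_{gen} = 0.1$, $\gamma = 1$, genetic→epigenetic
coupling $\rho = 0.8$, direct environment→epigenome effect $\beta = 0$ —
produce among-population variance fractions near 15% (microsatellites) and
15–20% (epiloci), the magnitudes typical of this design; the site-level
epigenetic effect scale (`epi_factor_sd = 1`) was fixed once against that
target.

The epigenome receives a site effect
$E = \rho\, \mathrm{std}(G) + \sqrt{1-\rho^2}\, e + \beta\, z_1$: with
$\rho = 1, \beta = 0$ it is a deterministic function of the same latent
factor that shifted allele frequencies; with $\rho = 0, \beta > 0$ it is
purely environmental. Per epilocus, four-state probabilities are a softmax
logit shift of a Dirichlet baseline by a locus response times $E$, plus
small locus × site drift (`epi_drift_sd`); individuals draw states
independently from their site's vector. Condition IV is generated as an
ordinary fourth state — restriction-site loss genetics is not modeled,
consistent with treating IV as informative downstream.

Two species are independent marker draws sharing the environment and river
network; the default second species has no environmental coupling and a
weaker genetic one, enabling the comparative design (one species coupled,
one not).

What the generator does *not* emulate: linkage between loci, spatially
autocorrelated gene flow along the network (sites are exchangeable given
their latent factors), microsatellite mutation models, scoring errors and
peak-calling noise, and tissue-specific methylation. Passing tests
therefore validate the statistical machinery and the inference logic, not
robustness to those real-data features.

## Validation regimes and problem sizes

Three simulation-based validations are part of the test suite, all fully
seeded and deterministic:

* **Null calibration** — every coupling off ($f_{gen} = 10^{-4}$,
  $\gamma = \rho = \beta = 0$, site-level epigenetic effects and drift set
  to zero): every permutation test in the pipeline (both AMOVAs, four
  Mantel combinations, MRM coefficients and $R^2$) sees an exchangeable
  null. Over 200 replicates of 13 sites × 24 individuals (60 epiloci, 8
  microsatellites, 100 SNPs per replicate — calibration does not depend on
  locus counts), each rejection count at $\alpha = 0.05$ must lie in the
  exact binomial 95% band. Tests use 199 permutations, so the null
  rejection probability is exactly $10/200 = 0.05$ on the p-value lattice.
* **Spuriousness recovery** — $\gamma$ on, $\rho = 1$, $\beta = 0$, 100
  replicates at full default sizes: the marginal Mantel epigenome ~
  environment test rejects in a majority of replicates (the spurious
  association), the MRM environment coefficient stays at or below its
  nominal rate once SNP differentiation is in the design, and the MRM
  genetic coefficient rejects in ≥ 90%.
* **Direct environmental forcing** — $\rho = 0$, $\beta = 2$: the MRM
  environment coefficient is recovered in ≥ 90% of replicates, confirming
  the chain has power when the environment truly acts.

## Numerical choices and degenerate inputs

* Permutation p-values always use the $+1$ convention on sampled nulls;
  exhaustive Mantel enumeration replaces sampling at ≤ 7 sites.
* Comparisons of permuted statistics use a $10^{-12}$ slack so exact ties
  (e.g. symmetric integer matrices) count as exceedances.
* A pair of populations with no gene diversity at any locus gets
  $G''_{ST} = 0$ with a warning; an all-zero distance matrix makes
  $\Phi_{ST}$ undefined and is flagged rather than silently clamped.
* Rank-deficient MRM designs error naming the dependent predictor;
  zero-variance distance matrices error in `mantel_test()` rather than
  returning an undefined correlation.
* Distance-matrix readers symmetrize asymmetries up to $10^{-9}$ and
  reject anything larger; diagonals must be exactly zero.
* All randomized stages draw from independent named substreams derived from
  one master seed, so adding or toggling one analysis never changes
  another's p-values.

## Known limitations

* The inter-individual distance metrics for AMOVA are a documented choice;
  other software may use different four-state dissimilarities, so variance
  percentages on real datasets can differ slightly between tools.
* Plugin $G''_{ST}$ is upward-biased at small sample sizes; use
  `nei_unbiased` when absolute levels (rather than cross-marker
  comparisons) matter and individual-level data are available.
* MRM coefficient tests are conservative in the presence of strong
  co-predictors (see above); partial Mantel is not offered as a separate
  statistic since MRM subsumes it.
* Riparian distances are required as input (or simulated); deriving them
  from GIS layers is upstream of this package.
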