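---
title: "Dissecting hybrid performance and heterosis in NCII maize populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting hybrid performance and heterosis in NCII maize populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nciiqtl)
```

## The design and the problem

A North Carolina Design II (NCII) population crosses a set of recombinant
inbred lines (RILs) to a small set of elite testers. The setting this
package targets is a maize study design: ~339 F11 RILs from a biparental
cross, two testers that carry the same parental allele at about 95% of the
genotyped loci, the two derived hybrid populations (TC and TM), and 4-5
environments with two replicates each. The analysis goal is to decompose
hybrid performance and midparent heterosis (MPH) into additive, dominance
and epistatic parts — at the level of variance components, of individual
loci (QTL), and of genomic prediction.

Genotypes are coded relative to the two RIL parents: +1 for the
first-parent allele, -1 for the second. A hybrid's genotype at a locus is
inferred from its parents: if the RIL and tester alleles agree the hybrid
is homozygous (additive code Z equal to the shared allele, dominance code
W = 0); if they disagree it is heterozygous (Z = 0, W = 1). A missing
parental call propagates to a missing hybrid code.

## Phenotype stage

Trial records are long-format observations (genotype x environment x
replicate x trait). The stage applies, in order:

* **Outlier razor.** A single sweep drops observations whose externally
  studentized residual from the fixed-effect model
  `value ~ genotype + environment/replicate` strictly exceeds 2.8 (a value
  exactly at the threshold is retained). The sweep is per trait and is not
  iterated. Genotype-by-environment deviations are deliberately left in the
  residual here; a gross outlier can therefore also flag replicate siblings
  of the same genotype, which the removal log makes visible.
* **Across-environment model.** y = mu + G + E + GxE + R(E) + eps, fitted
  twice: genotype fixed for best linear unbiased estimates (BLUEs), all
  terms random (REML, via lme4) for variance components. Component
  significance uses a REML likelihood-ratio test against the
  component-dropped model with the 50:50 chi-square(0)/chi-square(1)
  boundary mixture.
* **Broad-sense heritability** on an entry-mean basis:
  H^2 = sigma2_G / (sigma2_G + sigma2_GxE / N_E + sigma2_eps / (N_E N_R)).
* **MPH.** First step: per-environment BLUEs (genotype fixed, replicate
  random); MPH = H - (P1 + P2) / 2 per hybrid and environment. Second step:
  MPH = mu + G + E + eps with G and E random; MPH heritability is
  sigma2_G / (sigma2_G + sigma2_eps / N_E) — replicates are already
  absorbed by the first step.
* **GCA/SCA.** All-random decomposition of per-environment hybrid BLUEs
  into environment, general combining abilities of RILs and testers,
  specific combining ability, and their environment interactions. With one
  BLUE per RIL x tester x environment cell the SCA-by-environment term is
  confounded with the residual and is reported as missing. The summary
  ratio is sigma2_SCA / (sigma2_GCA_RIL + sigma2_GCA_Tester); users can
  recompute alternatives from the returned components.
* **Path analysis.** Path coefficients are standardized partial regression
  coefficients, p_i = b_i s_Xi / s_Y, of the response on all other traits;
  coefficients below 0.14 in magnitude are suppressed in the display copy
  only. (An alternative reading of path coefficients as scaled by sums of
  squares is internally inconsistent with their use as standardized
  contributions, so the standardized-coefficient convention is adopted.)

## Kinship kernels

Five kernels drive the polygenic model: K_a from the additive design Z,
K_d from the dominance design W, and three epistatic kernels over marker
pairs (additive-by-additive, additive-by-dominance including its mirrored
dominance-by-additive role, and dominance-by-dominance). Design columns are
mean-imputed (missing hybrid codes) and column-centered before the
cross-products — centering puts the variance components on the familiar
genomic-relationship scale where sigma2_x is the variance contributed
across individuals. Every kernel is normalized to mean diagonal 1 so the
variance ratios are comparable across kernels.

The pairwise kernels are computed without enumerating the O(m^2) pairs,
through closed-form Hadamard identities: with G_a = Z Z' and
D_a = (Z o Z)(Z o Z)',

* raw K_aa = (G_a o G_a - D_a) / 2 (unordered pairs k < k'),
* raw K_dd analogously from W,
* raw K_ad = G_a o G_d - (Z o W)(Z o W)' (ordered pairs k != k').

The identities are exact; the test suite verifies them against brute-force
pair enumeration to 1e-10. The separately scanned additive-by-dominance and
dominance-by-additive effect types share the single K_ad background kernel,
because the polygenic model has one additive-by-dominance term.

## The mixed model, whitening and tests

The polygenic model for a trait vector y over n hybrids is

y = X beta + xi_a + xi_d + xi_aa + xi_ad + xi_dd + eps,

with xi_x ~ N(0, K_x sigma2_x), eps ~ N(0, I sigma2), and X = [1, X1]
carrying the intercept and the population indicator (0 for TC, 1 for TM).
Writing lambda_x = sigma2_x / sigma2 and
K = sum_x K_x lambda_x, var(y) = (K + I) sigma2.

Two estimation backends are provided. The default for study-scale runs is
a Gibbs sampler with scaled-inverse-chi-square priors, 15,000 iterations
and 5,000 burn-in, seeded and therefore reproducible; each component is
updated in its kernel's eigenbasis so an iteration costs a handful of
matrix-vector products. The deterministic backend is REML by direct
numerical optimization of the restricted likelihood over the lambda
ratios (profiling out beta and sigma2); the tests and the acceptance
experiments use REML because it has no Monte-Carlo error. The two agree on
variance proportions within sampling error on simulated data.

For scans, K is eigen-decomposed once per trait/dataset, K = U D U', and
the data are whitened by Q' = (D + I)^(-1/2) U'. After this transform the
residual covariance is I sigma2 exactly, so every test is an ordinary
least-squares fit. Note the **square root**: only (D + I)^(-1/2) makes
var(Q'e) = I sigma2; an inverse without the square root would whiten twice.
The lambdas are estimated once from the null model per trait/dataset and
held fixed during the scan (the two-stage practice); the tested marker's
own contribution to K is not removed, so a sparse strong signal is partly
absorbed by its own kernel — "proximal contamination". The analysis
scripts surface this honestly: a single large dominance-by-dominance pair
under a strong polygenic background appears in the variance dissection but
may not reach pair-level significance.

Per-marker tests add the whitened additive column (and separately the
dominance column) to the null model; the likelihood-ratio statistic is
LRT = n log(RSS_null / RSS_full) (maximum likelihood, since the fixed
effects differ between the models), converted to LOD = LRT / 4.61.
Pairwise tests add the element-wise product of the two whitened design
columns to the two-main-effect null, following the transformed-model
formulation. Thresholds are LOD 2.5 for main effects, 5.0 for epistasis,
and a relaxed 2.0 for the favorable-QTL analysis. Effect estimates are the
regression coefficients of the tested columns; the per-QTL variance
explained is PVE = 1 - RSS_full / RSS_null.

Because the two testers share ~95% of their alleles, most loci in the
pooled population carry only two genotype classes; there the additive and
dominance columns are affinely dependent and the two scans give *exactly*
the same LOD — the mechanism behind near-identical additive and dominance
profiles in such designs. The package tests assert this identity exactly.

## QTL calling

Interval calling is the three-step procedure: keep markers passing the
threshold; greedy peak selection in descending LOD order (ties broken by
lower cM), suppressing other significant markers within 10 cM on the same
chromosome; support interval = the contiguous region around the peak with
LOD >= peak - 1.5, snapped to marker positions (bin-level resolution is
the data's resolution). QTL across traits/datasets are merged into
pleiotropic groups (transitive closure) when intervals overlap or peaks
are within 0.65 cM — the genome-wide average bin spacing. The
peak-suppression pass is per chromosome.

For the favorable-QTL analysis, each locus at LOD >= 2.0 is classified by
comparing genotype-class means of hybrid performance: heterozygous-
favorable if the heterozygote class is best, otherwise homozygous-favorable
with the better homozygote as the favorable class. Per-hybrid counts of
favorable homozygous (r1), heterozygous (r2) and total (r3) loci are
correlated with performance.

## Genomic prediction

Prediction uses GBLUP with the additive kernel (plus the dominance kernel
except for across-population prediction): variance components by REML on
the training set, then BLUP of the test individuals through the joint
kernel. Three schemes mimic hybrid breeding scenarios:

* **CV1** — one tester population predicts the other in full
  (additive-only model);
* **CV2** — RILs are halved; training hybrids are those of the training
  RILs under both testers (training hybrids share RILs across testers);
* **CV3** — training hybrids use disjoint RIL halves across the two
  testers, so every test hybrid's RIL is seen in training under the other
  tester.

Accuracy is the plain correlation between predicted and observed test
values (not divided by the square root of heritability), two folds per
repeat, 200 repeats at study scale (reduced in the desk-scale scripts).
Weighted genomic selection (wGS) adds significant markers as fixed
effects; the fixed set is re-mapped inside every training fold from the
training phenotypes only, so marker selection can never see test data (a
construction the tests audit). Undefined correlations (constant
predictions) are recorded as missing, never as zero.

## The synthetic-data generator

No field data are distributed, so a generator produces complete synthetic
studies with known truth:

* **RIL genomes.** Each RIL is a mosaic of the two parental alleles from a
  Haldane (Poisson, no-interference) crossover process along the genetic
  map: crossover counts are Poisson with mean equal to the chromosome
  length in Morgans, positions uniform, phase alternating. RILs are
  treated as fully inbred doubled-haploid-like mosaics, so the
  recombinant fraction between two markers equals the Haldane map function
  of their distance — the simplest self-consistent oracle (the map is the
  RIL map; the generational expansion of selfing generations is not
  modeled separately). A configurable fraction of residual heterozygous
  calls (default 0.5%, as expected at F11) is flagged and set missing
  before coding.
* **Testers.** Per locus the two testers share the same parental allele
  with probability `tester_similarity` (default 0.95) and carry opposite
  alleles otherwise.
* **Phenotypes.** Observations follow exactly the model the pipeline fits:
  mu + additive + dominance + epistatic values + environment effect + GxE
  draw + replicate effect + residual. Two calibration modes exist.
  `scale = "realized"` rescales each genetic component so its realized
  variance across individuals equals the target exactly — right for
  pipeline demonstrations where the realized data should match a headline
  number. For variance-recovery experiments the model-faithful mode is
  `polygenic_truth()` + `scale = "none"`: iid per-marker effects whose
  variance is calibrated to the centered-kernel normalization constant, so
  the model-scale sigma2_x equals the target in expectation. The
  distinction matters because REML concentrates on the model scale; the
  realized variance of a kernel-typical draw is itself noisy when the
  kernel spectrum is top-heavy, and forcing it to a constant injects that
  noise back into the "truth".

Defaults mirror the study dimensions (339 RILs, 10 chromosomes, ~414 bins
per chromosome at ~0.64 cM spacing, 4 environments x 2 replicates); every
test runs at reduced sizes. The generator does not model selection, drift,
segregation distortion, genotyping error beyond residual heterozygosity,
or sequence-level data — so passing tests say the estimators recover the
generative model's truth, not that real GBS data are free of upstream
artifacts.

## Design choices in the validation experiments

* **Variance recovery** is assessed at n = 500 pooled hybrids (250 RILs x
  2 testers) on a study-length map (10 x 267 cM) with 4 x 2 trial
  records, with **unrelated testers** (similarity 0.5). With near-identical
  testers the centered dominance column is exactly collinear with the
  additive column at every shared locus, so the additive/dominance split
  is structurally unidentifiable — the same confounding that makes the
  additive and dominance scans coincide. A recovery experiment must be run
  where its estimand is identified; the scan-identity test covers the
  confounded regime.
* **Scan power** is assessed at the study's trial design: 339 RILs, 500
  markers, a QTL explaining 10% of the plot-level phenotypic variance
  (GxE 10%, residual 80%), scans on entry means with an
  additive + additive-by-additive background — the configuration the
  pipeline actually faces. Null genomes calibrate the empirical LOD 2.5
  threshold.
* **Prediction** experiments use 160 RILs, a 15%-variance major QTL over a
  25% polygenic background, CV2 with 50 repeats; at much smaller training
  sets the fold-wise re-mapping inside wGS rarely finds the locus and wGS
  degenerates to GS.

Numerical notes: kernels are accepted as PSD down to an eigenvalue floor
of -1e-8 (relative); lambda estimates below 1e-6 are truncated to zero;
rank-deficient tested columns (e.g. a marker collinear with the population
indicator, or a monomorphic marker) are flagged inestimable with LOD 0
rather than dropped silently; greedy peak ties break toward the lower cM
position; PVE is clipped at 0 if numerical noise makes RSS_full exceed
RSS_null.

## Known limitations

* The additive/dominance split in the pooled population is only as
  identifiable as the testers are different; reported splits at high
  tester similarity should be read jointly (their sum is stable).
* The pairwise interaction test follows the transformed-column product
  formulation; under a strong background rotation a sparse epistatic
  signal loses pair-level power even though its variance is captured by
  the kernels.
* The background K is held fixed during scans (no leave-one-marker-out),
  so very large single loci are partly self-absorbed.
* The generator's crossover process has no interference and no map
  expansion; MPH for the synthetic parents uses additive values only (as
  appropriate for inbreds) and the within-environment BLUE machinery.
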