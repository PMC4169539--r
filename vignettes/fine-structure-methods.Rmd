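---
title: "Detecting fine-scale population structure and selecting ancestry-informative markers"
author: "aimsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting fine-scale population structure and selecting ancestry-informative markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genetic association studies on cohorts drawn from several closely related
populations risk confounding by population stratification: allele
frequencies drift between populations, so any trait that also differs
between them produces spurious marker associations.  Genome-wide
corrections (principal components, genomic control) need thousands of
markers; replication and candidate-gene studies do not have them.  A
practical alternative is a small panel of *ancestry-informative markers*
(AIMs) genotyped alongside the candidate markers.

`aimsel` implements the full workflow for deriving and validating such
panels on biallelic SNP dosage data: structure detection by principal
component analysis (PCA) with Tracy-Widom significance, quantification of
the concordance between genetic and geographic coordinates, pairwise
Hudson Fst with a genetic-indistinctness threshold, two marker-ranking
schemes (Rosenberg informativeness and PCA-loading weights), and
K-nearest-neighbour ancestry assignment with a strict-majority fallback
ladder.  Because cohort-scale genotype data of this kind is rarely
public, the package ships a first-class simulator whose default
configurations emulate a European-origin, multi-population GWAS cohort.

# Models and statistics

## Genotype standardization and PCA

Dosages $g_{ij} \in \{0,1,2\}$ count the alternate allele.  Missing
entries are imputed to the SNP mean; each column is centred and divided
by $\sqrt{\hat p(1-\hat p)}$ with the posterior (add-one) frequency
estimate $\hat p = (1+\sum_i g_{ij})/(2+2n_j)$, which keeps
nearly monomorphic SNPs numerically stable.  The thin SVD
$X = UDV^\top$ gives sample scores $UD$, unit-norm SNP loadings $V$, and
eigenvalues $d_k^2/(n-1)$.  A deterministic sign convention (largest
score entry positive) makes runs reproducible.

## Tracy-Widom significance

Component significance uses the successive-eigenvalue test: for
component $k$ the remaining eigenvalues are renormalized, an effective
marker count is estimated from their first two moments,
$n' = (m+1)S_1^2 / ((m-1)S_2 - S_1^2)$, and the leading remaining
eigenvalue is centred and scaled by the Tracy-Widom mean and standard
deviation formulas.  P-values come from a shifted-gamma representation
of the TW1 law ($\mathrm{TW1} \approx \theta\,\Gamma(k) - \alpha$ with
$k = 46.446$, $\theta = 0.18605$, $\alpha = 9.84801$), which matches the
distribution's first three moments and is accurate to about $10^{-4}$ in
the CDF; upper-tail p-values are floored at $10^{-300}$, never
extrapolated.  Two calibration caveats, both verified in the test suite:
the test is anticonservative on within-population dosage data below
roughly 100 samples (skewed low-frequency columns inflate the top
eigenvalue), and plateaus of several near-equal structure eigenvalues
mute the successive test's power, so the "significant component count"
under-counts axes in strongly multi-population data.

## Geographic concordance

Population centroids (per-population mean scores) are compared with the
population centres' planar coordinates (equirectangular projection,
$R = 6371$ km; distortion among European centroids is below 1% relative
to great circles).  Three views are provided: Spearman correlations of
each PC with latitude/longitude; the bearing $\theta$ maximizing the
absolute Spearman correlation between the PC and the geographic
projection $y\cos\theta + x\sin\theta$ (grid step 0.5 degrees, ties
toward smaller $|\theta|$); and Mantel and Procrustes permutation tests.
The Mantel statistic is the Pearson correlation of off-diagonal
distances with joint row/column relabelling of one matrix; Procrustes
centres and unit-scales both configurations and takes
$t = \sqrt{1-m^2}$ from the SVD of $Y^\top X$, with reflections
disallowed by default because geographic orientation is meaningful.
Both tests use the add-one p-value $(1+\#\{t^* \ge t\})/(1+B)$, so p is
never zero, and both expose exact enumeration over all $n!$ relabelings
for small panels.

## Pairwise Fst and indistinctness

The Hudson estimator is computed as a ratio of sums over SNPs:
numerator $(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)$
(allele counts $n$), denominator $p_1(1-p_2)+p_2(1-p_1)$.  It is nearly
unbiased at the small Fst values typical of intra-European comparisons
and may legitimately go slightly negative; estimates are reported
unclipped.  For two Balding-Nichols populations with parameters $F_1,
F_2$ the expectation is $(F_1+F_2)/2$, the identity the parameter-
recovery tests check.  Population pairs with $\mathrm{Fst} < 0.001$
(strict) are *genetically indistinct*; assignment scoring credits a
prediction landing on a population indistinct from the truth.  The raw
pair set is used for scoring; the transitive closure is reported for
diagnostics only, since indistinctness is not transitive.

## Marker ranking

**AIMs.**  SNPs pass a mean-MAF filter (unweighted mean of the alternate
frequency across populations, folded to the minor allele *after*
averaging, strictly above 1% by default -- folding after averaging is
what lets a marker private to one of 13 populations, mean MAF 3.8%,
survive a 1% threshold while a 5% threshold would discard it).  Survivors
are scored by Rosenberg's informativeness
$$I_n = \sum_j \Big[-\bar p_j \ln \bar p_j +
  \sum_{i=1}^{K} \frac{p_{ij}}{K} \ln p_{ij}\Big],$$
natural log, $0\ln 0 = 0$, summed over both alleles; $I_n = 0$ iff all
populations share the frequency and $I_n \le \ln K$.  The ranked list is
thinned for linkage disequilibrium greedily in score order (a SNP is
dropped if its squared dosage correlation with a better, kept SNP within
1 Mb on the same chromosome exceeds 0.8), so each correlated set is
represented by its most informative member.  Stability is assessed by
leave-one-population-out recomputation and Spearman correlation with the
full ranking; a genetically outlying population produces the lowest
correlation because it contributes unique information.

**PCAIMs.**  Per component, absolute loadings are normalized to the
component maximum (top contributor = 1) and scaled by the component's
eigenvalue; a SNP's score sums these over the leading components.  The
scale is read as the eigenvalue -- a per-component scalar -- because
multiplying a scalar weight by a whole eigenvector does not yield a
rank.  The component count defaults to the Tracy-Widom-significant
number in `pcaim_scores()`; the pipeline sums across all extracted
components, following the description of the weighting scheme this
implements.  Ranked lists are then positionally cluster-pruned (1 Mb
window) so that a selection sweep dominating one component contributes
one marker, not fifteen.

## KNN ancestry assignment

Queries are assigned by Euclidean distance over raw dosages restricted
to the marker panel (no standardization -- standardizing would silently
re-weight markers); missing cells are imputed with reference marker
means, so assignments are query-independent.  The five nearest reference
samples vote; a strict majority (more than half) is required, falling
back to the nearest four, then three, then `UNASSIGNED`.  Strictness is
what gives the fallback ladder meaning: plurality voting would almost
never fail at $k=5$.  Distance ties break by reference order,
deterministically.

# The synthetic cohort

The simulator draws ancestral frequencies $p_0 \sim U(0.05, 0.95)$ and
population frequencies from the Balding-Nichols law
$\mathrm{Beta}(p_0(1-F)/F,\,(1-p_0)(1-F)/F)$, so each population's $F$
equals its expected drift-based differentiation.  On top of this sit:

* **geographic clines** -- an additive shift per 1000 km of displacement
  from the panel centroid, applied to every SNP;
* **selection-like loci** -- a small fraction (1%) of LD-block lead SNPs
  with a locus-specific amplified cline at a near-latitudinal bearing,
  emulating the strongly differentiated selection gradients that
  dominate real European AIM lists;
* **population-private loci** -- markers at a low background frequency
  everywhere except one population, emulating the near-private
  low-mean-MAF marker class; these are modelled as young, untagged
  variants and do not propagate through their LD block;
* **LD blocks** -- within a block, genotypes are copies of the lead SNP
  with per-haplotype allele flips, giving $r^2 \approx (1-2f)^2$ to the
  lead for common alleles (for rare alleles the flip noise is comparable
  to the allele variance and realized $r^2$ is lower);
* uniform missingness, and an optional two-way admixture generator for
  mixed-origin cohorts.

`study_config()` fixes the canonical 13-population European-style cohort:
Table-scale sample sizes (39-120 per population at the demo marker count
of 5000), per-population $F$ chosen so genome-wide pairwise Fst spans
roughly 0-0.014 with the FIN analogue as the clear outlier, a weakly
drifted North-Central block whose GBR-hub pairs fall under the 0.001
indistinctness threshold, clines of 0.008 per 1000 km, and the private/
selection tails above.  The small SWE analogue (39 samples) is excluded
from the 70-per-population harmonized reference by size, and the
end-to-end experiments additionally hold it out entirely to probe
assignment of a previously unseen population.  `contrast_config()` is a
compact nine-population variant for the AIM-versus-PCAIM comparison: a
strongly drifted outlier with no private tail, six unmarked background
populations sized so that at most ten samples remain outside the
reference (hence, per the validation rule, they contribute reference
mass but no scored queries), and two private-marked query populations.

What the simulator does *not* reproduce: realistic LD decay (block-copy
LD is flat within a block and absent between blocks), shared phylogeny
(population drifts are independent given the ancestral frequency, so
e.g. Scandinavian populations do not share a branch), coalescent noise,
genotyping artefacts, or case/control phenotype structure.  Passing
tests therefore demonstrate the correctness and calibration of the
statistics on data with the assumed structure, not performance on any
real cohort.

# Numerical and design choices

* Missing dosages are `NA` in the integer matrix and only become numeric
  inside computations (mean imputation for PCA and KNN; exclusion for
  frequencies and Fst).
* PLINK1 I/O is SNP-major only; the two-bit codes are read
  least-significant-pair first with 0 = homozygous A1, 1 = missing,
  2 = heterozygous, 3 = homozygous A2, and A1 is the counted allele.
  Population labels live in a sidecar panel file, with an opt-in to read
  the .fam FID column.
* K-means subcluster detection selects $k$ by mean silhouette on the top
  two PCs (20 restarts, seeded).  The acceptance floor is 0.45 because
  an unstructured 2-D Gaussian cloud already yields silhouettes of about
  0.32-0.40 under K-means; weak continuum-like structure (admixture
  gradients) requires an explicitly lower floor.
* All randomness flows from one root seed through named substreams
  (`derive_seed`), so pipeline stages are independently reproducible and
  whole runs are bit-identical; RNG state is always restored.
* Problem sizes in the shipped experiments (5000 markers and 1348
  samples for the cohort demo, 8000 x 943 for the contrast cohort,
  20000 SNPs x 400 samples for Fst parameter recovery) were chosen as
  the smallest at which the relevant estimators are comfortably inside
  their asymptotic regimes.

# Known limitations

Three desk-scale effects, all documented by failing-by-design or
calibrated tests rather than hidden:

1. **Eigenvector noise.**  Population axes whose strength is bounded by
   the Fst < 0.001 indistinctness budget sit close to the
   Marchenko-Pastur bulk edge, so their eigenvectors -- and hence PCAIM
   loading weights -- carry substantial noise; strong synthetic block LD
   additionally inflates the bulk.  At chip scale (hundreds of
   thousands of markers) the spectral gaps are far larger.
2. **Vote fragmentation.**  The strict-majority 5-4-3 ladder fragments
   across indistinct blocks of five or more populations, capping
   credited accuracy near 70% regardless of marker quality.
3. **25-marker budget.**  A 25-marker panel cannot simultaneously carry
   a drifted outlier's axis and balanced coverage of many other
   populations; the study regime this emulates filled 25 slots from
   ~500,000 candidates.

Together these explain why the qualitative outlier contrast between the
two ranking schemes reproduces only directionally and unstably at this
scale; the quantitative experiment and its outcome are in the test
suite.

# A worked run

```{r}
library(aimsel)

cfg <- study_config(seed = 1)
sim <- simulate_dataset(cfg)
design <- make_study_design(sim$dataset, held_out_pops = "SWE", seed = 1)

pca <- genotype_pca(design$reference, n_pcs = 10)
print(pca)

cent <- population_centroids(pca, design$reference$populations,
                             study_geo_panel())
concordance_report(cent, n_perm = 1000, seed = 1)

fst <- pairwise_fst(allele_frequencies(
  bind_genotypes(design$reference, design$test)))
indistinct_groups(fst)$pairs

aims <- rank_aims(design$reference)
lopo_stability(design$reference)

report <- score_assignments(
  knn_assign(design$reference, design$test, top_markers(aims, 25)),
  design$test$populations, indistinct_groups(fst)$pairs)
print(report)
```

Or, equivalently, one cached end-to-end run:

```{r}
manifest <- run_pipeline(default_pipeline_config(seed = 1),
                         out_dir = "aimsel_run")
```
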