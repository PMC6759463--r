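---
title: "Methods: population structure and association analysis of GBS germplasm panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population structure and association analysis of GBS germplasm panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gbspop` implements the post-genotyping analysis chain used for
genotyping-by-sequencing (GBS) panels of highly inbred crop germplasm, of
the kind produced for *ex situ* legume collections: SNP and sample quality
control, duplicate-accession detection, population-structure inference by
three complementary routes, Weir–Cockerham differentiation analysis,
distance trees, field-trial phenotype statistics, and kinship mixed-model
association. This vignette is the package's own account of the models, the
tunable parameters, the numerical choices, and what the bundled synthetic
generator does and does not emulate.

## The data model

Genotypes are biallelic SNP calls coded 0/1/2 (alternate-allele count) with
an explicit missing code, held in a `geno_matrix` together with the two
nucleotides segregating at each locus. Phase is ignored — GBS data from
reduced-representation libraries are unphased — and loci carry no genomic
coordinates by default, because reference-free SNP callers emit anonymous
tag pairs; coordinates found in a VCF are kept as optional metadata only.
Missing calls are never imputed at I/O time: each stage states its own
missing-data policy below. This mirrors practice for selfing crops, where
filtering is preferred to imputation.

## Quality control

Loci are filtered on three per-locus statistics computed over non-missing
calls: minor allele frequency `maf = min(p, 1-p)` with `p = mean(call)/2`;
call rate; and the inbreeding coefficient `F = 1 - H_obs/H_exp` with
`H_exp = 2p(1-p)`. Defaults are MAF > 0.05, call rate > 0.80 and F > 0.8,
all strict inequalities; samples with call rate below 0.80 (more than 20%
missing data) are then excluded. The F filter keeps loci that behave as
expected in a cleistogamous (self-pollinating) species, where nearly all
material is homozygous and an excess of heterozygous calls indicates
paralogy or miscalled tags; the per-locus `1 - H_obs/H_exp` form is the
standard definition and can be negative under heterozygote excess. The
filter cascade runs loci first (MAF, then call rate, then inbreeding —
the order is configurable and per-step attrition is reported), then
samples, and is idempotent. The transition/transversion summary counts
`{A,G}`/`{C,T}` pairs as transitions and reports the ratio to two decimals.

Linkage-disequilibrium pruning uses composite genotypic LD: r² is the
squared Pearson correlation of 0/1/2 call vectors over pairwise-complete
samples, with no imputation (missingness is at most 20% after QC). The
scan is greedy in file order — a locus is dropped when its r² with any
previously kept locus reaches the threshold (default 0.5), ties keeping the
earlier locus. There is no genomic window because anonymous GBS loci have
no positions; whether a windowed scan would prune differently is moot
without coordinates, and the greedy all-pairs policy is this package's
decision. Zero-variance loci are treated as uncorrelated with everything.

## Duplicate detection

Identity by state between two samples is the shared-allele fraction per
locus (`1 - |a-b|/2`: 1 for identical genotypes, 0.5 for heterozygote
versus homozygote, 0 for opposite homozygotes), averaged over loci where
both calls are present. Although field usage sometimes calls this an "IBS
distance", replicated genotypes score near 1, so the package standardises
on IBS *similarity*; the allele-sharing *distance* used for the individual
dendrogram is its complement.

The redundancy threshold is calibrated from biological replicates of a
pure line: threshold = mean − 3·SD of all replicate-pair IBS values. Pairs
at or above the threshold are declared redundant (inclusive comparison —
the boundary case is treated conservatively for deduplication), groups are
the connected components of the resulting graph (near-identical genotypes
justify transitive closure; disjoint groups come out naturally), and the
member with the highest call rate represents each group, ties broken by
sample-id order. Note that a published calibration of this form can be
arithmetically loose — a printed mean and SD need not reproduce a printed
threshold — so the package always applies the formula as defined rather
than any quoted end value.

## Population structure

Three routes are provided, and on well-separated material they agree.

**k-means with BIC.** Loci are mean-imputed (for this step only), centred
and scaled, and projected on the smallest set of principal components
explaining at least 95% of the variance (configurable; the PC count fed to
k-means is an open choice in this literature, and 95% keeps essentially
all structure while dropping exact collinearity). k-means runs for k =
1..40 by default with 10 random restarts, and the number of clusters
minimises `BIC(k) = n ln(WSS_k/n) + k ln(n)` on the PC scores — the
standard k-means BIC, which in practice selects the elbow of the
within-cluster sum of squares curve; a shallow minimum (improvement under
1 over its neighbours) is flagged as a diagnostic.

**DAPC.** Discriminant analysis of principal components fits linear
discriminant axes (at most groups − 1) on the PC scores. The retained PC
count is chosen by stratified cross-validation over a grid: for each
candidate count, discriminant functions are trained on the training folds
and held-out assignment error is recorded; the count with the lowest mean
error wins, ties to fewer PCs. The grid is capped so every training fit
has more samples than predictors plus groups.

**Admixture model by EM.** The classical admixture likelihood — individual
i has ancestry proportions q_i over K clusters, cluster k has per-locus
alternate-allele frequencies f_kl, and the two alleles of a genotype are
independent draws with alternate probability Σ_k q_ik f_kl — is maximised
directly by expectation–maximisation with multiplicative updates rather
than sampled by Markov chain Monte Carlo. The model and its outputs of
interest (membership coefficients, per-cluster frequencies, per-run
log-likelihoods) are identical; EM gives desk-scale runtimes and exact
reproducibility given a seed, with run-to-run variability supplied by
random restarts (default 10 per K). Missing calls are skipped exactly in
the likelihood; frequencies are clamped to [1e-6, 1 − 1e-6]. Iteration
uses squared-extrapolation (SQUAREM-style) acceleration of the EM map,
safeguarded by rejecting any extrapolated step that does not improve on
the plain double EM step, so the recorded log-likelihood is monotone
non-decreasing — an invariant the tests assert at every iteration.
Convergence is declared when the improvement falls below 1e-4.

The number of clusters is selected by the Evanno delta-K statistic over a
contiguous K range with repeated runs per K: per run, L″(K) is the second
difference of the log-likelihood across K, and ΔK(K) is the mean of |L″(K)|
over runs divided by the standard deviation of L(K) across runs. Boundary
K values and zero-SD cases are reported as undefined rather than silently
dropped. Samples are assigned to their majority cluster only when the
membership coefficient strictly exceeds 0.6; otherwise they are classified
admixed. The synthetic generator draws admixed ancestry vectors from a flat
Dirichlet truncated to a maximum component of 0.6, so planted admixed
individuals fail the rule by construction.

LD pruning is applied upstream of both k-means and the admixture model, to
meet the likelihood's assumption of independent loci and to stop clusters
being driven by blocks of autocorrelated tags.

## Differentiation and trees

Weir–Cockerham variance components a (among populations), b (among
individuals within populations) and c (within individuals) are computed per
locus from group sizes, allele frequencies and *observed* heterozygote
frequencies — no Hardy–Weinberg assumption, which matters in a selfing
crop where H_obs is near zero. Multi-locus θ is the ratio of summed
components Σa / Σ(a+b+c), never the mean of per-locus ratios. Per-locus
one-vs-rest θ screens each cluster against the pooled remainder for
distinctive alleles; estimates are reported unclamped (negative values are
legitimate sampling noise, and clamping would bias the screen's null
behaviour), with flags at θ > 0.8 and θ > 0.95 and the enriched allele
recorded. θ reaches 1 exactly when the two groups fix different alleles
(analytically a = 0.5, b = c = 0 for equal group sizes), which the tests
verify.

Nei's (1972) standard distance is computed from group allele frequencies,
with the 1972 form chosen over the 1978 small-sample correction (the
variant is a documented choice; group sizes here make the difference
negligible). Neighbour-joining trees (Saitou–Nei) are built on the Nei
matrix; NJ can produce negative branch lengths on non-additive input, and
these are clamped to zero with the difference moved to the adjacent
branches, preserving additive input exactly. Bootstrap support resamples
loci with replacement — the standard phylogenetic bootstrap over
characters — and labels each internal bipartition of the full-data tree
with its replicate percentage. Individual-level relationships use the
allele-sharing distance (1 − IBS) under Ward agglomeration in the
`ward.D2` convention (squared distances inside the variance criterion),
recorded in the result.

## Phenotype statistics

Field-trial traits follow a randomised complete block design. Per trait,
a two-way additive model (genotype + block) is fitted on plot data with
Type-II sums of squares (identical to the sequential decomposition when
balanced, exact there to 1e-9 in the tests); the genotype effect is tested
by F = MS_G/MS_E. Broad-sense heritability is reported on an entry-mean
basis, `H² = σ²_g / (σ²_g + σ²_e/r)` with `σ²_g = (MS_G − MS_E)/r` and r
the replicate count — the standard form for replicated germplasm trials;
negative variance estimates are clamped to zero with a warning.

Cluster comparisons use genotype means over blocks as the analysis units
(cluster-level tables report mean ± SD across accessions, so accessions —
not plots — are the exchangeable units), then one-way ANOVA and
Tukey–Kramer studentized-range comparisons, exact for unequal cluster
sizes. The compact letter display is assembled by insert-and-absorb from
the significant pairs, so clusters sharing no letter differ at the chosen
level; the display is independent of cluster labelling order. Traits are
tested independently, with no cross-trait correction, matching
trait-by-trait reporting practice.

## Kinship mixed-model association

The association model is `y = Xβ + u + e` with `u ~ N(0, σ²_g K)` and K
the IBS similarity matrix — used as-is, no centring or allele-frequency
rescaling (a deliberate choice; a flagged variant can be added by passing
a transformed matrix). Trait input is the genotype mean over blocks, since
seed traits are typically measured once on bulked seed. Variance
components are estimated once per cofactor set by REML through the
spectral decomposition of K, a one-dimensional search over the variance
ratio on a log grid refined by golden-section optimisation; every marker
is then tested by generalised least squares with the fitted covariance
(Wald t-test with per-marker residual scale). With K = I this reduces
*exactly* to ordinary least squares, which the tests check to 1e-8.

The multi-locus procedure is forward selection gated by false discovery
rate: scan, Benjamini–Hochberg-adjust, and while the best marker's
q-value is below the threshold (default 0.05), add it as a fixed cofactor,
re-estimate variance components, and rescan, up to a step cap (default
10). A proprietary "multi-locus mixed model" of this class does not
publish its stopping rule; the FDR gate is chosen to match the declaration
rule stated with it, and both the cap and the gate are exposed as
parameters. Markers collinear with the chosen cofactors are skipped and
logged rather than silently dropped.

## The synthetic generator

`simulate_genotypes()` draws ancestral allele frequencies from
Uniform(0.05, 0.95) and population frequencies from the Balding–Nichols
Beta distribution, which parameterises differentiation directly by the
quantity the pipeline estimates (the fixation index F against the
ancestral pool) — the reason it was chosen over coalescent simulation,
whose extra realism (drift trajectories, mutation models) is irrelevant to
parameter-recovery testing and costs orders of magnitude more time.
Individuals are inbred by doubling a single allele draw with probability
F_IS; admixed individuals draw a population of origin per locus from a
truncated-Dirichlet ancestry vector; duplicate groups copy a source sample
and corrupt each call with a small error probability; missing data is
masked uniformly at random.

The default spec emulates a Mediterranean lentil germplasm panel: 185
accessions (five subpopulations of 34/34/33/33/32 plus 19 admixed),
differentiation parameters 0.35/0.30/0.25/0.22/0.20 giving pairwise
fixation indices of roughly 0.2–0.35, selfing inbreeding 0.95, 3,000
loci, 5% missing data, planted replicate groups at 1% genotype error, and
six field-trial traits (flowering time in days; plant and
first-flowering-node height in cm; seed area in mm², perimeter and
diameter in mm) whose per-cluster means are typical of such panels, e.g.
cluster seed diameters 3.8/4.5/5.6/4.7/4.6 mm. The three seed-size traits
share a latent per-genotype size deviate and a common large-effect causal
marker, so they are positively correlated and associate with the same
locus, as morphometrics measured on one seed lot do.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: hierarchical population structure (the
Balding–Nichols populations are exchangeable draws around one ancestral
pool, so nested splits and multi-level ΔK signals cannot be planted);
linkage and recombination (loci are independent, so LD pruning on
synthetic data removes only chance correlations); genotyping-error
structure correlated with read depth; site-frequency-spectrum realism; and
selection. Conclusions about those features require real panels.

## Numerical choices and problem sizes

Seeds are explicit everywhere; multi-run procedures derive per-run seeds
from one master seed so streams are independent but reproducible, and all
derived seeds stay below 2³¹. Ties in k-means restarts resolve by best
within-cluster sum of squares; ties in the DAPC grid resolve to fewer PCs;
ties in redundancy representatives resolve by sample-id order. Degenerate
inputs (monomorphic loci in θ, zero-variance loci in LD, undefined IBS
pairs, zero run-SD in ΔK) are flagged or skipped explicitly, never
silently zeroed.

The test suite exercises the estimators at sizes chosen to make the
statistics decisive while keeping the whole suite in the minutes range:
parameter-recovery runs use 2–5 populations of 20–100 samples and
300–2,000 loci, ten seeds where a claim is distributional; the
cluster-number check uses the full 5 × 40 × 1,000 design; the
mixed-model null uses 500 markers by 20 seeds. These sizes are the
package's choices for decisive-yet-quick checks, and all scale linearly
if users wish to rerun them larger.
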