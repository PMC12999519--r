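---
title: "Methods: detecting developmental convergence and upstream regulator modules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting developmental convergence and upstream regulator modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Rare mutations associated with autism spectrum disorder are genetically
heterogeneous, yet transcriptomic studies repeatedly find shared
downstream dysregulation. Cohorts of patient-derived cortical organoids
make it possible to ask *when* during differentiation distinct mutations
begin to look alike, and *what* sits upstream of the shared signal.
`convorg` implements the full analysis chain for that question: bulk
RNA-seq preprocessing, per-gene mixed-model differential expression with
cross-form meta-analysis, convergence statistics over differentiation
time, robust consensus co-expression networks with a kME-weighted
module-to-module regulation score, cell-type deconvolution, a
permutation connectedness test for IP–MS protein networks, and CROP-seq
style CRISPRi validation. Because the cohort data such a study rests on
are access-restricted, the package ships generators that emulate the
cohort's statistical structure with a complete ground-truth record, so
every stage can be exercised and validated by parameter recovery.

# The synthetic cohort

`simulate_cohort()` draws negative-binomial counts with
`Var = mu + alpha * mu^2` (dispersion `alpha`, default 0.1; below 1e-8
the sampler falls back to Poisson). The log2 mean of gene *g* in sample
*s* combines:

* a log-normal baseline (mean 6, SD 1.5 on the log2 scale), a per-gene
  linear maturation trend over days (SD 0.3), and per-sample depth
  (log-normal, SD 0.2);
* planted co-expression modules: one latent factor per module per
  sample, loadings drawn uniformly in 0.4–0.8 (eight modules of 40–80
  genes by default);
* per-day form effects with the convergence schedule: for day *d* with
  shared fraction `s_d`, the effect is
  `(1 - s_d) * specific(g, form) + s_d * shared(g)`, both components
  N(0, 0.5) on the log2 scale. The expected cross-form correlation of
  the planted effect vectors is `s_d^2 /(s_d^2 + (1 - s_d)^2)` for equal
  SDs, monotone in `s_d`; the default schedule (0.1, 0.3, 0.6, 0.9)
  plants convergence that grows with differentiation;
* CNV dosage: per non-control form, a disjoint gene set shifted by
  `log2(dosage)` (0.5 for a deletion, so −1);
* repressive regulators: genes of module 1 annotated as regulators whose
  targets, concentrated in modules 2–4 (60 % of their genes), lose
  `0.25 x` module-1 activity — producing negative regulator–target
  correlations and a planted module-1 → {2, 3, 4} regulatory hierarchy;
* nested random intercepts per individual (SD 0.3), line (0.15) and
  differentiation (0.15), and small sex/batch/PC covariate effects.

The default design is nine disorder forms plus a control group, four
days (25, 50, 75, 100), and three individuals per form (one line, one
differentiation each), i.e. 120 samples of 2,000 genes — large enough
for network recovery, small enough for a desk-scale run. Companion
generators produce a single-cell reference with disjoint planted
markers, an IP–MS bait × prey logFC table with a planted clique, a
CROP-seq screen with guide-level UMI counts (including sub-threshold and
multi-guide cells), and a motif-scan-style regulator annotation with a
configurable false-positive rate.

What the generator does **not** emulate: GC/length biases (hence TMM
log2-CPM replaces conditional quantile normalization), isoform
structure, batch-by-day interactions, doublets, and any genomic
coordinates (CNVs are gene sets). Passing recovery tests therefore shows
the machinery is correct and calibrated on data with the assumed
structure — not that real organoid data satisfy those assumptions.

# Preprocessing

Genes with fewer than 10 reads in 30 % of a group's samples are removed;
the boundary is inclusive (exactly 30 % supporting keeps the gene),
matching the common filtering convention, and both the threshold and the
grouping are arguments. Normalization is trimmed-mean-of-M-values via
edgeR with log2 CPM on effective library sizes and a pseudocount of 0.5
(configurable). Outliers are flagged by standardized sample-network
connectivity (sum of inter-sample correlations within day × form,
Pearson by default) below −2; a single pass is the default, with
`iterate = TRUE` available since it is genuinely unclear whether such
screens should be repeated until stable. Covariates are removed by
per-gene least squares with the gene mean restored. Variance fractions
come from per-gene variance-component fits (lme4): random intercepts for
categorical terms, fixed slopes for continuous ones, fractions
normalized to sum to one.

# Differential expression

Each gene is fit by REML with one random intercept (individual by
default; line, differentiation and so on are available through
`random_group`). A single grouping factor keeps the fit exact and fast:
the covariance is diagonalized once for all genes, and the REML
criterion is profiled over the variance ratio on a fixed log-spaced grid
(41 points spanning 1e-4 to 1e4 plus zero) simultaneously across genes.
The grid resolution affects standard errors only through the smooth
dependence of the weights on the ratio; tests against `lmer` agree to
three decimals on the fixed effects. When no group has two members the
model degenerates to ordinary least squares with the OLS residual
degrees of freedom; otherwise Wald tests use the residual-df
approximation `n - p - q + 1` rather than a Satterthwaite correction — a
documented divergence from crossed-random-effects fits, acceptable
because the approximation delivers calibrated type-I error at this
design's sample sizes, which the test suite verifies by simulation.

Contrasts compare each form with control at each day, with BH within
each (form, day). The meta-analysis across forms is the inverse-variance
fixed-effect combination per gene and day (`beta = sum(w b)/sum(w)`,
`se = 1/sqrt(sum w)`), BH within day; whether idiopathic-like forms are
pooled is left to `exclude_forms` since the defaults pool every
non-control form.

# Convergence statistics

Condition signatures (form × day logFC vectors over the shared gene
universe) are correlated with Spearman's rho and clustered with Ward.D2
on Euclidean distances of the correlation rows. Cluster support uses
multiscale bootstrap: at relative scales 0.5–1.4 genes are resampled
with replacement, BP is the per-cluster recurrence frequency, and AU
comes from the weighted probit fit `qnorm(1 - BP_r) = v sqrt(r) +
c/sqrt(r)` with inverse-variance weights; frequencies of exactly 0 or 1
are clamped to `1/(2B)` before the probit. The bootstrap budget is split
evenly across scales because the total-versus-per-scale convention is
ambiguous; both BP and AU are reported since either can serve as the
headline support measure. Concordance across clustering procedures uses
cophenetic correlations and the plain Rand index on k-cluster cuts, plus
gene-subsampling repeats.

The convergence trend itself is deliberately simple: for each day, the
Spearman correlation of every unordered pair of forms (36 values for
nine forms), then a one-way ANOVA of rho on day with Tukey HSD. The rho
values enter untransformed, matching the descriptive use of the trend; a
Fisher z-transform is available behind a flag. Note that all forms share
the control samples, so per-day correlations carry a common positive
offset from shared estimation noise — the trend across days, not the
absolute level, is the signal.

# Consensus networks and modules

Signed adjacency `((1 + cor)/2)^beta`; the soft power is the smallest
one (scan 1–20) whose connectivity histogram fits a power law with
signed R² above 0.8. Topological overlap follows the standard
`(shared neighbours + a_ij)/(min(k_i, k_j) + 1 - a_ij)` form, verified
against a triple-loop oracle to 1e-10. Robustness to outlier samples
comes from form-balanced resampling: each iteration resamples every
form's samples with replacement to their original count, re-drawing
until at least four distinct samples per form are present, and the
consensus is the element-wise median of the TOM dissimilarities (the
median is computed in compiled code; medians of dissimilarities and
1 − median of similarities coincide by monotone equivariance). Twenty
resampled networks are the synthetic-scale default; the study-scale 100
is one argument away.

Module detection is a simplified hybrid tree cut, not a port of the
published dynamic algorithm: an average-linkage tree on the consensus
dissimilarity is decomposed into branches below the detection cut
height; a branch splits recursively when both children reach
`min_module_size * (1 - deep_split/6)` genes; when only one side is
substantial the small side is shaved off (left for kME adoption) and
descent continues into the dominant branch. Unassigned genes with best
kME ≥ 0.3 are adopted; modules whose eigengenes correlate above
`1 - cut_height_merge` merge iteratively. The simplification is
validated by planted-module recovery (adjusted Rand ≥ 0.8 across
20 seeds) rather than label-exact equality with any particular
implementation. Recovery is scored over the planted-module genes: the
generator's form and shared effects give non-module genes genuinely
correlated variation (that is the convergence signal), so those genes
can legitimately co-cluster in ways the truth labels do not encode; the
question the metric answers is whether the planted modules come out
intact and separated.

Eigengenes are first principal components of standardized module
submatrices, oriented so own-module mean kME is positive. Module–trait
association fits `ME ~ form` (control as base) and `ME ~ diagnosis`,
reporting `sign(sum of coefficients) * sqrt(max(adjusted R^2, 0))`; the
signed adjusted R² itself is available via a flag because "adjusted R"
is ambiguous, and downstream code treats the quantity as descriptive
only. Trajectories use a quadratic polynomial spline of day (df 2,
degree 2) interacting with a form-versus-control indicator, tested by F.
Preservation is a two-statistic lightweight analogue of the full
permutation suite: within-module adjacency density and the
reference-versus-test correlation of intramodular connectivity, each
z-scored against label permutations; when test and reference coincide
the connectivity null is degenerate and that component is dropped.

# The regulation score

For ordered modules U → V the score is the sum of kME values (with
respect to V's eigengene) of V genes that are annotated targets of at
least one high-confidence regulator residing in U, divided by the size
of V. Genes count once regardless of regulator multiplicity, and
negative kME values enter as-is since the formula does not restrict
sign. Edges require the score to strictly exceed one standard deviation
above the mean over all ordered pairs (U ≠ V); the population
(n-denominator) SD is the default and the sample SD a flag, a choice the
printed threshold of the motivating analysis cannot adjudicate. The
threshold is computed per network, i.e. per day when networks are built
per day.

# Deconvolution, enrichment, PPI and CRISPRi

Deconvolution builds per-type mean-CPM signatures restricted to top
specificity markers and solves non-negative least squares per bulk
sample, renormalizing to the simplex. Marker genes are weighted by the
inverse of their signature row mean — the generalized-least-squares
weighting when expressed genes share a roughly constant coefficient of
variation, as in bulk RNA-seq — and the signature is column-normalized
for solver conditioning. This replaces a learned bulk/single-cell transform because the
synthetic setting controls the moments that transform would estimate;
noiseless mixtures are recovered to 1e-6 and 10 %-CV noise keeps the
maximum absolute error within 0.05. Proportion changes are tested on the
adjusted logit (`a = 0.001`) with the same mixed-model machinery as
gene-level DE.

Fisher tests use the minimum-likelihood two-sided rule (summing
hypergeometric probabilities not exceeding the observed table's), with
a Haldane 0.5 correction on the sample odds ratio when a cell is zero.
The cell-type bootstrap draws same-size background sets and uses the
add-one p-value rule, so p is never zero; null uniformity is checked by
KS. IP–MS connectedness is the mean bait × member logFC with zeros kept
for undetected pairs and bait self-entries excluded; the null draws
size-matched sets from the universe excluding the tested set (and baits,
both flagged), 10,000 permutations by default, z against the null
moments and a normal two-sided p. CROP-seq assignment collapses guides
to targets before requiring uniqueness (two guides of one target still
assign, per the target-level reading of "one and only one"; guide-level
uniqueness is a flag), with the UMI ≥ 10 threshold applied per guide
before collapsing. Pseudobulk DE sums counts per arm × replicate and
uses a moderated two-sample test on log2 CPM (limma), validated by
type-I calibration and planted-effect recovery rather than numeric
equality with any count-model test.

# Numerical choices and limitations

Determinism: every generator and every stochastic stage takes a seed;
identical seeds give identical output. Ties in peak-day calls go to the
earliest day; hierarchical clustering inherits R's deterministic merge
order. Degenerate inputs error early and name the offender (all-zero
samples, constant genes, rank-deficient designs, missing factor levels).
Problem sizes in the tests and the acceptance script (2,000 genes, 120
samples, 20 resampled networks, 100–10,000 permutations) are the
package's synthetic-scale choices; study-scale parameters (minimum
module size 160, deep split 4, 100 resamples, 100,000 bootstrap draws)
are reachable through the same arguments. Known limitations: a single
random intercept rather than crossed random effects; no blockwise
decomposition for very large gene sets; a single shared deconvolution
reference per run; and the consensus stores all resampled TOM matrices
in memory, which bounds practical gene counts to a few thousand per run.
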