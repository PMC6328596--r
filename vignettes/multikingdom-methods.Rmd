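---
title: "Models and methods for multi-kingdom microbiome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-kingdom microbiome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mkmicrobiome)
```

This vignette is the package's own account of the statistics it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations. The README shows a worked example; the test
suite and `scripts/acceptance.R` compute every empirical claim made here.

## The data and the depth problem

The observation unit is a sample: one organ (leaf or root) of one replicate
plant of one inbred accession, sequenced with kingdom-specific primers, so
each plant contributes up to two samples per kingdom. Counts are reads per
phylotype. Sequencing effort varies enormously between samples and between
kingdoms, and every model in the package treats it the same way: the log of
the sample's total reads enters count GLM(M)s as an offset, fixing its
coefficient at one. Resampling to a fixed depth (`rarefy()`, without
replacement from the realized read pool, so retained rows sum exactly to
the target) is used only where a common scale is structurally required —
the correlation networks and visualization-style diversity summaries — and
the default depth of 400 reads reflects the shallower, more multiplexed
fungal libraries.

## Organ enrichment

`fit_enrichment()` fits, per taxon,

    count ~ organ + block + run + offset(log N)

with a Poisson likelihood (IRLS, convergence 1e-10). The enrichment is the
rate ratio `exp(beta_organ)` with leaf as reference. In the balanced
two-sample case without covariates it collapses to the ratio of relative
abundances exactly, which is how the worked examples in the acceptance
suite check it against printed values. Wald p-values are the default (a
likelihood-ratio alternative is a flag) and no multiple-testing correction
is applied at this stage. A taxon entirely absent from one organ sits on
the boundary of the parameter space: the point estimate is reported as 0 or
infinity with `boundary = TRUE`, and the p-value from the separated fit
should not be trusted — we flag rather than print a spurious zero.
Mean per-sample relative abundances and pooled proportions are both
reported; they differ under unequal depths and the table does not say which
a given published table used.

## Diversity

Richness is the count of observed taxa. `fit_richness_glmm()` fits a
Poisson log-link GLMM by Laplace approximation (`lme4::glmer`, the fitter
this literature itself uses):

    richness ~ block + run + offset(log N) + (1 | accession)

with kingdom added as a fixed effect and run nested in kingdom when the two
kingdoms are stacked (each kingdom is sequenced on its own runs, so run
labels are only meaningful within kingdom). Accession BLUPs are the
conditional modes of the random effect; they shrink toward zero as the
accession variance vanishes. `kingdom_preference()` is the per-accession
difference of bacterial minus fungal richness BLUPs — positive values mark
hosts relatively more permissive to diverse bacterial communities.

An important misspecification to know about: richness is *not*
proportional to reads — it saturates — so the unit-coefficient offset is
only adequate when per-sample depths vary moderately (coefficient of
variation up to roughly 0.3 in our simulations). Under the heavy dispersion
typical of 454-era libraries the lack of fit, which correlates with depth,
can dominate the accession signal in the BLUPs. The recovery tests
therefore run in the moderate-dispersion regime where the fitted model
matches the generating model; with real data of highly dispersed depth the
richness BLUPs should be interpreted cautiously (real communities with
hundreds of mostly-rare phylotypes sit closer to the proportional regime
than small simulated communities do).

Whittaker's beta for a pair of samples is `S / alpha_bar - 1`, with `S` the
union richness and `alpha_bar` the mean of the two richnesses. This form
lives in [0, 1]: identical presence sets give 0 and disjoint non-empty sets
give 1, which is the only variant consistent with published values below
one. It is symmetric and invariant to taxa absent from both samples.
`beta_pairs()` averages over unordered within-group pairs;
`beta_paired()` links each plant's leaf and root sample via `plant_id`.

## Correlation networks

`correlation_matrix()` computes Pearson correlations among the top-`n`
best-sequenced taxa of each kingdom (default 100 per kingdom, ranked by
total reads with lexicographic tie-breaks) on a rarefied table, with
two-sided p-values from the t transform with `n - 2` degrees of freedom —
the same computation as the `rcorr` routine this literature cites.
Zero-variance taxa have undefined correlations and are excluded from
graphs. `build_network()` draws an unweighted, undirected edge wherever
`p < edge_alpha` (default 0.01), keeping the correlation sign for display;
degree and betweenness come from igraph on the unweighted graph, because no
weighting scheme is specified in this methodology and signed or weighted
betweenness would be a different statistic. Under independent taxa the edge
fraction calibrates to `edge_alpha`, which the acceptance suite measures.
Note that rarefied counts are compositional: with few taxa the closure
induces a small negative dependence (order `-1/(T-1)`), so calibration
checks simulate independent Poisson counts rather than multinomial draws.

## BLUP ordination and Procrustes

`abundance_blups()` fits the abundance GLMM per taxon (same fixed effects
and offset as the richness model) and collects accession conditional modes
into an accessions × taxa matrix — the "genotypic" view of the community
with replicate and design noise shrunk away. PCA is centered and
unit-variance scaled; zero-variance columns are dropped; the sign of each
PC is fixed by making its largest-magnitude loading positive so results are
reproducible. Non-converged taxon models are flagged, and excluded from
PCA when more than 1% of columns failed (zero-imputing a rare failure is
harmless; imputing many would manufacture structure).

`procrustes_test()` implements symmetric Procrustes: both score matrices
are centered and scaled to unit Frobenius norm, the optimal rotation comes
from the SVD of their cross-product, `m² = 1 − (Σ singular values)²`, and
`r = √(1 − m²)`. Significance is by permuting the accession rows of one
configuration with `p = (#{r_perm ≥ r_obs} + 1)/(n_perm + 1)`, so 999
permutations floor at 0.001. The implementation is cross-checked in the
tests against `vegan::protest` to 1e-10; `vegan` is never the
implementation. Because a community-wide accession effect is only
identifiable up to the compositional closure, per-taxon BLUPs recover
taxon-specific effect architecture well (the acceptance suite measures the
correlation with simulated truth) but absorb a shared axis only as
contrasts between taxa.

## The host-genotype grid

The question is whether replicates of the same accession cluster in
ordination space, and how the answer depends on how much of each community
is included. `nested_subsets()` takes the top `⌈f·T⌉` taxa by total reads
for each fraction `f`, so subsets are nested. Each cell of
`grid_scan()` then: (1) rescales counts to a common depth and applies
`log1p` (a raw-scale option exists; log1p is the default because PCA with
unit-variance scaling on heavily skewed counts is otherwise dominated by a
few samples), (2) residualizes every taxon on block and run, (3) runs PCA
with unit-variance scaling, and (4) computes
`R² = SS_between-accession / SS_total` over the first `n_pcs` score
columns jointly.

Significance is by label permutation **within block strata**. This is a
deliberate refinement: in a randomized block design each accession's
replicates are balanced over blocks, and block residualization leaves a
within-block negative correlation behind. Freely permuted labels lose the
balance, systematically deflating the permuted statistic and inflating the
test (we measured a null rejection rate of 0.10–0.14 at nominal 0.05 with
free permutation, and 0.05 with stratified permutation — the acceptance
suite re-measures the latter). Stratified permutation is the standard
restricted-permutation remedy. The default fraction axis is
{1, 2, 3, 4, 5, 10, 25, 50, 100}% to keep desk-scale runtime; the full
1–100% axis is a parameter. p-values use the same `(r+1)/(n+1)`
convention, n_perm defaulting to 999.

## Kinship, heritability, GWAS

`kinship()` builds the standardized genomic relationship matrix
`K = Z Z'/m` from mean-0, variance-1 SNP columns; "identity by descent"
estimators differ in detail and the construction is tagged on the object so
alternatives can be added. Inbred lines are coded haploid 0/1;
heterozygous VCF calls are set missing by default (or rejected), SNPs
missing in more than 20% of accessions are dropped, and remaining gaps are
mean-imputed.

`reml_h2()` fits `y = μ + g + e`, `g ~ N(0, σ²_g K)`, by restricted
maximum likelihood profiled to one dimension on the spectral decomposition
of `K` — the classic single-kinship trick — optimizing the log variance
ratio on [−12, 12] with tolerance 1e-8 and comparing the interior optimum
with the boundaries. Estimates at the boundary are flagged. Two practical
caveats the tests document: with few accessions or a weakly structured
kinship (few SNPs, no population structure) `h²` is weakly identified and
its sampling distribution is diffuse even under the null; estimates
concentrate once the SNP panel is dense and the panel structured, which is
the regime of a worldwide inbred panel genotyped at millions of SNPs.

`broad_sense_h2()` partitions the GLMM's linear-predictor variance:
`H² = σ²_accession / (σ²_fixed + Σσ²_random + σ²_dist)`, with `σ²_fixed`
the variance of the fixed-effect predictor (offset excluded) and the
log-link distribution-specific variance `ln(1 + 1/λ̄)` evaluated at the
mean fitted rate — the conditional-minus-marginal decomposition used for
GLMM R². It answers "how much does the accession identity explain",
regardless of whether the effect is additive in SNPs; `reml_h2()` answers
the SNP-linear version, and the two can legitimately disagree.

`gwas_scan()` estimates the variance components once on the null model,
then tests each SNP by generalized least squares under
`V̂ = σ̂²_g K + σ̂²_e I`, working in the eigenbasis of `K` so every SNP
costs one weighted regression. Genomic-control λ (median χ² over its null
median) is always reported; the acceptance suite verifies λ ≈ 1 under a
structured null where naive per-SNP regression inflates.
`cholesky_perm_threshold()` computes genome-wide significance by whitening
the phenotype with the Cholesky factor of `V̂⁻¹` (making its entries
exchangeable), permuting, back-transforming, rescanning, and taking the
empirical α-quantile of per-permutation minimum p-values; it reduces to
plain phenotype permutation at `K = I` and tracks the Šidák bound for
independent SNPs. Fewer than 20 permutations are refused because the
quantile is unstable. The default of 100 permutations is a desk-scale
choice; report Bonferroni alongside if in doubt.

`window_summary()` bins SNPs into half-open 10-kb windows
(`⌊pos/w⌋`, 0-based) and keeps the minimum p per window;
`overlap_windows()` joins two traits' windows for overlap plots.
`go_tail_enrichment()` scores each gene by the best SNP p within the gene
body ± 10 kb, takes the top 1% of genes (ties broken by gene id), tests
each GO category hypergeometrically for tail over-representation, and
corrects with Storey q-values: `π₀` estimated on the λ grid 0.05–0.95
(step 0.05) with a df-3 cubic smoothing spline evaluated at λ = 0.95,
clamped to (0, 1]; q-values monotonized from the largest p downward.
Forcing `π₀ = 1` reproduces Benjamini–Hochberg exactly, which the tests
assert. Categories with fewer than two scored genes are excluded.

## The synthetic-data generator

`simulate_community()` emulates the study design the package targets: 196
accessions × 4 replicate plants, leaf and root sampled from each, two
kingdoms sequenced separately, blocks confounded with nothing (replicates
rotate through blocks), runs assigned at random, and per-sample depths
lognormal with parameters moment-matched to means ± sd of 2524 ± 1594
(bacteria) and 562 ± 726 (fungi) reads — only the first two moments of the
real depth distributions are public, so lognormal is an assumption. For
each taxon the log-rate is

    eta = mu + a[accession] + o[organ] + b[block] + c[run] + F L' + e

and counts are Poisson conditioned on the sample's depth, i.e. multinomial
with probabilities `softmax(eta)`, so depth is conserved exactly.
Baseline log-abundances `mu ~ N(0, mu_sd = 1.5)` give a realistic uneven
rank-abundance curve; latent factors `F` (2 per sample, loading sd 0.3)
induce the mildly positive-skewed cross-taxon correlations; `e` is
log-scale overdispersion (sd 0.4).

Accession effects are polygenic: each taxon has its own causal SNPs, and a
fraction `shared_fraction` (default 0.5) of each taxon's accession-effect
variance rides on a single kingdom-wide polygenic score with taxon-varying
loadings that lean on baseline abundance. Two facts force this
architecture. First, a shared axis with *uniform* loadings would cancel
exactly under the multinomial closure — only compositional contrasts are
observable. Second, with purely independent per-taxon effects, community
*richness* is nearly non-heritable (effects on individual taxa wash out of
the presence/absence sum), leaving the heritability stages nothing to
recover; a dominance/evenness axis — hosts differing in how strongly their
community is dominated by its abundant members — moves observed richness
at fixed depth, and community-wide host effects are exactly the biological
claim this analysis tradition makes. Effects are rescaled per taxon so the
realized variance fraction of `eta` attributable to accession equals the
target `h2`, and infeasible targets (no non-genetic variance to balance)
error before sampling. The truth record stores every component and
`reconstruct_eta()` rebuilds the linear predictor bit-exactly in tests.

What the generator does **not** emulate: taxonomic lineage structure
(simulated taxa carry no lineages), raw reads, chimera/denoising artifacts,
the real depth distributions beyond two moments, phylogenetic correlation
among taxa, and any specific published effect sizes. Passing recovery
tests therefore show the estimators are correct under the stated model,
not that real data satisfy that model.

## Problem sizes in the test and acceptance runs

The suites choose sizes that keep the full run in tens of seconds to a few
minutes on one core while preserving the design features each check needs:
unit tests use 8–50 accessions with 2–4 replicates and 5–60 taxa;
calibration suites use 100–150 replicate null datasets with 49–99
permutations; recovery checks run the full 196 × 4 design with 30–60 taxa,
400–3000 SNPs, and 10–50 seeds. The heritability-ordering check uses a
5-cluster, Fst 0.15, 3000-SNP panel, standing in for a worldwide panel's
dense genotyping.

## Known limitations

- Pearson correlations on rarefied counts are not
  compositionality-corrected; that matches the target methodology, but
  SparCC-style estimators would be the robust alternative.
- The Poisson family is assumed throughout; overdispersed alternatives
  (negative binomial) are out of scope by design.
- The richness offset misspecification under extreme depth dispersion
  (above) is a genuine caveat for both this package and the methodology it
  implements.
- `reml_h2` with a single kinship component cannot separate non-additive
  accession effects from noise; `broad_sense_h2` can, which is one honest
  reason the two orderings may differ on the same data.
- The GO tail test treats genes as exchangeable units; gene length and SNP
  density bias (longer genes get more chances at a small minimum p) is not
  corrected beyond the fixed flank window.
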