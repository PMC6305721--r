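---
title: "Methods: virome profiling, viral types, biomarkers and co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virome profiling, viral types, biomarkers and co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutviromics)
```

This vignette documents the statistical models and procedures behind each
stage of the package, the tunable parameters and their defaults, the
design of the synthetic-community generator, and the numerical choices a
maintainer should know about.

## Abundance profiling

Read mapping to a viral contig database yields a contig × sample count
table. Coverage is expressed as RPKM,

$$\mathrm{RPKM}(c,s) = \frac{n_{cs}}{(L_c/10^3)\,(N_s/10^6)},$$

with $L_c$ the contig length in bp and $N_s$ the per-sample read total.
Two readings of $N_s$ are defensible: the reads mapped to the contig
database in sample $s$, or an externally measured library size. The
package defaults to the former (the column sum — the only total
derivable from the mapping results themselves) and accepts an external
total through `sample_totals`. A sample with zero mapped reads makes the
normalization undefined; `compute_rpkm()` refuses it by name rather than
silently dropping it.

Taxon abundance is the arithmetic mean RPKM over the taxon's contigs
(the mean, rather than the median, keeps the statistic linear in
coverage), closed per sample to relative abundances. Samples in which no
taxon of a given kind was detected are carried along but flagged
(`zero_samples` attribute) and must be excluded from distance-based
stages, where an all-zero composition has no meaning.

## Alpha diversity

`alpha_indices()` reports Shannon entropy in nats (natural log is the
convention of the ecology toolchain; the base is exposed for bits),
Simpson's index in its Gini–Simpson form $1-\sum p_i^2$ (diversity
software most often reports this form under the name "Simpson"; the
concentration form $\sum p_i^2$ is available via `simpson =
"concentration"` since usage in the literature is split), Pielou
evenness $H/\ln S$ (defined as 0 for a single-taxon sample, where
evenness is vacuous), and richness. Shannon and Simpson are delegated to
`vegan::diversity()`.

Group differences are assessed with the two-sided Wilcoxon rank-sum
test: the exact null distribution when both groups have ≤ 25 samples and
the pooled values are tie-free, otherwise the normal approximation with
continuity and tie correction. The threshold of 25 keeps exact
enumeration cheap while covering every group size where the normal
approximation is materially inaccurate.

## Viral-type discovery

Community types are discovered the way bacterial enterotypes are:
Jensen–Shannon distance on the compositions, k-medoids clustering, and
silhouette-guided selection of K.

*Distance.* Zeros are replaced by a pseudocount (default `1e-10`, the
community-typing convention: small enough not to perturb observed
abundances, large enough to keep $\log$ finite) and columns
renormalized; the JSD is computed in nats, so distances are bounded by
$\sqrt{\ln 2} \approx 0.8326$.

*Clustering.* `pam_cluster()` wraps the deterministic BUILD + SWAP
k-medoids of the `cluster` package. Two properties matter here. First,
determinism: no random restarts, so a distance matrix always yields the
same partition. Second, PAM is a local optimizer — the SWAP loop stops
at a medoid set no single swap can improve. On instances with genuine
cluster structure this is the global optimum (the test suite verifies
equality with exhaustive medoid search on such instances up to n = 8),
but on unstructured point sets SWAP can converge one swap short of the
optimum; this is inherent to the algorithm, not to the implementation.

*Model selection.* `choose_k()` scans K = 2…min(10, n−1) and takes the
largest mean silhouette width, breaking ties toward the smallest K
(parsimony, and a deterministic rule). The silhouette-by-K profile is
returned in full so the margin of the choice can be inspected.

*Embedding.* `pcoa_embed()` is classical metric scaling
(`stats::cmdscale`): double-centred squared distances,
eigendecomposition, coordinates scaled by $\sqrt{\lambda_i}$. JSD
matrices are generally non-Euclidean, so negative eigenvalues occur;
they are dropped and counted in `n_negative`. Requested axes whose
eigenvalue is numerically zero (≤ 10⁻⁹ of the leading one) are returned
as exact zeros rather than eigenvector noise. Between-class (instrumented)
ordination is deliberately not applied — the embedding is descriptive
only.

*Concordance.* `type_concordance()` compares two partitions (e.g.
viral types vs enterotypes) after relabelling one by the bijection that
maximizes agreement, found exhaustively over label permutations (capped
at 8 labels), and reports mismatch proportions overall and per group.

## Biomarker scoring

Screening uses the Kruskal–Wallis test with tie correction
(`stats::kruskal.test`), α = 0.05. Its p-value is the chi-square
asymptotic approximation; at very small group sizes (n per group ≈ 4)
this deviates from the exact permutation p by a few percent absolute,
which the test suite bounds explicitly. Taxa identical across all
samples have an undefined statistic and are flagged degenerate with
p = 1 rather than dropped, so output rows stay aligned with input taxa.

Effect sizes follow the LEfSe recipe for class-only designs: abundances
rescaled so each sample sums to 10⁶; 30 subsamples of ⅔ of the samples
(redrawn up to 50 times if a class is lost); per subsample and per class
pair, a linear discriminant (`MASS::lda`); a feature's effect is the
mean of (i) the absolute between-class difference of its class means and
(ii) its absolute share of the between-class separation along the unit
discriminant axis; effects are averaged over subsamples and the score is
$\log_{10}(1 + \max_{\text{pairs}})$. A tiny Gaussian jitter
(σ = 10⁻⁵ on the 10⁶ scale) keeps within-class-constant features from
making the discriminant singular; it is orders of magnitude below any
meaningful effect. The conventional threshold of 2.0 then corresponds to
an abundance contrast of ~100 on the 10⁶ scale, i.e. 0.01 % — by design
a permissive gate; the Kruskal–Wallis screen is what controls
false calls. There is no subclass (within-class Wilcoxon) stage because
the designs targeted here have plain group labels. Scores are
deterministic given `seed`, but bootstrap resampling means they are
reproducible, not invariant, under sample reordering.

The dominant-taxa heat-map matrix (`dominant_zscore()`) keeps taxa above
0.7 % overall mean abundance that also pass the screen, and standardizes
each taxon's vector of group means. The default uses the sample standard
deviation (the `scale()` convention), under which three equally spaced
group means map to (−1, 0, 1); the population-sd variant is available
via `sd_type = "population"` and differs only by the factor
$\sqrt{(g-1)/g}$.

## Group discrimination

For a pairwise comparison the larger group is down-sampled without
replacement to the smaller group's size (`balance_groups()`), a choice
that keeps samples independent; groups below 10 samples are refused
because an 80/20 split with 10-fold CV is no longer meaningful.
`rf_evaluate()` then runs (by default) 50 repeats of: stratified 80/20
split; `mtry` tuned over $\{\tfrac12\sqrt p, \sqrt p, 2\sqrt p\}$ by
k-fold CV on the training set; a 500-tree forest (`ranger`) fitted on
the training set and scored on the held-out samples. Only `mtry` is
tuned — forest accuracy is famously insensitive to the other
hyper-parameters at these sample sizes. The AUC is computed from the
held-out class probabilities of a representative repeat, chosen as the
one attaining the median accuracy (lowest index on ties) so the report
is deterministic. `auc_score()` itself is the Mann–Whitney rank
formulation with midranks, exact under ties.

All features are passed to the forests by default; restricting to
screened taxa is the caller's choice (subset the table first).

## Co-occurrence networks

Candidate edges are all virus × bacteria pairs — within-kind
correlations are neither tested nor part of the FDR family, keeping the
multiplicity budget on the bipartite question. Spearman's ρ uses
midranks; the two-sided p comes from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df (p = 0 at |ρ| = 1);
Benjamini–Hochberg q-values are computed over the whole family. Pairs
with a constant vector have undefined ρ and are skipped and logged.
Edges require |ρ| ≥ 0.5 and q ≤ 0.05 by default; isolated taxa are not
network nodes.

Topology (`network_topology()`):

* density $2M/(N(N-1))$ — the simple-graph formula;
* degree distribution and Brandes betweenness (`igraph`) on the
  unsigned graph;
* natural connectivity
  $\bar\lambda = \ln\big(\tfrac1N\sum_i e^{\lambda_i}\big)$ over the
  adjacency eigenvalues, computed by symmetric eigendecomposition with
  a max-shift for overflow safety (0 for an edgeless graph);
* degree entropy $-\sum_i \tfrac{d_i}{\sum d}\ln\tfrac{d_i}{\sum d}$,
  natural log by default with a base argument, since degree entropies
  are reported in both nats and bits in the network literature;
* the linkage count: virus nodes of degree exactly one, i.e. viruses
  tied to a single bacterium — the "targeted linkage" statistic of the
  bipartite graph.

`robustness_curve()` removes nodes cumulatively — degree-descending with
first-listed tie-break (the classic targeted-attack convention; removal
order is fixed from the initial degrees), or a seeded random order — and
recomputes natural connectivity on the remaining induced graph at each
removal fraction. Surviving isolates are retained, so N shrinks only by
removal, and the curve stops when one node remains.

## The synthetic-community generator

`generate_dataset()` emulates the study design the package targets: a
196-sample cohort split 41/56/99 into Control, pHTN and HTN; ~400 viral
taxa (with as many bacterial taxa); two latent viral community types
with group-dependent mixing proportions (defaults 0.80/0.69/0.61 toward
type 1, reflecting the decreasing type-1 share across disease stages
this design emulates) and a 50-fold dominant-taxon enrichment.

Compositions are Dirichlet draws via the gamma representation: each
sample has a concentration vector (default 0.3 per taxon — sparse,
long-tailed compositions of the kind gut viromes show) modified
multiplicatively by its type's dominant taxon and by any planted
group-specific biomarker folds. Expected relative abundances then carry
the configured fold-changes exactly on the concentration scale; closure
perturbs realized folds slightly.

Planted virus–bacteria correlations use a Gaussian copula on the gamma
representation: a latent bivariate normal with Pearson correlation
$2\sin(\pi\rho_s/6)$ (the inverse of the bivariate-normal Spearman map)
is pushed through `qgamma`, so the pair's Spearman correlation
approaches the target as n grows, up to the perturbation introduced by
closure — hence interval-based tests, not exact ones. Because the
coupling acts on the gamma marginal at a fixed shape, a coupled virus
may be neither a type-dominant taxon nor a planted biomarker (their
type- or group-dependent shapes would scramble the ranks);
`synth_config()` rejects such configurations.

Two consequences of the design are worth knowing when writing tests.
First, group-dependent type mixing makes *background* taxa genuinely
group-differential through closure — exactly the biology the design
emulates — so tests that count false-positive biomarkers must use a
uniform `type_mix`. Second, with several hundred background taxa the
α = 0.05 screen passes ~5 % of them by chance; false-positive counts are
therefore only meaningful on small taxon universes.

What the generator does **not** emulate: read-level noise (counts enter
only through the separate contig-table generator, which uses
negative-binomial counts around length-proportional means), taxonomic
hierarchy, compositional correlation structure beyond the planted
pairs, covariates such as age or medication, and batch effects. Passing
tests therefore demonstrate correctness of the statistical machinery on
data satisfying the generative assumptions, not performance on real
cohort data.

## Problem sizes and determinism

The test and acceptance workloads use cohort-scale simulations where the
statistics need them (196 samples for type recovery, twenty independent
cohorts for the K-selection rate, 50-forest ensembles for the accuracy
distribution) and reduced taxon universes (40–120 taxa) where only the
mechanism is under test; these sizes give each check a comfortable
signal-to-noise margin while keeping the full suite fast. Every
stochastic function takes a seed and restores the caller's RNG state
(`local_seed()`), so pipelines are reproducible end-to-end from a single
master seed.

## Known limitations

* PAM local optimality (above): on unstructured instances the partition
  can differ from the exhaustive-search optimum.
* The chi-square Kruskal–Wallis p is approximate below ~5 samples per
  group; an exact/permutation mode is not provided.
* LEfSe-style scores have no closed-form null; the threshold of 2.0 is a
  convention, and the package validates the scorer by planted-signal
  recovery and fold-monotonicity rather than against a reference
  implementation.
* Viral-type proportions, biomarker identities and network statistics of
  any *real* cohort depend on its actual profiles; the package
  reproduces procedures and their behaviour on planted ground truth, not
  cohort-specific values.
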