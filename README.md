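# gutviromics

Community-level analysis of the human gut virome from shotgun-metagenome
profiles, with a focus on relating viral community structure to host
phenotype groups (e.g. normotensive, pre-hypertensive and hypertensive
cohorts). The package takes over where read mapping and taxonomic
annotation stop: it consumes contig-level mapped-read counts and taxon ×
sample relative-abundance tables, and provides every downstream stage of a
virome–phenotype study as tested, composable R functions.

## What it computes

* **Abundance profiling.** Contig coverage as RPKM,
  `RPKM(c,s) = n(c,s) / ((L_c/10³)(N_s/10⁶))`, averaged per taxon and
  closed per sample into relative abundances.
* **Alpha diversity.** Shannon `H = −Σ pᵢ ln pᵢ`, Gini–Simpson
  `1 − Σ pᵢ²`, Pielou `H / ln S`, richness `S`; Wilcoxon rank-sum
  comparison of every index between every pair of groups; shared/union
  taxon counts over all sample pairs for saturation curves.
* **Viral-type discovery.** Jensen–Shannon distance
  `d(P,Q) = √(½KL(P‖M) + ½KL(Q‖M))`, `M = (P+Q)/2`, between all samples;
  partitioning-around-medoids clustering; mean silhouette width
  `s = (b−a)/max(a,b)` over K = 2…10 to select the number of community
  types; principal-coordinates embedding; optimal-bijection concordance
  with an external partition (e.g. bacterial enterotypes).
* **Biomarkers.** Kruskal–Wallis screening (α = 0.05), LEfSe-style
  bootstrapped linear-discriminant effect sizes on the 10⁶ scale with the
  conventional log₁₀ threshold of 2.0, and Z-score matrices of dominant
  (> 0.7 % mean abundance) discrepant taxa.
* **Group discrimination.** Balanced down-sampling, 50 repeats of
  stratified 80/20 random-forest evaluation with 10-fold CV tuning, and
  rank-formulation AUC `P(s⁺ > s⁻) + ½P(tie)`.
* **Virus–bacteria co-occurrence networks.** Spearman correlation of all
  virus × bacteria pairs, Benjamini–Hochberg FDR, |ρ| ≥ 0.5 and
  q ≤ 0.05 gates, and bipartite topology: density `2M/(N(N−1))`, degree
  distribution, betweenness, natural connectivity
  `ln((1/N) Σ e^{λᵢ})`, degree entropy, the count of single-linkage
  viruses, and natural-connectivity robustness curves under targeted or
  random node removal. GraphML/TSV export for Cytoscape.
* **Synthetic cohorts.** A seeded generator of paired virome/bacteriome
  compositions with planted community types, planted group-enriched taxa
  and Gaussian-copula rank-coupled virus–bacteria pairs, so every stage
  can be validated against known ground truth.

## Worked example

```r
library(gutviromics)

cfg <- synth_config(
  group_sizes = c(Control = 41, pHTN = 56, HTN = 99),
  n_virus_taxa = 120, n_bacteria_taxa = 120,
  biomarkers = data.frame(taxon = 11:16,
                          group = rep(c("Control", "pHTN", "HTN"), 2),
                          fold = 10),
  correlated_pairs = data.frame(virus = c(31, 41), bacteria = c(21, 22),
                                rho = c(0.9, -0.85)),
  seed = 42)
d <- generate_dataset(cfg)

typing <- choose_k(jsd_matrix(d$viral), 2:10)
typing
#> viral-type clustering: chosen K = 2
#> mean silhouette by K:
#>      2      3      4      5      6      7      8      9     10
#> 0.2004 0.0812 0.0832 0.0353 0.0342 0.0279 0.0259 0.0188 0.0178

type_concordance(d$truth$type_labels, typing$labels)$overall_mismatch
#> [1] 0

bm <- select_biomarkers(kruskal_screen(d$viral, d$labels),
                        lda_effect_sizes(d$viral, d$labels, seed = 1))
head(bm[bm$is_biomarker, c("taxon", "kw_p", "enriched_group", "lda_score")], 4)
#>        taxon         kw_p enriched_group lda_score
#> 11 virus_011 1.310571e-19        Control  4.449676
#> 12 virus_012 3.620784e-24           pHTN  4.464107
#> 13 virus_013 1.844467e-29            HTN  4.393124
#> 14 virus_014 2.181306e-18        Control  4.364130

net <- build_network(correlation_edges(d$viral, d$bacterial))
network_topology(net)
#> network topology: N=4 M=2 density=0.3333 nat.conn=0.4338 entropy=1.3863 linkages=2
```

The silhouette profile peaks at K = 2, recovering the two planted
community types with zero label mismatch; all planted biomarkers pass
both gates with log₁₀ effect sizes ≈ 4.4 (an abundance contrast of
~2.5 × 10⁴ on the 10⁶ scale); and the only edges surviving the
|ρ| ≥ 0.5, q ≤ 0.05 gates are the two planted virus–bacteria couplings,
each a single-linkage virus.

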