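#' Configuration for the synthetic gut-community generator
#'
#' Bundles and validates every knob of [generate_dataset()]. Defaults emulate
#' the cohort the package targets: 196 faecal metagenomes split into
#' Control (41), pHTN (56) and HTN (99); about four hundred viral taxa; two
#' latent viral community types with distinct dominant bacteriophages and
#' group-dependent mixing proportions; optional planted group-enriched viral
#' taxa (biomarkers) and rank-coupled virus-bacteria abundance pairs.
#'
#' @param group_sizes named integer vector, samples per group; every group
#'   needs at least 2 samples.
#' @param n_virus_taxa,n_bacteria_taxa number of taxa per kind.
#' @param n_types number of latent viral community types; type `t` is
#'   dominated by viral taxon `t`.
#' @param type_dominance fold-enrichment (>= 1) of each type's dominant taxon
#'   relative to a background taxon, on the Dirichlet-mean scale.
#' @param type_mix matrix (groups x types) of mixing proportions, rows
#'   summing to 1; default sends 80/69/61% of Control/pHTN/HTN samples to
#'   type 1 when `n_types == 2`, otherwise uniform.
#' @param biomarkers `data.frame(taxon, group, fold)`: viral taxon index,
#'   the group it is enriched in, and the fold-change (> 0) of its expected
#'   abundance there.
#' @param correlated_pairs `data.frame(virus, bacteria, rho)`: taxon indices
#'   and target Spearman correlation in `[-1, 1]`; each taxon may appear in
#'   at most one pair, and a pair's virus may be neither a type-dominant
#'   taxon (index `<= n_types`) nor a planted biomarker (their type- or
#'   group-dependent scale would defeat the rank coupling).
#' @param dirichlet_concentration per-taxon Dirichlet concentration (> 0);
#'   small values give the sparse, long-tailed compositions typical of gut
#'   viromes.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(group_sizes = c(Control = 41, pHTN = 56, HTN = 99),
                         n_virus_taxa = 400,
                         n_bacteria_taxa = 400,
                         n_types = 2,
                         type_dominance = 50,
                         type_mix = NULL,
                         biomarkers = NULL,
                         correlated_pairs = NULL,
                         dirichlet_concentration = 0.3,
                         seed = 1L) {
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector")
  if (any(group_sizes < 2)) stop("every group needs at least 2 samples")
  if (n_virus_taxa < 1 || n_bacteria_taxa < 1) stop("need at least one taxon per kind")
  if (n_types < 1 || n_types > n_virus_taxa)
    stop("more community types than viral taxa")
  if (type_dominance < 1) stop("type_dominance must be >= 1")
  if (dirichlet_concentration <= 0) stop("dirichlet_concentration must be > 0")
  g <- length(group_sizes)
  if (is.null(type_mix)) {
    type_mix <- if (n_types == 2 &&
                    identical(sort(names(group_sizes)),
                              sort(c("Control", "pHTN", "HTN")))) {
      p1 <- c(Control = 0.80, pHTN = 0.69, HTN = 0.61)[names(group_sizes)]
      cbind(p1, 1 - p1)
    } else {
      matrix(1 / n_types, g, n_types)
    }
    rownames(type_mix) <- names(group_sizes)
  }
  type_mix <- as.matrix(type_mix)
  if (is.null(rownames(type_mix))) rownames(type_mix) <- names(group_sizes)
  if (!all(dim(type_mix) == c(g, n_types)) ||
      any(abs(rowSums(type_mix) - 1) > 1e-8) || any(type_mix < 0))
    stop("type_mix must be a groups x types stochastic matrix")
  if (!is.null(biomarkers)) {
    biomarkers <- as.data.frame(biomarkers)
    stopifnot(all(c("taxon", "group", "fold") %in% names(biomarkers)))
    if (any(biomarkers$fold <= 0)) stop("biomarker fold-changes must be > 0")
    if (any(biomarkers$taxon < 1 | biomarkers$taxon > n_virus_taxa))
      stop("biomarker taxon index out of range")
    if (!all(biomarkers$group %in% names(group_sizes)))
      stop("biomarker group not among group_sizes names")
  }
  if (!is.null(correlated_pairs)) {
    correlated_pairs <- as.data.frame(correlated_pairs)
    stopifnot(all(c("virus", "bacteria", "rho") %in% names(correlated_pairs)))
    if (any(abs(correlated_pairs$rho) > 1)) stop("|target rho| must be <= 1")
    if (any(correlated_pairs$virus < 1 | correlated_pairs$virus > n_virus_taxa) ||
        any(correlated_pairs$bacteria < 1 | correlated_pairs$bacteria > n_bacteria_taxa))
      stop("correlated pair taxon index out of range")
    if (anyDuplicated(correlated_pairs$virus) ||
        anyDuplicated(correlated_pairs$bacteria))
      stop("each taxon may appear in at most one correlated pair")
    if (any(correlated_pairs$virus <= n_types))
      stop("correlated pairs may not involve type-dominant taxa ",
           "(indices 1..n_types): their type-dependent scale breaks ",
           "the rank coupling")
    if (!is.null(biomarkers) && any(correlated_pairs$virus %in%
                                      biomarkers$taxon))
      stop("correlated pairs may not involve planted biomarker taxa")
  }
  structure(list(group_sizes = group_sizes,
                 n_virus_taxa = as.integer(n_virus_taxa),
                 n_bacteria_taxa = as.integer(n_bacteria_taxa),
                 n_types = as.integer(n_types),
                 type_dominance = type_dominance,
                 type_mix = type_mix,
                 biomarkers = biomarkers,
                 correlated_pairs = correlated_pairs,
                 dirichlet_concentration = dirichlet_concentration,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a synthetic paired virome/bacteriome dataset with known truth
#'
#' Viral compositions are drawn per sample from a Dirichlet distribution
#' whose concentration vector encodes (i) the sample's latent community type
#' (the type's dominant taxon is up-weighted `type_dominance`-fold) and
#' (ii) any planted group-specific biomarker enrichments. Bacterial
#' compositions use a flat concentration. Planted virus-bacteria pairs are
#' coupled through a shared latent bivariate normal (Gaussian copula on the
#' gamma representation of the Dirichlet), so their empirical Spearman
#' correlation approaches the target as the number of samples grows;
#' closure renormalization perturbs it slightly.
#'
#' @param config a [synth_config()].
#' @return list with elements `viral` and `bacterial` ([abundance_table()]s,
#'   taxa x samples), `labels` (named factor of group memberships) and
#'   `truth` (list: `type_labels`, `biomarkers`, `correlated_pairs`).
#' @examples
#' d <- generate_dataset(synth_config(group_sizes = c(A = 5, B = 5),
#'                                    n_virus_taxa = 30, n_bacteria_taxa = 20))
#' colSums(d$viral)  # all 1
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    groups <- rep(names(config$group_sizes), config$group_sizes)
    n <- length(groups)
    sample_ids <- sprintf("%s_%02d", groups,
                          unlist(lapply(config$group_sizes, seq_len)))
    labels <- stats::setNames(factor(groups, levels = names(config$group_sizes)),
                              sample_ids)

    # latent type per sample
    types <- vapply(groups, function(g)
      sample.int(config$n_types, 1L, prob = config$type_mix[g, ]), 1L)
    names(types) <- sample_ids

    # per-sample Dirichlet concentration vectors (viral)
    a <- config$dirichlet_concentration
    shapes_v <- matrix(a, config$n_virus_taxa, n)
    for (i in seq_len(n)) shapes_v[types[i], i] <- a * config$type_dominance
    if (!is.null(config$biomarkers)) {
      for (r in seq_len(nrow(config$biomarkers))) {
        b <- config$biomarkers[r, ]
        hit <- groups == b$group
        shapes_v[b$taxon, hit] <- shapes_v[b$taxon, hit] * b$fold
      }
    }

    # latent normals for rank-coupled pairs; Pearson r on the latent scale
    # chosen so that the bivariate-normal Spearman equals the target rho
    zv <- matrix(NA_real_, config$n_virus_taxa, n)
    zb <- matrix(NA_real_, config$n_bacteria_taxa, n)
    if (!is.null(config$correlated_pairs)) {
      for (r in seq_len(nrow(config$correlated_pairs))) {
        p <- config$correlated_pairs[r, ]
        rlat <- 2 * sin(pi * p$rho / 6)
        z1 <- stats::rnorm(n)
        z2 <- rlat * z1 + sqrt(1 - rlat^2) * stats::rnorm(n)
        zv[p$virus, ] <- z1
        zb[p$bacteria, ] <- z2
      }
    }

    viral <- gamma_compositions(shapes_v, zv)
    shapes_b <- matrix(a, config$n_bacteria_taxa, n)
    bacterial <- gamma_compositions(shapes_b, zb)

    dimnames(viral) <- list(sprintf("virus_%03d", seq_len(config$n_virus_taxa)),
                            sample_ids)
    dimnames(bacterial) <- list(sprintf("bacteria_%03d",
                                        seq_len(config$n_bacteria_taxa)),
                                sample_ids)
    list(viral = abundance_table(viral, "virus", renormalize = TRUE),
         bacterial = abundance_table(bacterial, "bacteria", renormalize = TRUE),
         labels = labels,
         truth = list(type_labels = types,
                      biomarkers = config$biomarkers,
                      correlated_pairs = config$correlated_pairs))
  })
}

# draw gamma variates per taxon x sample; rows with a latent normal are
# transformed through the copula (qgamma of pnorm), others drawn directly
gamma_compositions <- function(shapes, z) {
  out <- matrix(stats::rgamma(length(shapes), shape = shapes),
                nrow(shapes), ncol(shapes))
  coupled <- which(!is.na(z[, 1]))
  for (j in coupled)
    out[j, ] <- stats::qgamma(stats::pnorm(z[j, ]), shape = shapes[j, ])
  # guard against all-zero columns when concentrations are tiny
  zero <- colSums(out) == 0
  out[1, zero] <- 1
  out
}

#' Generate a synthetic contig table with mapped-read counts
#'
#' Contig lengths are drawn log-uniformly within `length_range` (default
#' spanning 1,000-374,762 bp, the span retained after assembly filtering at
#' 1 kb). Counts are negative-binomial around length-proportional means with
#' per-sample depth factors and per-contig expression factors, giving the
#' overdispersed coverage typical of metagenome read mapping.
#'
#' @param n_contigs,n_samples table dimensions (>= 1).
#' @param length_range numeric length-2, minimum >= 1000 bp.
#' @param n_taxa number of distinct taxon annotations to spread contigs over.
#' @param mean_depth expected mapped reads per kb per contig at depth 1.
#' @param dispersion negative-binomial size parameter.
#' @param seed integer seed.
#' @return a `data.frame` of class `contig_table`: columns `contig_id`,
#'   `length_bp`, `taxon`, then one integer count column per sample.
#' @export
generate_contig_data <- function(n_contigs, n_samples,
                                 length_range = c(1000, 374762),
                                 n_taxa = max(1L, n_contigs %/% 5L),
                                 mean_depth = 20, dispersion = 2,
                                 seed = 1L) {
  if (n_contigs < 1 || n_samples < 1) stop("dimensions must be positive")
  if (length_range[1] < 1000) stop("minimum contig length is 1000 bp")
  if (length_range[2] < length_range[1]) stop("invalid length range")
  local_seed(seed, {
    len <- round(exp(stats::runif(n_contigs, log(length_range[1]),
                                  log(length_range[2]))))
    taxon <- sprintf("virus_%03d", sample.int(n_taxa, n_contigs, replace = TRUE))
    depth <- exp(stats::rnorm(n_samples, 0, 0.5))        # per-sample depth
    expr <- exp(stats::rnorm(n_contigs, 0, 1))           # per-contig abundance
    mu <- outer(expr * len / 1000 * mean_depth, depth)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
                     n_contigs, n_samples)
    colnames(counts) <- sprintf("S%03d", seq_len(n_samples))
    out <- data.frame(contig_id = sprintf("contig_%05d", seq_len(n_contigs)),
                      length_bp = as.integer(len),
                      taxon = taxon,
                      counts, check.names = FALSE)
    class(out) <- c("contig_table", "data.frame")
    out
  })
}

# count matrix (contigs x samples) of a contig_table
contig_counts <- function(contigs) {
  m <- as.matrix(contigs[, setdiff(colnames(contigs),
                                   c("contig_id", "length_bp", "taxon")),
                         drop = FALSE])
  rownames(m) <- contigs$contig_id
  storage.mode(m) <- "double"
  m
}
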