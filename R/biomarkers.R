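#' Kruskal-Wallis screening of group-differential taxa
#'
#' Rank-based k-sample test per taxon with tie correction and chi-square
#' p-value on `groups - 1` degrees of freedom. Taxa whose values are
#' identical in every sample (typically all-zero) have an undefined
#' statistic; they are flagged degenerate and assigned `p = 1`.
#'
#' @param table an [abundance_table()] (taxa x samples).
#' @param labels named factor of group memberships.
#' @param alpha significance gate.
#' @return data.frame: `taxon`, `kw_H`, `kw_p`, `pass`, `degenerate`.
#' @export
kruskal_screen <- function(table, labels, alpha = 0.05) {
  g <- droplevels(factor(labels[colnames(table)]))
  if (anyNA(g)) stop("labels missing for some samples")
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  res <- t(apply(unclass(table), 1, function(x) {
    if (max(x) == min(x)) return(c(NA_real_, 1))
    kt <- stats::kruskal.test(x, g)
    c(unname(kt$statistic), kt$p.value)
  }))
  data.frame(taxon = rownames(table),
             kw_H = res[, 1], kw_p = res[, 2],
             pass = res[, 2] < alpha,
             degenerate = is.na(res[, 1]),
             row.names = NULL)
}

#' LEfSe-style linear-discriminant effect sizes
#'
#' Reimplementation of the effect-size stage of LEfSe (Segata et al. 2011)
#' for designs with classes only (no subclass stage). Abundances are
#' rescaled so each sample sums to 1e6. Over `n_boot` subsamples of a
#' `subsample` fraction of the samples, a linear discriminant is fitted for
#' every unordered pair of classes; a feature's effect for that pair is the
#' mean of (i) the absolute between-class difference of its class means and
#' (ii) the absolute component of the between-class separation along the
#' unit discriminant axis attributed to it. Effects are averaged over the
#' bootstraps and the score is `log10(1 + max over pairs)`. A taxon's
#' enriched group is the class with the highest mean rescaled abundance.
#'
#' @param table an [abundance_table()] (taxa x samples).
#' @param labels named factor of group memberships.
#' @param n_boot number of bootstrap subsamples.
#' @param subsample fraction of samples drawn (without replacement) per
#'   bootstrap; draws losing an entire class are retried up to 50 times.
#' @param seed integer seed; results are deterministic given it.
#' @return data.frame: `taxon`, `lda_score` (log10 scale), `enriched_group`.
#' @export
lda_effect_sizes <- function(table, labels, n_boot = 30, subsample = 2 / 3,
                             seed = 1L) {
  g <- droplevels(factor(labels[colnames(table)]))
  if (anyNA(g)) stop("labels missing for some samples")
  if (nlevels(g) < 2) stop("need at least 2 groups")
  x <- t(unclass(table)) * 1e6                 # samples x features, 1e6 scale
  n <- nrow(x)
  p <- ncol(x)
  cls <- levels(g)
  pairs <- utils::combn(cls, 2, simplify = FALSE)
  local_seed(seed, {
    eff <- array(0, dim = c(p, length(pairs), n_boot))
    for (b in seq_len(n_boot)) {
      idx <- NULL
      for (attempt in 1:50) {
        cand <- sample.int(n, max(2L, floor(subsample * n)))
        if (all(table(g[cand]) >= 2)) { idx <- cand; break }
      }
      if (is.null(idx)) stop("could not draw a subsample retaining every class")
      # tiny jitter keeps within-class-constant features from breaking LDA
      xb <- x[idx, , drop = FALSE] +
        matrix(stats::rnorm(length(idx) * p, 0, 1e-5), length(idx), p)
      gb <- g[idx]
      for (j in seq_along(pairs)) {
        sel <- gb %in% pairs[[j]]
        eff[, j, b] <- pairwise_lda_effect(xb[sel, , drop = FALSE],
                                           droplevels(gb[sel]))
      }
    }
    mean_eff <- apply(eff, c(1, 2), mean)       # features x pairs
    score <- log10(1 + pmax(apply(mean_eff, 1, max), 0))
    grp_means <- vapply(cls, function(cl) colMeans(x[g == cl, , drop = FALSE]),
                        numeric(p))
    data.frame(taxon = rownames(table),
               lda_score = score,
               enriched_group = cls[max.col(grp_means, ties.method = "first")],
               row.names = NULL)
  })
}

# per-feature effect for one class pair: mean of |class-mean difference|
# and |feature's share of the separation along the unit discriminant|
pairwise_lda_effect <- function(x, g) {
  fit <- tryCatch(suppressWarnings(MASS::lda(x, grouping = g, tol = 1e-10)),
                  error = function(e) NULL)
  mu1 <- colMeans(x[g == levels(g)[1], , drop = FALSE])
  mu2 <- colMeans(x[g == levels(g)[2], , drop = FALSE])
  gm <- abs(mu1 - mu2)
  if (is.null(fit)) return(gm)                  # degenerate fit: mean diff only
  w <- fit$scaling[, 1]
  w <- w / sqrt(sum(w^2))
  ld <- drop(x %*% w)
  sep <- abs(mean(ld[g == levels(g)[1]]) - mean(ld[g == levels(g)[2]]))
  (gm + abs(w * sep)) / 2
}

#' Combine screening and effect sizes into biomarker calls
#'
#' A taxon is a biomarker when it passes the Kruskal-Wallis gate
#' (`kw_p < alpha`) and its LDA effect score reaches `lda_threshold`
#' (log10 scale; 2.0 is the conventional cutoff).
#'
#' @param screen output of [kruskal_screen()].
#' @param lda output of [lda_effect_sizes()].
#' @param alpha,lda_threshold the two gates.
#' @return data.frame: `taxon`, `kw_H`, `kw_p`, `enriched_group`,
#'   `lda_score`, `is_biomarker`, with a `counts_by_group` attribute giving
#'   biomarker counts per enriched group.
#' @export
select_biomarkers <- function(screen, lda, alpha = 0.05, lda_threshold = 2.0) {
  if (!setequal(screen$taxon, lda$taxon))
    stop("screen and LDA results cover different taxa")
  m <- merge(screen, lda, by = "taxon", sort = FALSE)
  m <- m[match(screen$taxon, m$taxon), ]
  out <- data.frame(taxon = m$taxon, kw_H = m$kw_H, kw_p = m$kw_p,
                    enriched_group = m$enriched_group,
                    lda_score = m$lda_score,
                    is_biomarker = m$kw_p < alpha & m$lda_score >= lda_threshold,
                    row.names = NULL)
  counts <- table(factor(out$enriched_group)[out$is_biomarker])
  attr(out, "counts_by_group") <- counts
  out
}

#' Z-score matrix of dominant, group-discrepant taxa
#'
#' Keeps taxa whose overall mean relative abundance exceeds
#' `mean_abundance_threshold` and whose Kruskal-Wallis p-value is below
#' 0.05, then standardizes each kept taxon's vector of group means to zero
#' mean and unit (population) standard deviation across groups.
#'
#' @param table an [abundance_table()] (taxa x samples).
#' @param labels named factor of group memberships.
#' @param mean_abundance_threshold overall-mean abundance gate in (0,1);
#'   the default 0.007 keeps taxa above 0.7% mean abundance.
#' @param sd_type `"sample"` (divide by n-groups minus one, the [scale()]
#'   convention, under which three equally spaced group means map to
#'   -1, 0, 1) or `"population"`.
#' @return matrix kept-taxa x groups of Z-scores.
#' @export
dominant_zscore <- function(table, labels, mean_abundance_threshold = 0.007,
                            sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (mean_abundance_threshold <= 0 || mean_abundance_threshold >= 1)
    stop("mean_abundance_threshold must be in (0, 1)")
  g <- droplevels(factor(labels[colnames(table)]))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  keep <- rowMeans(table) > mean_abundance_threshold
  scr <- kruskal_screen(table, labels, alpha = 0.05)
  keep <- keep & scr$pass
  if (!any(keep)) return(matrix(0, 0, nlevels(g),
                                dimnames = list(NULL, levels(g))))
  x <- unclass(table)[keep, , drop = FALSE]
  gs <- rowsum(t(x), g)
  gm <- t(gs / as.vector(table(g)[rownames(gs)]))  # taxa x groups
  ctr <- gm - rowMeans(gm)
  sdv <- if (sd_type == "population") sqrt(rowMeans(ctr^2))
         else apply(gm, 1, stats::sd)
  z <- ctr / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}
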