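#' Alpha-diversity indices per sample
#'
#' Shannon entropy `H = -sum p ln p` (nats by default), Gini-Simpson
#' diversity `1 - sum p^2` (the concentration form `sum p^2` is available
#' via `simpson = "concentration"`), Pielou evenness `H / ln(richness)`
#' (defined as 0 for a single-taxon sample) and richness (number of taxa
#' with non-zero abundance).
#'
#' @param table an [abundance_table()] (taxa x samples); all-zero samples
#'   are rejected.
#' @param base logarithm base for Shannon and Pielou.
#' @param simpson `"gini"` (default, `1 - sum p^2`) or `"concentration"`.
#' @return data.frame: `sample_id`, `richness`, `shannon`, `simpson`,
#'   `pielou`.
#' @examples
#' m <- matrix(rep(0.25, 4), 4, dimnames = list(paste0("v", 1:4), "s1"))
#' alpha_indices(abundance_table(m))  # H = ln 4, Simpson 0.75, Pielou 1
#' @export
alpha_indices <- function(table, base = exp(1),
                          simpson = c("gini", "concentration")) {
  simpson <- match.arg(simpson)
  if (any(table < 0)) stop("negative abundances")
  zero <- colSums(table) == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(table)[zero], collapse = ", "))
  comm <- t(unclass(table))                     # samples x taxa, vegan layout
  h <- vegan::diversity(comm, index = "shannon", base = base)
  d2 <- vegan::diversity(comm, index = "simpson")   # 1 - sum p^2
  rich <- rowSums(comm > 0)
  data.frame(sample_id = colnames(table),
             richness = as.integer(rich),
             shannon = unname(h),
             simpson = unname(if (simpson == "gini") d2 else 1 - d2),
             pielou = unname(ifelse(rich > 1, h / log(rich, base = base), 0)),
             row.names = NULL)
}

#' Shared and union taxon counts over all sample pairs
#'
#' The pairwise accumulation statistics behind rarefaction-style saturation
#' curves: for every unordered pair of samples, the number of taxa detected
#' in both and in at least one.
#'
#' @param presence samples-in-columns matrix; non-zero entries (or `TRUE`)
#'   mean detected. An [abundance_table()] works directly.
#' @return data.frame with one row per unordered pair: `sample_a`,
#'   `sample_b`, `shared`, `union`.
#' @export
pairwise_accumulation <- function(presence) {
  p <- unclass(presence) > 0
  if (ncol(p) < 2) stop("need at least 2 samples")
  shared <- crossprod(p)                       # samples x samples
  rich <- colSums(p)
  uni <- outer(rich, rich, "+") - shared
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  data.frame(sample_a = colnames(p)[idx[, 1]],
             sample_b = colnames(p)[idx[, 2]],
             shared = as.integer(shared[idx]),
             union = as.integer(uni[idx]),
             row.names = NULL)
}

#' Rank-based group comparison of alpha-diversity indices
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of every index between
#' every pair of groups. The exact null distribution is used when both
#' groups have at most 25 samples and the values are tie-free; otherwise
#' the normal approximation with continuity and tie correction.
#'
#' @param records output of [alpha_indices()].
#' @param labels named factor of group memberships covering the samples.
#' @param indices which index columns to compare.
#' @return data.frame: `index`, `group_a`, `group_b`, `p`.
#' @export
compare_alpha_groups <- function(records, labels,
                                 indices = c("shannon", "simpson",
                                             "pielou", "richness")) {
  g <- labels[records$sample_id]
  if (anyNA(g)) stop("labels missing for some samples")
  g <- droplevels(factor(g))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 samples")
  pairs <- utils::combn(levels(g), 2)
  out <- do.call(rbind, lapply(indices, function(ix) {
    v <- records[[ix]]
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      x <- v[g == pairs[1, j]]
      y <- v[g == pairs[2, j]]
      exact <- length(x) <= 25 && length(y) <= 25 &&
        !anyDuplicated(c(x, y))
      p <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
      data.frame(index = ix, group_a = pairs[1, j], group_b = pairs[2, j],
                 p = p)
    }))
  }))
  rownames(out) <- NULL
  out
}
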