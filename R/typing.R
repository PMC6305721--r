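#' Jensen-Shannon distance matrix between samples
#'
#' For compositions `P`, `Q` and mixture `M = (P + Q) / 2`, the
#' Jensen-Shannon divergence is `0.5 KL(P || M) + 0.5 KL(Q || M)` (natural
#' log) and the distance is its square root, a metric bounded by
#' `sqrt(ln 2)`. Zeros are replaced by a small pseudocount and each column
#' renormalized before the computation, the convention of community-typing
#' (enterotype) analyses.
#'
#' @param table an [abundance_table()] (taxa x samples); samples flagged as
#'   all-zero are dropped with a warning.
#' @param pseudocount positive replacement for zero abundances.
#' @return symmetric samples x samples matrix of class `dist_matrix` with
#'   zero diagonal.
#' @export
jsd_matrix <- function(table, pseudocount = 1e-10) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  x <- unclass(table)
  if (any(x < 0)) stop("negative abundances")
  zero <- colSums(x) == 0
  if (any(zero)) {
    warning("dropping all-zero sample(s): ",
            paste(colnames(x)[zero], collapse = ", "))
    x <- x[, !zero, drop = FALSE]
  }
  x[x == 0] <- pseudocount
  x <- sweep(x, 2, colSums(x), "/")
  n <- ncol(x)
  xlogx <- x * log(x)
  hs <- -colSums(xlogx)                        # per-sample entropies
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n - 1)) {
    m <- (x[, i] + x[, (i + 1):n, drop = FALSE]) / 2
    hm <- -colSums(m * log(m))
    jsd <- pmax(hm - (hs[i] + hs[(i + 1):n]) / 2, 0)
    d[i, (i + 1):n] <- d[(i + 1):n, i] <- sqrt(jsd)
  }
  structure(d, class = c("dist_matrix", class(d)))
}

check_dist <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12 ||
      any(diag(d) != 0) || any(d < 0))
    stop("not a valid distance matrix (symmetric, non-negative, zero diagonal)")
  d
}

#' Partitioning around medoids on a distance matrix
#'
#' Deterministic k-medoids (BUILD followed by SWAP) as implemented in the
#' \pkg{cluster} package; the total distance of samples to their cluster
#' medoid is non-increasing over SWAP iterations and the result is a local
#' optimum of the medoid-set objective.
#'
#' @param d distance matrix (square symmetric or `dist`).
#' @param k number of clusters, `2 <= k < n`.
#' @return list: `labels` (named integer vector in `1..k`), `medoids`
#'   (sample ids), `cost` (sum of distances to assigned medoids),
#'   `silhouette` (mean silhouette width).
#' @export
pam_cluster <- function(d, k) {
  d <- check_dist(d)
  n <- nrow(d)
  if (k < 2 || k >= n) stop("need 2 <= k < n")
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                      variant = "original")
  list(labels = stats::setNames(as.integer(fit$clustering), rownames(d)),
       medoids = rownames(d)[fit$id.med],
       cost = sum(d[cbind(seq_len(n), fit$id.med[fit$clustering])]),
       silhouette = if (k < n) fit$silinfo$avg.width else NA_real_)
}

#' Choose the number of viral types by mean silhouette width
#'
#' Runs [pam_cluster()] for every K in `k_range` and picks the K with the
#' largest mean silhouette width `s(i) = (b - a) / max(a, b)`; ties go to
#' the smallest K.
#'
#' @param d distance matrix.
#' @param k_range candidate cluster numbers (clipped to `2..n-1`).
#' @return list of class `typing_result`: `chosen_k`, `labels`, `medoids`,
#'   `silhouette_by_k` (named numeric vector), `cost`.
#' @export
choose_k <- function(d, k_range = 2:10) {
  d <- check_dist(d)
  n <- nrow(d)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range empty after clipping to [2, n-1]")
  fits <- lapply(k_range, function(k) pam_cluster(d, k))
  sw <- stats::setNames(vapply(fits, `[[`, 0, "silhouette"), k_range)
  best <- which.max(sw)                         # first max = smallest K
  structure(list(chosen_k = k_range[best],
                 labels = fits[[best]]$labels,
                 medoids = fits[[best]]$medoids,
                 silhouette_by_k = sw,
                 cost = fits[[best]]$cost),
            class = "typing_result")
}

#' @export
print.typing_result <- function(x, ...) {
  cat("viral-type clustering: chosen K =", x$chosen_k, "\n")
  cat("mean silhouette by K:\n")
  print(round(x$silhouette_by_k, 4))
  invisible(x)
}

#' Principal coordinates (classical metric scaling) of a distance matrix
#'
#' Double-centers the squared distances, eigendecomposes and scales
#' eigenvectors by the square roots of the positive eigenvalues. Negative
#' eigenvalues (non-Euclidean distances) are dropped and reported. Axes
#' beyond the number of positive eigenvalues are zero-padded.
#'
#' @param d distance matrix.
#' @param n_axes number of coordinate axes to return.
#' @return list: `coords` (samples x `n_axes`), `eigenvalues` (descending,
#'   all of them), `n_negative`.
#' @export
pcoa_embed <- function(d, n_axes = 2) {
  d <- check_dist(d)
  n <- nrow(d)
  if (n_axes < 1 || n_axes > n - 1) stop("need 1 <= n_axes <= n-1")
  if (all(d == 0)) {
    co <- matrix(0, n, n_axes, dimnames = list(rownames(d), NULL))
    return(list(coords = co, eigenvalues = rep(0, n), n_negative = 0L))
  }
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n_axes,
                                          eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  if (max(eig) <= 1e-12) stop("no positive eigenvalue: distances are degenerate")
  co <- fit$points
  if (ncol(co) < n_axes)                       # pad degenerate trailing axes
    co <- cbind(co, matrix(0, n, n_axes - ncol(co)))
  # axes whose eigenvalue is numerically zero carry no signal
  dead <- which(eig[seq_len(n_axes)] <= 1e-9 * max(eig))
  co[, dead] <- 0
  rownames(co) <- rownames(d)
  list(coords = co, eigenvalues = eig,
       n_negative = sum(eig < -1e-12 * max(abs(eig))))
}

#' Agreement between two sample partitions (e.g. viral-types vs enterotypes)
#'
#' Relabels `partition_b` by the bijection between cluster labels that
#' maximizes overall agreement with `partition_a` (searched exhaustively
#' over label permutations), then reports the proportion of mismatched
#' samples per group and overall.
#'
#' @param partition_a,partition_b named vectors of cluster labels over the
#'   same sample set.
#' @param groups optional named factor of sample groups for the per-group
#'   breakdown.
#' @return list: `overall_mismatch`, `by_group` (named proportions),
#'   `n_mismatch`, `mapping` (levels of b -> levels of a).
#' @export
type_concordance <- function(partition_a, partition_b, groups = NULL) {
  if (!setequal(names(partition_a), names(partition_b)))
    stop("partitions cover different sample sets")
  b <- partition_b[names(partition_a)]
  la <- sort(unique(as.character(partition_a)))
  lb <- sort(unique(as.character(b)))
  if (length(lb) > 8) stop("too many cluster labels for exhaustive matching")
  k <- max(length(la), length(lb))
  lab_a <- c(la, rep(NA_character_, k - length(la)))
  perms <- perm_matrix(k)
  best <- NULL; best_agree <- -1
  for (r in seq_len(nrow(perms))) {
    map <- stats::setNames(lab_a[perms[r, seq_along(lb)]], lb)
    agree <- sum(map[as.character(b)] == as.character(partition_a), na.rm = TRUE)
    if (agree > best_agree) { best_agree <- agree; best <- map }
  }
  mismatch <- is.na(best[as.character(b)]) |
    best[as.character(b)] != as.character(partition_a)
  overall <- mean(mismatch)
  by_group <- NULL
  if (!is.null(groups)) {
    g <- groups[names(partition_a)]
    by_group <- tapply(mismatch, g, mean)
  }
  list(overall_mismatch = overall, by_group = by_group,
       n_mismatch = sum(mismatch), mapping = best)
}

# all permutations of 1..k as rows
perm_matrix <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}
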