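# Independent brute-force oracles used to check the package's fast paths.

# tiny abundance table from a plain matrix (auto names, renormalized)
toy_table <- function(m, kind = "virus", renormalize = TRUE) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("t%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  abundance_table(m, kind = kind, renormalize = renormalize)
}

# exhaustive k-medoids: minimal cost over all C(n, k) medoid sets
brute_pam_cost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# AUC by explicit pair counting
brute_auc <- function(scores, positive) {
  pos <- scores[as.logical(positive)]
  neg <- scores[!as.logical(positive)]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Benjamini-Hochberg by the literal step-up definition (no cummin tricks)
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    # q of the i-th smallest p: min over j >= i of p_(j) * m / j
    q[o[i]] <- min(p[o][i:m] * m / (i:m))
  }
  pmin(q, 1)
}

# natural connectivity via the matrix exponential itself (scaling-and-
# squaring Taylor series), an eigendecomposition-free route
expm_natcon <- function(adj) {
  n <- nrow(adj)
  s <- max(0L, ceiling(log2(max(rowSums(abs(adj)), 1))) + 1L)
  b <- adj / 2^s
  e <- diag(n)
  term <- diag(n)
  for (k in 1:40) {
    term <- term %*% b / k
    e <- e + term
  }
  for (i in seq_len(s)) e <- e %*% e
  log(sum(diag(e))) - log(n)
}

# Monte-Carlo permutation p-value for the Kruskal-Wallis statistic
perm_kw_p <- function(x, g, n_perm = 20000, seed = 1) {
  obs <- stats::kruskal.test(x, g)$statistic
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_perm)) {
    stat <- stats::kruskal.test(x, sample(g))$statistic
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# mean silhouette width straight from the definition
brute_silhouette <- function(d, labels) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), 0))
    s[i] <- if (sum(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Euclidean distance matrix of a coordinate set
coord_dist <- function(x) as.matrix(stats::dist(x))
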