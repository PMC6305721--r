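#' Select the most abundant taxa per kind for network inference
#'
#' Taxa whose overall mean relative abundance reaches the kind-specific
#' threshold are ranked by mean abundance and truncated to the `top_n` most
#' abundant. Defaults mirror the conventional gut-virome network filter:
#' 0.1% for viruses, 0.02% for bacteria, at most 107 taxa per kind.
#'
#' @param viral,bacterial [abundance_table()]s (taxa x samples).
#' @param virus_threshold,bacteria_threshold mean-abundance gates in (0,1).
#' @param top_n maximum number of taxa kept per kind.
#' @return list with filtered `viral` and `bacterial` tables (row order =
#'   descending mean abundance).
#' @export
select_top_taxa <- function(viral, bacterial, virus_threshold = 0.001,
                            bacteria_threshold = 0.0002, top_n = 107) {
  pick <- function(tab, thr, kind) {
    if (thr <= 0 || thr >= 1) stop("thresholds must be in (0, 1)")
    mu <- rowMeans(tab)
    keep <- which(mu >= thr)
    if (length(keep) < 2)
      stop("fewer than 2 ", kind, " taxa pass the abundance threshold")
    keep <- keep[order(mu[keep], decreasing = TRUE)]
    keep <- keep[seq_len(min(top_n, length(keep)))]
    structure(unclass(tab)[keep, , drop = FALSE],
              kind = taxon_kind(tab)[keep], class = class(tab))
  }
  list(viral = pick(viral, virus_threshold, "virus"),
       bacterial = pick(bacterial, bacteria_threshold, "bacteria"))
}

#' Spearman correlation of every virus-bacteria pair
#'
#' Spearman rho with midranks for ties; two-sided p from the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom (p = 0 at |rho| = 1); q-values by Benjamini-Hochberg
#' over all tested virus x bacteria pairs jointly. Pairs involving a
#' constant vector have undefined rho and are skipped (recorded in the
#' `skipped` attribute).
#'
#' @param viral,bacterial abundance tables (taxa x samples, same samples).
#' @param samples optional character vector restricting the computation to
#'   a sample subset (e.g. one cohort group); at least 4 samples.
#' @return data.frame: `virus`, `bacteria`, `rho`, `p`, `q`.
#' @export
correlation_edges <- function(viral, bacterial, samples = NULL) {
  if (!setequal(colnames(viral), colnames(bacterial)))
    stop("viral and bacterial tables cover different samples")
  if (is.null(samples)) samples <- colnames(viral)
  if (!all(samples %in% colnames(viral))) stop("unknown sample ids")
  if (length(samples) < 4) stop("need at least 4 samples")
  v <- unclass(viral)[, samples, drop = FALSE]
  b <- unclass(bacterial)[, samples, drop = FALSE]
  n <- length(samples)
  const_v <- apply(v, 1, function(x) max(x) == min(x))
  const_b <- apply(b, 1, function(x) max(x) == min(x))
  rho <- stats::cor(t(v[!const_v, , drop = FALSE]),
                    t(b[!const_b, , drop = FALSE]), method = "spearman")
  out <- data.frame(virus = rownames(rho)[row(rho)],
                    bacteria = colnames(rho)[col(rho)],
                    rho = as.vector(rho), row.names = NULL)
  tstat <- out$rho * sqrt((n - 2) / pmax(1 - out$rho^2, 0))
  out$p <- ifelse(abs(out$rho) >= 1, 0,
                  2 * stats::pt(-abs(tstat), df = n - 2))
  out$q <- stats::p.adjust(out$p, method = "BH")
  skipped <- c(rownames(v)[const_v], rownames(b)[const_b])
  if (length(skipped))
    message(length(skipped), " constant taxa skipped in correlation testing")
  attr(out, "skipped") <- skipped
  attr(out, "n_samples") <- n
  out
}

#' Threshold correlation candidates into a bipartite network
#'
#' Keeps virus-bacteria pairs with `|rho| >= rho_cut` and `q <= q_cut`;
#' nodes are the endpoints of surviving edges (taxa with no edge are not
#' part of the network).
#'
#' @param edges output of [correlation_edges()].
#' @param rho_cut,q_cut the two gates (conventionally 0.5 and 0.05).
#' @param abundance optional named vector of mean relative abundances used
#'   to annotate nodes (e.g. for export).
#' @return list of class `bipartite_network`: `nodes` (data.frame `id`,
#'   `kind`, `mean_abundance`), `edges` (data.frame `virus`, `bacteria`,
#'   `rho`, `q`, `sign`), `empty` flag.
#' @export
build_network <- function(edges, rho_cut = 0.5, q_cut = 0.05,
                          abundance = NULL) {
  keep <- abs(edges$rho) >= rho_cut & edges$q <= q_cut
  e <- edges[keep, c("virus", "bacteria", "rho", "q"), drop = FALSE]
  if (any(e$virus %in% e$bacteria)) stop("virus and bacteria ids overlap")
  e$sign <- ifelse(e$rho >= 0, "positive", "negative")
  rownames(e) <- NULL
  ids <- c(sort(unique(e$virus)), sort(unique(e$bacteria)))
  nodes <- data.frame(id = ids,
                      kind = rep(c("virus", "bacteria"),
                                 c(length(unique(e$virus)),
                                   length(unique(e$bacteria)))),
                      mean_abundance = if (is.null(abundance))
                                         rep(NA_real_, length(ids))
                                       else unname(abundance[ids]),
                      row.names = NULL)
  net <- structure(list(nodes = nodes, edges = e,
                        empty = nrow(e) == 0),
                   class = "bipartite_network")
  if (net$empty) warning("no edge passes the rho/q gates: empty network")
  net
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite virus-bacteria network: %d nodes (%d virus, %d bacteria), %d edges (%d positive)\n",
              nrow(x$nodes), sum(x$nodes$kind == "virus"),
              sum(x$nodes$kind == "bacteria"), nrow(x$edges),
              sum(x$edges$sign == "positive")))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("virus", "bacteria", "rho", "q", "sign")],
    directed = FALSE, vertices = net$nodes)
}

#' Graph density from node and edge counts
#'
#' Simple-graph density `2 M / (N (N - 1))`.
#' @param n_nodes,n_edges counts.
#' @return density in `[0, 1]`.
#' @examples
#' graph_density(138, 225)  # 0.0238 (control-network arithmetic)
#' @export
graph_density <- function(n_nodes, n_edges) {
  if (n_nodes < 2) stop("density needs at least 2 nodes")
  2 * n_edges / (n_nodes * (n_nodes - 1))
}

#' Natural connectivity of an adjacency matrix
#'
#' `ln((1/N) sum_i exp(lambda_i))` over the eigenvalues of the (unsigned)
#' adjacency matrix; a spectral measure of robustness equal to the log
#' average Estrada subgraph centrality. Zero for an edgeless graph.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @return natural connectivity in nats.
#' @export
natural_connectivity <- function(adj) {
  adj <- as.matrix(adj)
  n <- nrow(adj)
  if (n == 0) return(NaN)
  if (n == 1 || all(adj == 0)) return(0)
  lam <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(lam)
  lmax + log(sum(exp(lam - lmax))) - log(n)
}

#' Entropy of the degree distribution
#'
#' Degrees are normalized to a probability vector `d_i / sum(d)` and the
#' Shannon entropy `-sum p ln p` is taken over nodes with non-zero degree.
#'
#' @param degrees non-negative integer vector of node degrees.
#' @param base logarithm base (natural log by default; use 2 for bits).
#' @return entropy; 0 when at most one node has edges.
#' @export
degree_entropy <- function(degrees, base = exp(1)) {
  if (any(degrees < 0)) stop("negative degrees")
  s <- sum(degrees)
  if (s == 0) return(0)
  p <- degrees[degrees > 0] / s
  -sum(p * log(p, base = base))
}

#' Topological summary of a bipartite co-occurrence network
#'
#' Density (`2M / (N(N-1))`), degree distribution, Brandes betweenness
#' (on the unsigned graph, via \pkg{igraph}), natural connectivity, degree
#' entropy, and the linkage count: the number of virus nodes of degree
#' exactly one, i.e. viruses tied to a single bacterium.
#'
#' @param net a [build_network()] result with at least 2 nodes.
#' @param entropy_base base for [degree_entropy()].
#' @return list of class `network_topology`: `n_nodes`, `n_edges`,
#'   `density`, `degrees` (named), `betweenness` (named),
#'   `natural_connectivity`, `degree_entropy`, `linkage_count`.
#' @export
network_topology <- function(net, entropy_base = exp(1)) {
  stopifnot(inherits(net, "bipartite_network"))
  if (nrow(net$nodes) < 2) stop("need at least 2 nodes")
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  adj[adj > 0] <- 1
  virus_deg <- deg[net$nodes$id[net$nodes$kind == "virus"]]
  structure(list(n_nodes = igraph::vcount(g),
                 n_edges = igraph::ecount(g),
                 density = graph_density(igraph::vcount(g),
                                         igraph::ecount(g)),
                 degrees = deg,
                 betweenness = igraph::betweenness(g, directed = FALSE),
                 natural_connectivity = natural_connectivity(adj),
                 degree_entropy = degree_entropy(deg, base = entropy_base),
                 linkage_count = sum(virus_deg == 1),
                 entropy_base = entropy_base),
            class = "network_topology")
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("network topology: N=%d M=%d density=%.4f nat.conn=%.4f entropy=%.4f linkages=%d\n",
              x$n_nodes, x$n_edges, x$density, x$natural_connectivity,
              x$degree_entropy, x$linkage_count))
  invisible(x)
}

#' Natural-connectivity robustness under cumulative node removal
#'
#' Nodes are removed in a fixed order - degree-descending with
#' first-listed-node tie-break (targeted attack) or a seeded random order -
#' and natural connectivity is recomputed on the remaining induced graph
#' (isolated survivors are retained, so N shrinks only by removal) at every
#' removal fraction `0, step, 2 step, ...` while more than one node
#' remains.
#'
#' @param net a [build_network()] result.
#' @param strategy `"degree_desc"` or `"random"`.
#' @param step removal-fraction increment in (0, 1).
#' @param seed seed for the random strategy.
#' @return data.frame: `fraction_removed`, `n_removed`, `n_remaining`,
#'   `natural_connectivity`.
#' @export
robustness_curve <- function(net, strategy = c("degree_desc", "random"),
                             step = 0.05, seed = 1L) {
  strategy <- match.arg(strategy)
  if (step <= 0 || step >= 1) stop("step must be in (0, 1)")
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  deg <- igraph::degree(g)
  order_ids <- if (strategy == "degree_desc") {
    net$nodes$id[order(-deg[net$nodes$id], seq_len(n))]
  } else {
    local_seed(seed, sample(net$nodes$id))
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  adj <- adj[net$nodes$id, net$nodes$id]
  fracs <- seq(0, 1 - 1e-9, by = step)
  rows <- list()
  for (f in fracs) {
    n_rm <- floor(f * n)
    if (n - n_rm <= 1) break
    left <- setdiff(net$nodes$id, order_ids[seq_len(n_rm)])
    rows[[length(rows) + 1]] <-
      data.frame(fraction_removed = f, n_removed = n_rm,
                 n_remaining = length(left),
                 natural_connectivity =
                   natural_connectivity(adj[left, left, drop = FALSE]))
  }
  do.call(rbind, rows)
}

#' Export / import a bipartite network
#'
#' GraphML (node attributes `kind`, `mean_abundance`; edge attributes
#' `rho`, `q`, `sign`) via \pkg{igraph}, or a Cytoscape-friendly TSV edge
#' list (`virus`, `bacteria`, `rho`, `q`, `sign`). `import_network`
#' round-trips either format.
#'
#' @param net a [build_network()] result.
#' @param path file path.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @return `export_network` returns `path` invisibly; `import_network`
#'   returns a `bipartite_network`.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) == 0) {
      return(structure(list(nodes = data.frame(id = character(0),
                                               kind = character(0),
                                               mean_abundance = numeric(0)),
                            edges = data.frame(virus = character(0),
                                               bacteria = character(0),
                                               rho = numeric(0),
                                               q = numeric(0),
                                               sign = character(0)),
                            empty = TRUE),
                       class = "bipartite_network"))
    }
    nodes <- data.frame(id = igraph::V(g)$name,
                        kind = igraph::V(g)$kind,
                        mean_abundance =
                          if ("mean_abundance" %in%
                              igraph::vertex_attr_names(g))
                            igraph::V(g)$mean_abundance else NA_real_,
                        row.names = NULL)
    el <- igraph::as_edgelist(g)
    swap <- nodes$kind[match(el[, 1], nodes$id)] != "virus"
    e <- data.frame(virus = ifelse(swap, el[, 2], el[, 1]),
                    bacteria = ifelse(swap, el[, 1], el[, 2]),
                    rho = if (igraph::ecount(g)) igraph::E(g)$rho else numeric(0),
                    q = if (igraph::ecount(g)) igraph::E(g)$q else numeric(0),
                    sign = if (igraph::ecount(g)) igraph::E(g)$sign else character(0),
                    row.names = NULL)
  } else {
    e <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    nodes <- data.frame(id = c(sort(unique(e$virus)),
                               sort(unique(e$bacteria))),
                        kind = rep(c("virus", "bacteria"),
                                   c(length(unique(e$virus)),
                                     length(unique(e$bacteria)))),
                        mean_abundance = NA_real_, row.names = NULL)
  }
  structure(list(nodes = nodes, edges = e, empty = nrow(e) == 0),
            class = "bipartite_network")
}
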