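test_that("top-taxa selection applies threshold then rank truncation", {
  set.seed(101)
  v <- toy_table(matrix(rexp(200 * 8), 200, 8))
  b <- toy_table(matrix(rexp(200 * 8), 200, 8), kind = "bacteria")
  sel <- select_top_taxa(v, b, virus_threshold = 1e-6,
                         bacteria_threshold = 1e-6, top_n = 107)
  expect_equal(nrow(sel$viral), 107)      # >107 pass, truncated to 107
  expect_equal(nrow(sel$bacterial), 107)
  mu <- rowMeans(v)
  expect_true(all(rowMeans(sel$viral) >= sort(mu, decreasing = TRUE)[107]))
  # only taxa above the threshold survive when fewer than top_n pass
  m <- matrix(c(0.90, 0.05, 0.04, 0.01), 4, 6,
              dimnames = list(paste0("v", 1:4), paste0("s", 1:6)))
  tv <- abundance_table(m)
  sel2 <- select_top_taxa(tv, b, virus_threshold = 0.02,
                          bacteria_threshold = 1e-6)
  expect_equal(rownames(sel2$viral), c("v1", "v2", "v3"))
  expect_error(select_top_taxa(tv, b, virus_threshold = 0.95,
                               bacteria_threshold = 1e-6), "fewer than 2")
  expect_error(select_top_taxa(tv, b, virus_threshold = 1.5,
                               bacteria_threshold = 1e-6), "\\(0, 1\\)")
})

test_that("Spearman edges carry t-based p and BH q-values", {
  # columns built to sum to 1 so closure does not distort ranks
  n <- 12
  s <- paste0("s", 1:n)
  up <- (1:n) / (4 * n)
  v <- rbind(vUp = up, vDown = rev(up),
             vConst = rep(1 - (n + 1) / (4 * n), n))
  colnames(v) <- s
  set.seed(102)
  noise <- runif(n, 0, 0.25)
  b <- rbind(bUp = (4 * up)^2 / 4, bNoise = noise,
             bRest = 1 - (4 * up)^2 / 4 - noise)
  colnames(b) <- s
  tv <- abundance_table(v)
  tb <- abundance_table(b, kind = "bacteria")
  expect_message(ce <- correlation_edges(tv, tb), "constant")
  # closure with a constant third taxon preserves the monotone orders
  e <- function(vi, bi) ce[ce$virus == vi & ce$bacteria == bi, ]
  expect_equal(e("vUp", "bUp")$rho, 1)
  expect_equal(e("vUp", "bUp")$p, 0)
  expect_equal(e("vDown", "bUp")$rho, -1)
  expect_true("vConst" %in% attr(ce, "skipped"))
  # t-formula oracle for an intermediate correlation
  r <- e("vUp", "bNoise")$rho
  tt <- r * sqrt((n - 2) / (1 - r^2))
  expect_equal(e("vUp", "bNoise")$p, 2 * pt(-abs(tt), df = n - 2),
               tolerance = 1e-12)
  expect_error(correlation_edges(tv, tb, samples = s[1:3]), "4 samples")
})

test_that("BH q-values match the literal step-up definition", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.005, 0.04, 0.04), "BH"),
               c(0.015, 0.04, 0.04))
  # implementation route (p.adjust inside correlation_edges) vs oracle
  set.seed(103)
  for (m in c(1, 10, 1000)) {
    p <- runif(m)^2
    expect_equal(stats::p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("network construction gates on |rho| and q and keeps signs", {
  cand <- data.frame(virus = c("v1", "v2", "v3", "v4"),
                     bacteria = c("b1", "b2", "b3", "b4"),
                     rho = c(0.9, -0.7, 0.6, 0.9),
                     p = c(0.001, 0.002, 0.01, 0.3),
                     q = c(0.01, 0.02, 0.20, 0.40))
  net <- build_network(cand, rho_cut = 0.5, q_cut = 0.05)
  expect_equal(nrow(net$edges), 2)        # v3 fails q, v4 fails q
  expect_equal(nrow(net$nodes), 4)
  expect_equal(net$edges$sign, c("positive", "negative"))
  expect_false(net$empty)
  expect_warning(net0 <- build_network(cand, rho_cut = 0.99), "empty")
  expect_true(net0$empty)
  expect_equal(nrow(net0$nodes), 0)
})

test_that("topology reproduces printed-density arithmetic and closed forms", {
  expect_equal(round(graph_density(138, 225), 4), 0.0238)
  expect_equal(round(graph_density(121, 181), 4), 0.0249)
  expect_equal(round(graph_density(112, 182), 4), 0.0293)
  # triangle: eigenvalues {2, -1, -1}
  K3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(natural_connectivity(K3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(K3), 0.9963, tolerance = 1e-4)
  expect_equal(degree_entropy(c(2, 2, 2)), log(3), tolerance = 1e-12)
  # single edge: eigenvalues {+1, -1}
  e1 <- rbind(c(0, 1), c(1, 0))
  expect_equal(natural_connectivity(e1), log((exp(1) + exp(-1)) / 2),
               tolerance = 1e-12)
  expect_equal(natural_connectivity(e1), 0.4338, tolerance = 1e-4)
  expect_equal(degree_entropy(c(1, 1)), log(2), tolerance = 1e-12)
  # k-regular graph on n nodes has degree entropy ln n; relabel-invariant
  cyc <- igraph::as_adjacency_matrix(igraph::make_ring(7), sparse = FALSE)
  expect_equal(degree_entropy(rowSums(cyc)), log(7), tolerance = 1e-12)
  expect_equal(degree_entropy(c(3, 1, 2)), degree_entropy(c(1, 2, 3)))
  expect_equal(degree_entropy(c(2, 2), base = 2), 1)
  expect_equal(natural_connectivity(matrix(0, 4, 4)), 0)  # edgeless
})

test_that("natural connectivity matches the matrix-exponential oracle", {
  set.seed(104)
  for (rep in 1:10) {
    n <- sample(5:50, 1)
    a <- matrix(0, n, n)
    on <- sample(which(upper.tri(a)), min(3 * n, n * (n - 1) / 2))
    a[on] <- 1
    a <- a + t(a)
    expect_equal(natural_connectivity(a), expm_natcon(a), tolerance = 1e-9)
  }
  # non-increasing under edge removal
  a <- matrix(0, 10, 10)
  a[upper.tri(a)][sample(45, 20)] <- 1
  a <- a + t(a)
  prev <- natural_connectivity(a)
  edges <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  for (e in seq_len(nrow(edges))) {
    a[edges[e, 1], edges[e, 2]] <- 0
    a[edges[e, 2], edges[e, 1]] <- 0
    cur <- natural_connectivity(a)
    expect_lte(cur, prev + 1e-9)
    prev <- cur
  }
})

test_that("full topology summary and linkage count are consistent", {
  cand <- data.frame(virus = c("v1", "v2", "v3", "v3"),
                     bacteria = c("b1", "b1", "b1", "b2"),
                     rho = c(0.8, 0.7, 0.9, -0.6),
                     p = 0.001, q = 0.01)
  net <- build_network(cand)
  topo <- network_topology(net)
  expect_equal(topo$n_nodes, 5)
  expect_equal(topo$n_edges, 4)
  expect_equal(topo$density, 2 * 4 / (5 * 4))
  # virus degrees {1, 1, 2} -> two single-linkage viruses
  expect_equal(topo$linkage_count, 2)
  expect_equal(unname(topo$degrees[c("v1", "v2", "v3", "b1", "b2")]),
               c(1, 1, 2, 3, 1))
  # b1 lies on every shortest path between the degree-one leaves
  expect_gt(topo$betweenness[["b1"]], topo$betweenness[["v1"]])
  expect_equal(topo$degree_entropy, degree_entropy(topo$degrees))
})

test_that("robustness curves start at the static value and hit zero for stars", {
  star <- data.frame(virus = "vHub",
                     bacteria = paste0("b", 1:5),
                     rho = 0.9, p = 0.001, q = 0.01)
  net <- build_network(star)
  rc <- robustness_curve(net, strategy = "degree_desc", step = 0.2)
  topo <- network_topology(net)
  expect_equal(rc$natural_connectivity[1], topo$natural_connectivity)
  # first removal takes the hub: remainder is edgeless
  after <- rc$natural_connectivity[rc$n_removed >= 1]
  expect_true(all(abs(after) < 1e-12))
  # random strategy is seeded and reproducible
  r1 <- robustness_curve(net, strategy = "random", step = 0.2, seed = 5)
  r2 <- robustness_curve(net, strategy = "random", step = 0.2, seed = 5)
  expect_identical(r1, r2)
  expect_error(robustness_curve(net, step = 0), "step")
})

test_that("planted correlated pairs surface as network edges", {
  found <- 0; fp <- 0; tested <- 0
  for (s in 1:5) {
    cfg <- synth_config(group_sizes = c(A = 25, B = 24),
                        n_virus_taxa = 60, n_bacteria_taxa = 60,
                        correlated_pairs = data.frame(virus = c(10, 20, 30),
                                                      bacteria = c(11, 21, 31),
                                                      rho = c(0.85, -0.85,
                                                              0.9)),
                        seed = 200 + s)
    d <- generate_dataset(cfg)
    ce <- correlation_edges(d$viral, d$bacterial)
    net <- suppressWarnings(build_network(ce))
    planted <- sprintf("virus_%03d|bacteria_%03d", c(10, 20, 30),
                       c(11, 21, 31))
    got <- paste0(net$edges$virus, "|", net$edges$bacteria)
    found <- found + sum(planted %in% got)
    fp <- fp + sum(!(got %in% planted))
    tested <- tested + nrow(ce)
  }
  expect_gte(found / 15, 0.9)
  # false edges stay near the FDR level of the q gate
  expect_lte(fp / tested, 0.05 + 0.01)
})

test_that("network export round-trips through GraphML and TSV", {
  cand <- data.frame(virus = c("v1", "v2"), bacteria = c("b1", "b2"),
                     rho = c(0.9, -0.6), p = 0.001, q = c(0.01, 0.02))
  net <- build_network(cand)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f1, format = "graphml")
  back <- import_network(f1, format = "graphml")
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(back$nodes$kind[match(net$nodes$id, back$nodes$id)],
               net$nodes$kind)
  key <- function(x) paste(x$edges$virus, x$edges$bacteria, x$edges$sign)
  expect_setequal(key(back), key(net))
  expect_equal(sort(back$edges$rho), sort(net$edges$rho), tolerance = 1e-9)
  expect_true("negative" %in% back$edges$sign)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f2, format = "edge_tsv")
  back2 <- import_network(f2, format = "edge_tsv")
  expect_setequal(key(back2), key(net))
  # empty network still writes a valid file
  net0 <- suppressWarnings(build_network(cand, rho_cut = 0.99))
  f3 <- withr::local_tempfile(fileext = ".graphml")
  export_network(net0, f3)
  expect_true(import_network(f3)$empty)
  expect_error(export_network(net, f1, format = "dot"), "arg")
})
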