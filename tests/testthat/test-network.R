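# simulate a compositional count table from independent lognormal basis taxa
lognormal_counts <- function(n = 55, p = 30, depth = 20000, seed = 1,
                             basis = NULL) {
  set.seed(seed)
  if (is.null(basis)) basis <- matrix(rlnorm(n * p, 0, 1), n, p)
  cnt <- t(apply(basis, 1, function(b) rmultinom(1, depth, b / sum(b))[, 1]))
  dimnames(cnt) <- list(paste0("s", seq_len(n)), paste0("t", seq_len(p)))
  cnt
}

test_that("SparCC output is a proper correlation matrix", {
  cnt <- lognormal_counts(20, 8, seed = 30)
  rho <- sparcc(cnt, n_resample = 10, seed = 1)
  expect_true(isSymmetric(rho))
  expect_equal(unname(diag(rho)), rep(1, 8))
  expect_true(all(abs(rho) <= 1))
  expect_error(sparcc(cnt[, 1:3]), ">=4")
})

test_that("SparCC estimates are insensitive to per-sample count scaling", {
  cnt <- lognormal_counts(30, 12, seed = 31, depth = 5000)
  rho1 <- sparcc(cnt, n_resample = 50, seed = 2)
  rho2 <- sparcc(cnt * 10L, n_resample = 50, seed = 2)
  off <- lower.tri(rho1)
  expect_lt(mean(abs(rho1[off] - rho2[off])), 0.05)
})

test_that("network edges obey the strict rho and p thresholds", {
  rho <- matrix(c(1, 0.3, 0.8, -0.5,
                  0.3, 1, 0.1, 0.9,
                  0.8, 0.1, 1, 0.2,
                  -0.5, 0.9, 0.2, 1), 4,
                dimnames = list(letters[1:4], letters[1:4]))
  p <- matrix(0.01, 4, 4, dimnames = dimnames(rho)); diag(p) <- NA
  p["b", "d"] <- p["d", "b"] <- 0.5
  g <- build_network(rho, p)
  es <- apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "-"))
  # by enumeration: |rho|>0.3 & p<0.05 leaves a-c (0.8) and a-d (-0.5);
  # a-b is excluded at rho = 0.3 exactly, b-d by p = 0.5
  expect_setequal(es, c("a-c", "a-d"))
  expect_equal(igraph::graph_attr(g, "positive_edge_share"), 0.5)

  p[] <- 1
  g2 <- build_network(rho, p)
  expect_equal(igraph::vcount(g2), 0)
})

test_that("topology metrics hit closed forms and a brute-force oracle", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:5)
  tp <- node_topology(star)
  expect_equal(tp$degree[tp$asv_id == "v1"], 4)
  expect_equal(tp$betweenness[tp$asv_id == "v1"], 6)   # (4*3)/2
  expect_equal(tp$clustering[tp$asv_id == "v2"], 0)

  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- paste0("v", 1:3)
  expect_equal(node_topology(tri)$clustering, rep(1, 3))

  # 6-node graph against an independent BFS shortest-path oracle
  set.seed(32)
  g <- igraph::sample_gnp(6, 0.6)
  while (igraph::components(g)$no != 1) g <- igraph::sample_gnp(6, 0.6)
  igraph::V(g)$name <- paste0("v", 1:6)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  # Floyd-Warshall distances
  dm <- ifelse(adj == 1, 1, Inf); diag(dm) <- 0
  for (k in 1:6) for (i in 1:6) for (j in 1:6)
    dm[i, j] <- min(dm[i, j], dm[i, k] + dm[k, j])
  tp6 <- node_topology(g)
  expect_equal(tp6$closeness, unname(5 / rowSums(dm)), tolerance = 1e-12)
  # betweenness by path enumeration over all intermediate vertices
  btw <- numeric(6)
  npaths <- function(i, j, via_excluded = NULL) {
    # count shortest paths via dynamic programming on BFS layers
    if (i == j) return(1)
    total <- 0
    for (k in which(adj[, j] == 1))
      if (dm[i, k] == dm[i, j] - 1) total <- total + npaths(i, k)
    total
  }
  for (v in 1:6) {
    for (i in 1:6) for (j in 1:6) {
      if (i >= j || i == v || j == v) next
      tot <- npaths(i, j)
      thru <- if (dm[i, v] + dm[v, j] == dm[i, j])
        npaths(i, v) * npaths(v, j) else 0
      btw[v] <- btw[v] + thru / tot
    }
  }
  expect_equal(tp6$betweenness, btw, tolerance = 1e-10)
})

test_that("Zi-Pi connectivity and keystone classes follow their definitions", {
  # three 4-cliques plus one broker linked to a single node of each clique
  clique_edges <- do.call(rbind, lapply(0:2, function(m) t(combn(1:4 + 4 * m, 2))))
  g <- igraph::make_empty_graph(13, directed = FALSE)
  g <- igraph::add_edges(g, c(t(clique_edges), 13, 1, 13, 5, 13, 9))
  igraph::V(g)$name <- paste0("v", 1:13)
  zp <- modules_zipi(g, seed = 1)
  broker <- zp[zp$asv_id == "v13", ]
  # broker: degree 3 split 1/1/1 across the three clique modules (whichever
  # module it lands in) -> Pi = 1 - 3*(1/3)^2 = 2/3 > 0.62 -> connector
  expect_equal(broker$pi, 2 / 3, tolerance = 1e-12)
  expect_equal(as.character(broker$role), "connector")
  # an interior clique node keeps all edges inside its module -> Pi = 0
  interior <- zp[zp$asv_id == "v2", ]
  expect_equal(interior$pi, 0)
  expect_equal(as.character(interior$role), "peripheral")
  # partition of roles is exhaustive
  expect_false(anyNA(zp$role))
})

test_that("robustness matches enumeration on the star and the extremes", {
  full <- igraph::make_full_graph(6)
  igraph::V(full)$name <- paste0("v", 1:6)
  rb <- robustness(full, n_iter = 50, seed = 1)
  expect_equal(rb$mean, 1)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("v", 1:5)
  # remove 2 of 5: 4/10 removals hit the hub (share 0), 6/10 keep it (share 1)
  rb2 <- robustness(star, remove_frac = 0.5, n_iter = 4000, seed = 2)
  expect_equal(rb2$mean, 0.6, tolerance = 0.03)

  lonely <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(lonely)$name <- paste0("v", 1:5)
  expect_equal(robustness(lonely, n_iter = 20, seed = 1)$mean, 0)
})

test_that("stage subnetworks gain connectivity when late-stage taxa co-vary", {
  set.seed(33)
  n_per <- 12; p <- 12; depth <- 20000
  mk_stage <- function(rho_target, seed) {
    set.seed(seed)
    if (rho_target == 0) {
      basis <- matrix(rlnorm(n_per * p, 0, 1), n_per, p)
    } else {
      # taxa in correlated pairs on the log scale
      Sig <- diag(p)
      for (k in seq(1, p, 2)) Sig[k, k + 1] <- Sig[k + 1, k] <- rho_target
      z <- matrix(rnorm(n_per * p), n_per, p) %*% chol(Sig)
      basis <- exp(z)
    }
    lognormal_counts(n_per, p, depth, seed = seed + 1, basis = basis)
  }
  tb <- rbind(mk_stage(0, 100), mk_stage(0.95, 200))
  rownames(tb) <- paste0("s", 1:(2 * n_per))
  meta <- stages_meta(tb, c(0, 20))
  sn <- suppressWarnings(
    stage_subnetworks(tb, meta, min_n = 4, n_resample = 30, n_boot = 49,
                      seed = 3))
  s <- sn$summary[order(sn$summary$duration), ]
  expect_equal(nrow(s), 2)
  expect_gt(s$mean_degree[2], s$mean_degree[1])
})
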