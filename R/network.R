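# Dirichlet posterior draw of per-sample fractions from counts (add-one prior)
.dirichlet_fractions <- function(counts) {
  g <- matrix(stats::rgamma(length(counts), shape = counts + 1),
              nrow = nrow(counts), dimnames = dimnames(counts))
  g / rowSums(g)
}

# One SparCC basis solution from a samples x taxa fraction matrix.
# T_ij = var(log(x_i/x_j)); under the sparsity assumption the basis
# variances omega^2 solve a linear system; the most correlated pair above
# `exclusion_thresh` is removed from the system each iteration.
.sparcc_once <- function(fracs, n_iter = 20, exclusion_thresh = 0.1) {
  L <- log(fracs)
  V <- stats::cov(L)
  d <- diag(V)
  Tm <- outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) - 2 * V
  p <- ncol(Tm)
  if (p < 4) stop("SparCC basis solution needs >=4 taxa")
  M <- matrix(1, p, p); diag(M) <- 0          # included pairs
  rho <- NULL
  for (it in seq_len(n_iter + 1L)) {
    di <- rowSums(M)
    if (any(di < 2)) break                     # too few equations left
    A <- M + diag(di)
    t_i <- rowSums(Tm * M)
    w2 <- tryCatch(solve(A, t_i), error = function(e) NULL)
    if (is.null(w2)) break
    w2 <- pmax(w2, 1e-12)
    w <- sqrt(w2)
    new_rho <- (outer(w2, w2, "+") - Tm) / (2 * outer(w, w))
    new_rho <- pmin(pmax(new_rho, -1), 1)
    diag(new_rho) <- 1
    rho <- new_rho
    if (it > n_iter) break
    cand <- abs(rho) * M
    diag(cand) <- 0
    mx <- max(cand)
    if (mx <= exclusion_thresh) break
    ij <- which(cand == mx, arr.ind = TRUE)[1L, ]
    M[ij[1L], ij[2L]] <- M[ij[2L], ij[1L]] <- 0
  }
  rho
}

#' SparCC compositional correlation estimates
#'
#' Estimates basis correlations between taxa from compositional count data:
#' per resample, fractions are drawn from a Dirichlet posterior of each
#' sample's counts (add-one smoothing); the log-ratio variance matrix is
#' inverted for basis variances under a sparsity assumption, iteratively
#' excluding the most strongly correlated pair above `exclusion_thresh`;
#' correlations are averaged over resamples.
#'
#' @param table samples x taxa count matrix (>=4 taxa).
#' @param n_exclusion_iter exclusion iterations per solution.
#' @param exclusion_thresh |rho| above which the strongest pair is excluded.
#' @param n_resample Dirichlet resamples averaged for the estimate.
#' @param seed integer seed.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_exclusion_iter = 20, exclusion_thresh = 0.1,
                   n_resample = 100, seed = 1L) {
  if (ncol(table) < 4) stop("SparCC needs >=4 taxa")
  set.seed(seed)
  acc <- 0
  for (b in seq_len(n_resample)) {
    fr <- .dirichlet_fractions(table)
    acc <- acc + .sparcc_once(fr, n_exclusion_iter, exclusion_thresh)
  }
  rho <- acc / n_resample
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(table), colnames(table))
  rho
}

#' Bootstrap pseudo p-values for SparCC correlations
#'
#' Each bootstrap dataset shuffles every taxon's counts independently across
#' samples (destroying all between-taxon association while keeping marginal
#' distributions), recomputes SparCC, and the two-sided p-value is
#' (1 + #\{|rho_boot| >= |rho_obs|\}) / (n_boot + 1) per pair.
#'
#' @param table samples x taxa count matrix.
#' @param rho_obs observed SparCC matrix from [sparcc()].
#' @param n_boot bootstrap datasets.
#' @param n_resample Dirichlet resamples per bootstrap run (fewer than for
#'   the point estimate keeps the cost manageable).
#' @param n_exclusion_iter,exclusion_thresh as in [sparcc()].
#' @param seed integer seed.
#' @return matrix of p-values (diagonal NA).
#' @export
sparcc_pvalues <- function(table, rho_obs, n_boot = 999, n_resample = 10,
                           n_exclusion_iter = 20, exclusion_thresh = 0.1,
                           seed = 1L) {
  set.seed(seed)
  n <- nrow(table)
  exceed <- matrix(0, ncol(table), ncol(table))
  for (b in seq_len(n_boot)) {
    shuf <- apply(table, 2, function(col) col[sample.int(n)])
    rho_b <- sparcc(shuf, n_exclusion_iter, exclusion_thresh,
                    n_resample, seed = sample.int(.Machine$integer.max, 1))
    exceed <- exceed + (abs(rho_b) >= abs(rho_obs))
  }
  p <- (1 + exceed) / (n_boot + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(rho_obs)
  p
}

#' Build a co-occurrence network from SparCC estimates
#'
#' An edge is kept iff |rho| > `rho_min` (strict) and p < `alpha` (strict).
#' Isolated nodes are dropped.
#'
#' @param rho,p symmetric matrices over the same taxa.
#' @param labels optional rarity classification ([classify_taxa()] output)
#'   attached as a vertex attribute `class`.
#' @param rho_min,alpha edge thresholds.
#' @return undirected [igraph] graph with edge attributes rho, p, sign and
#'   graph attribute positive_edge_share.
#' @export
build_network <- function(rho, p, labels = NULL, rho_min = 0.3, alpha = 0.05) {
  stopifnot(all(dim(rho) == dim(p)))
  adj <- abs(rho) > rho_min & !is.na(p) & p < alpha
  adj[upper.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = ncol(rho), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = colnames(rho))
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx))
    g <- igraph::set_edge_attr(g, "rho", value = rho[idx])
    g <- igraph::set_edge_attr(g, "p", value = p[idx])
    g <- igraph::set_edge_attr(g, "sign", value = ifelse(rho[idx] > 0, 1L, -1L))
  }
  g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  if (!is.null(labels)) {
    cls <- as.character(labels$class[match(igraph::V(g)$name, labels$asv_id)])
    g <- igraph::set_vertex_attr(g, "class", value = cls)
  }
  pos <- if (igraph::ecount(g)) mean(igraph::E(g)$sign > 0) else NA_real_
  igraph::set_graph_attr(g, "positive_edge_share", pos)
}

#' Node-level topology of a co-occurrence network
#'
#' Degree, closeness centrality (computed within each connected component),
#' betweenness centrality and local clustering coefficient, all on the
#' unweighted undirected graph.
#'
#' @param g igraph graph.
#' @return data.frame: asv_id, class (if present), degree, closeness,
#'   betweenness, clustering.
#' @export
node_topology <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  cls <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  comp <- igraph::components(g)$membership
  clo <- rep(NA_real_, igraph::vcount(g))
  for (cm in unique(comp)) {
    vs <- which(comp == cm)
    if (length(vs) == 1) { clo[vs] <- 0; next }
    sub <- igraph::induced_subgraph(g, vs)
    clo[vs] <- igraph::closeness(sub, normalized = TRUE)
  }
  out <- data.frame(asv_id = igraph::V(g)$name, degree = unname(deg),
                    closeness = clo, betweenness = unname(btw),
                    clustering = unname(cls), stringsAsFactors = FALSE)
  if (!is.null(igraph::V(g)$class)) out$class <- igraph::V(g)$class
  out
}

#' Module detection, Zi-Pi connectivity and keystone classes
#'
#' Modules by greedy modularity maximization. Within-module connectivity
#' Zi = (k_is - mean k_s) / sd k_s over nodes of module s; among-module
#' connectivity Pi = 1 - sum_s (k_is / k_i)^2. Keystone classes: network hub
#' (Zi > 2.5 and Pi > 0.62), module hub (Zi > 2.5, Pi <= 0.62), connector
#' (Zi <= 2.5, Pi > 0.62), peripheral otherwise.
#'
#' @param g igraph graph with >=1 edge.
#' @param seed integer seed (module detection is deterministic but the seed
#'   is set for forward compatibility with stochastic methods).
#' @param method "greedy" (default) or "louvain".
#' @return data.frame: asv_id, module, zi, pi, role, degenerate (TRUE when
#'   the node's module has a single member or zero degree spread, in which
#'   case Zi = 0).
#' @export
modules_zipi <- function(g, seed = 1L, method = c("greedy", "louvain")) {
  method <- match.arg(method)
  if (igraph::ecount(g) == 0) stop("network has no edges")
  set.seed(seed)
  cm <- switch(method,
    greedy  = igraph::cluster_fast_greedy(g),
    louvain = igraph::cluster_louvain(g))
  mem <- igraph::membership(cm)
  deg <- igraph::degree(g)
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  nmod <- max(mem)
  # within-module degree of every node toward every module
  kis <- matrix(0, igraph::vcount(g), nmod)
  for (s in seq_len(nmod)) {
    kis[, s] <- as.numeric(adj %*% (mem == s))
  }
  k_own <- kis[cbind(seq_along(mem), as.integer(mem))]
  zi <- numeric(length(mem)); degen <- logical(length(mem))
  for (s in seq_len(nmod)) {
    vs <- which(mem == s)
    mu <- mean(k_own[vs]); sdv <- stats::sd(k_own[vs])
    if (length(vs) < 2 || !is.finite(sdv) || sdv == 0) {
      zi[vs] <- 0; degen[vs] <- TRUE
    } else zi[vs] <- (k_own[vs] - mu) / sdv
  }
  pi <- 1 - rowSums((kis / deg)^2)
  role <- ifelse(zi > 2.5 & pi > 0.62, "network_hub",
          ifelse(zi > 2.5, "module_hub",
          ifelse(pi > 0.62, "connector", "peripheral")))
  data.frame(asv_id = igraph::V(g)$name, module = as.integer(mem),
             zi = zi, pi = pi,
             role = factor(role, levels = c("network_hub", "module_hub",
                                            "connector", "peripheral")),
             degenerate = degen, stringsAsFactors = FALSE)
}

#' Network robustness to random node removal
#'
#' Per iteration, floor(`remove_frac` * n) nodes are removed uniformly at
#' random; the retained share is the fraction of surviving nodes that still
#' have at least one edge ("connected_share", default) or the share of
#' survivors in the largest connected component ("lcc_share").
#'
#' @param g igraph graph with >=4 nodes.
#' @param remove_frac fraction of nodes removed per iteration.
#' @param n_iter iterations.
#' @param seed integer seed.
#' @param mode retained-share definition.
#' @return list(mean, sd, values).
#' @export
robustness <- function(g, remove_frac = 0.5, n_iter = 1000, seed = 1L,
                       mode = c("connected_share", "lcc_share")) {
  mode <- match.arg(mode)
  n <- igraph::vcount(g)
  if (n < 4) stop("need >=4 nodes")
  n_rm <- floor(remove_frac * n)
  set.seed(seed)
  vals <- vapply(seq_len(n_iter), function(i) {
    keep <- setdiff(seq_len(n), sample.int(n, n_rm))
    sub <- igraph::induced_subgraph(g, keep)
    if (igraph::vcount(sub) == 0) return(0)
    if (mode == "connected_share") {
      mean(igraph::degree(sub) > 0)
    } else {
      max(igraph::components(sub)$csize) / igraph::vcount(sub)
    }
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), values = vals)
}

#' Per-stage correlation subnetworks
#'
#' Builds a SparCC network from the samples of each restoration stage and
#' reports stage-level mean degree for downstream analyses. Correlation
#' estimates from few samples are weak; stages below `min_n` samples are
#' skipped and every emitted stage carries a low-n warning when n < 10.
#'
#' @param table ASV count table (prefiltered to the taxa of interest).
#' @param meta chronosequence metadata.
#' @param labels optional rarity classification for vertex classes.
#' @param min_n minimum samples per stage.
#' @param rho_min,alpha edge thresholds.
#' @param n_resample,n_boot,seed SparCC parameters.
#' @return list(networks = per-stage igraph list, summary = data.frame with
#'   stage, duration, n_samples, n_nodes, n_edges, mean_degree).
#' @export
stage_subnetworks <- function(table, meta, labels = NULL, min_n = 4,
                              rho_min = 0.3, alpha = 0.05,
                              n_resample = 100, n_boot = 99, seed = 1L) {
  al <- align_inputs(table, meta)
  table <- al$table; meta <- al$meta
  stages <- split(seq_len(nrow(table)), meta$stage)
  nets <- list(); rows <- list()
  for (st in names(stages)) {
    ix <- stages[[st]]
    if (length(ix) < min_n) {
      warning("stage ", st, " skipped (<", min_n, " samples)")
      next
    }
    if (length(ix) < 10)
      warning("stage ", st, ": correlations from only ", length(ix),
              " samples are weak")
    sub <- table[ix, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    if (ncol(sub) < 4) { warning("stage ", st, ": <4 taxa, skipped"); next }
    if (any(apply(sub, 2, stats::sd) == 0))
      warning("stage ", st, ": constant taxa present, correlations unstable")
    rho <- sparcc(sub, n_resample = n_resample, seed = seed)
    p <- sparcc_pvalues(sub, rho, n_boot = n_boot,
                        n_resample = max(2, n_resample %/% 10), seed = seed)
    g <- build_network(rho, p, labels = labels, rho_min = rho_min, alpha = alpha)
    nets[[st]] <- g
    deg <- igraph::degree(g)
    rows[[st]] <- data.frame(stage = st,
                             duration = meta$duration[ix][1L],
                             n_samples = length(ix),
                             n_nodes = igraph::vcount(g),
                             n_edges = igraph::ecount(g),
                             mean_degree = if (length(deg)) mean(deg) else 0,
                             stringsAsFactors = FALSE)
  }
  list(networks = nets, summary = do.call(rbind, unname(rows)))
}
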