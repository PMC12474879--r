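# row minima of a matrix; max.col is C-level and much faster than apply()
.row_min <- function(M) M[cbind(seq_len(nrow(M)), max.col(-M, ties.method = "first"))]

#' Abundance-weighted beta mean nearest taxon distance (betaMNTD)
#'
#' For communities x and y with relative abundances f and patristic
#' distances d(i, j),
#' betaMNTD = 0.5 * ( sum_i f_i,x min_j d(i,j) + sum_j f_j,y min_i d(i,j) ),
#' the minima running over taxa present in the other community.
#'
#' @param x,y named count or abundance vectors (names = taxon ids); zeros
#'   denote absence.
#' @param tree phylo object covering all present taxa (ignored when `D`
#'   given).
#' @param D optional precomputed patristic distance matrix with dimnames.
#' @param weighted abundance-weighted (default) or presence/absence
#'   (equal weights).
#' @return non-negative scalar.
#' @export
bmntd <- function(x, y, tree = NULL, D = NULL, weighted = TRUE) {
  if (is.null(D)) {
    if (is.null(tree)) stop("supply a tree or a distance matrix")
    D <- ape::cophenetic.phylo(tree)
  }
  ix <- names(x)[x > 0]; iy <- names(y)[y > 0]
  miss <- setdiff(c(ix, iy), rownames(D))
  if (length(miss)) stop("taxa absent from tree: ", paste(miss, collapse = ", "))
  wx <- x[ix] / sum(x[ix]); wy <- y[iy] / sum(y[iy])
  if (!weighted) { wx[] <- 1 / length(ix); wy[] <- 1 / length(iy) }
  Dxy <- D[ix, iy, drop = FALSE]
  0.5 * (sum(wx * .row_min(Dxy)) + sum(wy * .row_min(t(Dxy))))
}

# betaMNTD from index vectors into D, used by the null loop
.bmntd_idx <- function(D, ix, wx, iy, wy) {
  Dxy <- D[ix, iy, drop = FALSE]
  0.5 * (sum(wx * .row_min(Dxy)) + sum(wy * .row_min(t(Dxy))))
}

#' Beta nearest taxon index (betaNTI) for one community pair
#'
#' The observed betaMNTD is standardized against a null in which taxon
#' labels are shuffled across the tips of the whole tree (richness and
#' abundances fixed): betaNTI = (obs - mean_null) / sd_null. |betaNTI| > 2
#' signals deterministic selection; the sign separates variable (> +2) from
#' homogeneous (< -2) selection.
#'
#' @param x,y named abundance vectors.
#' @param tree phylo object (ignored when `D` given).
#' @param D optional patristic matrix for all tips eligible for the shuffle.
#' @param n_null null randomizations.
#' @param seed integer seed.
#' @param weighted abundance weighting, as in [bmntd()].
#' @return list(bnti, obs, null_mean, null_sd, degenerate).
#' @export
bnti <- function(x, y, tree = NULL, D = NULL, n_null = 999, seed = 1L,
                 weighted = TRUE) {
  if (is.null(D)) {
    if (is.null(tree)) stop("supply a tree or a distance matrix")
    D <- ape::cophenetic.phylo(tree)
  }
  tips <- rownames(D)
  ix0 <- names(x)[x > 0]; iy0 <- names(y)[y > 0]
  miss <- setdiff(c(ix0, iy0), tips)
  if (length(miss)) stop("taxa absent from tree: ", paste(miss, collapse = ", "))
  union_taxa <- union(ix0, iy0)
  u <- length(union_taxa)
  pos_x <- match(ix0, union_taxa); pos_y <- match(iy0, union_taxa)
  wx <- x[ix0] / sum(x[ix0]); wy <- y[iy0] / sum(y[iy0])
  if (!weighted) { wx[] <- 1 / length(ix0); wy[] <- 1 / length(iy0) }
  obs <- .bmntd_idx(D, match(ix0, tips), wx, match(iy0, tips), wy)
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    su <- sample.int(length(tips), u)
    .bmntd_idx(D, su[pos_x], wx, su[pos_y], wy)
  }, numeric(1))
  m <- mean(nulls); s <- stats::sd(nulls)
  degenerate <- !is.finite(s) || s == 0
  list(bnti = if (degenerate) 0 else (obs - m) / s,
       obs = obs, null_mean = m, null_sd = s, degenerate = degenerate)
}

#' Bray–Curtis-based Raup–Crick index (RC_bray) for one community pair
#'
#' Null communities preserve each sample's observed richness and total
#' abundance: taxa are first drawn (without replacement, probability
#' proportional to regional occupancy) up to the observed richness, then the
#' observed number of individuals is allocated multinomially with probability
#' proportional to the regional relative abundance of the selected taxa. Both
#' members of the pair are drawn independently per null replicate. RC is the
#' fraction of null Bray–Curtis values below the observed one (ties counted
#' half), rescaled to \[-1, 1\]. RC > 0.95 signals dispersal limitation and
#' RC < -0.95 homogenizing dispersal among pairs not governed by selection.
#'
#' @param x,y named integer count vectors.
#' @param pool_occ named occupancy (number or fraction of samples occupied)
#'   of every taxon in the regional pool.
#' @param pool_relab named regional relative abundances, same taxa.
#' @param n_null null replicates.
#' @param seed integer seed.
#' @return list(rc, obs, null) with `null` the vector of null distances.
#' @export
rc_bray <- function(x, y, pool_occ, pool_relab, n_null = 999, seed = 1L) {
  taxa <- names(pool_occ)
  stopifnot(identical(taxa, names(pool_relab)))
  miss <- setdiff(c(names(x)[x > 0], names(y)[y > 0]), taxa)
  if (length(miss)) stop("taxa absent from pool: ", paste(miss, collapse = ", "))
  rich <- c(sum(x > 0), sum(y > 0))
  tot <- c(sum(x), sum(y))
  if (any(rich > length(taxa))) stop("observed richness exceeds pool richness")
  bc <- function(a, b) {
    A <- sum(pmin(a, b))
    1 - 2 * A / (sum(a) + sum(b))
  }
  xf <- x[match(taxa, names(x))]; xf[is.na(xf)] <- 0
  yf <- y[match(taxa, names(y))]; yf[is.na(yf)] <- 0
  obs <- bc(xf, yf)
  draw <- function(S, N) {
    sel <- sample.int(length(taxa), S, prob = pool_occ)
    cnt <- numeric(length(taxa))
    # every selected taxon gets one individual, the rest by abundance
    cnt[sel] <- 1
    if (N > S)
      cnt[sel] <- cnt[sel] + stats::rmultinom(1, N - S, prob = pool_relab[sel])[, 1]
    cnt
  }
  set.seed(seed)
  nulls <- vapply(seq_len(n_null), function(i) {
    bc(draw(rich[1L], tot[1L]), draw(rich[2L], tot[2L]))
  }, numeric(1))
  frac <- (sum(nulls < obs) + 0.5 * sum(nulls == obs)) / n_null
  list(rc = 2 * frac - 1, obs = obs, null = nulls)
}

#' Assign the five assembly processes from betaNTI and RC_bray
#'
#' variable selection iff betaNTI > 2; homogeneous selection iff
#' betaNTI < -2; among pairs with |betaNTI| < 2 (selection absent):
#' dispersal limitation iff RC > 0.95, homogenizing dispersal iff
#' RC < -0.95, otherwise undominated.
#'
#' @param bnti numeric vector of betaNTI values.
#' @param rc numeric vector of RC_bray values (same length).
#' @return factor with the five process levels.
#' @export
assign_process <- function(bnti, rc) {
  stopifnot(length(bnti) == length(rc))
  out <- ifelse(bnti > 2, "variable_selection",
         ifelse(bnti < -2, "homogeneous_selection",
         ifelse(rc > 0.95, "dispersal_limitation",
         ifelse(rc < -0.95, "homogenizing_dispersal", "undominated"))))
  factor(out, levels = c("variable_selection", "homogeneous_selection",
                         "dispersal_limitation", "homogenizing_dispersal",
                         "undominated"))
}

#' Fraction of sample pairs assigned to each assembly process
#'
#' @param pairs data.frame with a `process` column (or a factor of
#'   processes).
#' @return named numeric vector of five fractions summing to 1.
#' @export
partition_processes <- function(pairs) {
  pr <- if (is.data.frame(pairs)) pairs$process else pairs
  if (!length(pr)) stop("no pairs")
  tab <- table(factor(pr, levels = levels(assign_process(0, 0))))
  fr <- as.numeric(tab) / length(pr)
  names(fr) <- names(tab)
  fr
}

#' Pairwise assembly analysis of an ASV table
#'
#' Computes betaMNTD, betaNTI, RC_bray and the assigned process for every
#' requested sample pair. The regional pool for RC_bray is the analysed
#' table itself (occupancy and pooled relative abundance across all its
#' samples); for a subcommunity analysis pass the table restricted to the
#' taxa of that class (re-normalization is implicit in the indices). The
#' betaNTI null shuffles taxa across every tip of the supplied tree, so the
#' tree defines the phylogenetic pool.
#' Per-pair null seeds are derived from `seed` plus the pair index, so
#' results are independent of pair order.
#'
#' @param table ASV count table.
#' @param tree phylo object covering the table's taxa.
#' @param n_null null randomizations per pair for both indices.
#' @param seed master seed.
#' @param pairs optional 2-column matrix of sample index pairs; default all
#'   pairs.
#' @param weighted abundance weighting for betaMNTD.
#' @return data.frame: sample_i, sample_j, bmntd_obs, bnti, rc, process,
#'   degenerate.
#' @export
assembly_analysis <- function(table, tree, n_null = 999, seed = 1L,
                              pairs = NULL, weighted = TRUE) {
  validate_asv_table(table)
  keep <- colSums(table) > 0
  table <- table[, keep, drop = FALSE]
  miss <- setdiff(colnames(table), tree$tip.label)
  if (length(miss))
    stop("taxa absent from tree: ", paste(utils::head(miss, 5), collapse = ", "))
  # the taxa-shuffle null runs across every tip of the supplied tree, so the
  # tree defines the phylogenetic pool; prune it upstream to narrow the pool
  D <- ape::cophenetic.phylo(tree)
  pool_occ <- colSums(table > 0)
  pool_relab <- colSums(table) / sum(table)
  if (is.null(pairs)) pairs <- t(utils::combn(nrow(table), 2))
  res <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    x <- table[i, ]; y <- table[j, ]
    pair_seed <- (seed + 7919L * k) %% .Machine$integer.max
    b <- bnti(x, y, D = D, n_null = n_null, seed = pair_seed,
              weighted = weighted)
    r <- rc_bray(x, y, pool_occ, pool_relab, n_null = n_null,
                 seed = pair_seed + 1L)
    data.frame(sample_i = rownames(table)[i], sample_j = rownames(table)[j],
               bmntd_obs = b$obs, bnti = b$bnti, rc = r$rc,
               degenerate = b$degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$process <- assign_process(out$bnti, out$rc)
  out
}

#' Stage-wise assembly-process fractions
#'
#' Restricts the pairwise analysis to within-stage sample pairs and reports
#' the five process fractions per stage (and the per-pair table).
#'
#' @param table ASV count table.
#' @param tree phylogeny.
#' @param meta chronosequence metadata with a `stage` column.
#' @param n_null,seed,weighted passed to [assembly_analysis()].
#' @return list(pairs, fractions) where `fractions` is a stages x processes
#'   matrix with rows summing to 1.
#' @export
stagewise_assembly <- function(table, tree, meta, n_null = 999, seed = 1L,
                               weighted = TRUE) {
  al <- align_inputs(table, meta)
  table <- al$table; meta <- al$meta
  stages <- split(seq_len(nrow(table)), meta$stage)
  small <- names(stages)[vapply(stages, length, 1L) < 2]
  if (length(small)) {
    warning("stage(s) with <2 samples skipped: ", paste(small, collapse = ", "))
    stages <- stages[!names(stages) %in% small]
  }
  if (!length(stages)) stop("no stage with >=2 samples")
  pairs <- do.call(rbind, lapply(stages, function(ix) t(utils::combn(ix, 2))))
  pw <- assembly_analysis(table, tree, n_null = n_null, seed = seed,
                          pairs = pairs, weighted = weighted)
  pw$stage <- meta$stage[match(pw$sample_i, meta$sample_id)]
  fr <- t(vapply(split(pw$process, pw$stage), function(p)
    partition_processes(p), numeric(5)))
  list(pairs = pw, fractions = fr)
}
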