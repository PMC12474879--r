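#' Bray–Curtis dissimilarity matrix
#'
#' With A = sum of per-taxon minima and B, C the sample-specific remainders,
#' d = (B + C) / (2A + B + C). Computed via [vegan::vegdist()].
#'
#' @param x samples x taxa abundance matrix with no all-zero rows.
#' @return symmetric full matrix with zero diagonal, entries in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  if (any(rowSums(x) <= 0))
    stop("all-zero sample(s): ", paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  as.matrix(vegan::vegdist(x, method = "bray"))
}

#' Baselga partition of Bray–Curtis into balanced-variation and
#' abundance-gradient components
#'
#' For each sample pair, with A = sum of minima and B, C the remainders,
#' the balanced-variation (species replacement / turnover) component is
#' min(B,C) / (A + min(B,C)) and the abundance-gradient (richness difference)
#' component is the rest of the Bray–Curtis distance, so
#' balanced + gradient = d exactly.
#'
#' @param x samples x taxa abundance matrix.
#' @return list with `pairs` (data.frame: sample_i, sample_j, total, balanced,
#'   gradient) and `summary` (mean similarity, turnover share and
#'   richness-difference share; the three sum to 1).
#' @export
partition_beta <- function(x) {
  if (any(rowSums(x) <= 0))
    stop("all-zero sample(s): ", paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  n <- nrow(x)
  idx <- utils::combn(n, 2)
  res <- apply(idx, 2, function(ij) {
    xi <- x[ij[1L], ]; xj <- x[ij[2L], ]
    A <- sum(pmin(xi, xj))
    B <- sum(xi) - A
    C <- sum(xj) - A
    d <- (B + C) / (2 * A + B + C)
    bal <- min(B, C) / (A + min(B, C))
    c(total = d, balanced = bal, gradient = d - bal)
  })
  pairs <- data.frame(sample_i = rownames(x)[idx[1L, ]],
                      sample_j = rownames(x)[idx[2L, ]],
                      t(res), stringsAsFactors = FALSE)
  summary <- c(similarity = 1 - mean(pairs$total),
               turnover   = mean(pairs$balanced),
               richness_difference = mean(pairs$gradient))
  list(pairs = pairs, summary = summary)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS with seeded random restarts via [vegan::metaMDS()]
#' run directly on the supplied distances (no transformation).
#'
#' @param d distance matrix ("dist" or symmetric matrix).
#' @param k dimensions.
#' @param seed integer seed for the restarts.
#' @param trymax maximum random restarts.
#' @return list(points, stress, converged).
#' @export
nmds_config <- function(d, k = 2, seed = 1L, trymax = 20) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < k + 1) stop("need more samples than NMDS dimensions")
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, trymax = trymax, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  if (!isTRUE(fit$converged))
    warning("NMDS did not converge in ", trymax, " restarts; best configuration returned")
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged))
}

# correlation between lower triangles of two distance matrices
.tri_cor <- function(d1, d2, method) {
  v1 <- d1[lower.tri(d1)]; v2 <- d2[lower.tri(d2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero-variance distance matrix in Mantel correlation")
  stats::cor(v1, v2, method = method)
}

#' Mantel test between two distance matrices
#'
#' Permutation test of the (Spearman or Pearson) correlation between the
#' lower triangles, permuting rows and columns of the second matrix jointly.
#' p uses the +1 correction: (1 + #\{r_perm >= r_obs\}) / (nperm + 1).
#'
#' @param d1,d2 distance matrices over the same samples in the same order.
#' @param method "spearman" (default) or "pearson".
#' @param nperm number of random permutations; ignored when `permutations`
#'   is given.
#' @param seed integer seed.
#' @param permutations optional matrix of permutations (one per row) for an
#'   exhaustive or externally controlled test.
#' @return list(r, p, nperm).
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        nperm = 999, seed = 1L, permutations = NULL) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  n <- nrow(d1)
  r_obs <- .tri_cor(d1, d2, method)
  if (is.null(permutations)) {
    set.seed(seed)
    perms <- t(vapply(seq_len(nperm), function(i) sample.int(n), integer(n)))
  } else perms <- permutations
  r_null <- apply(perms, 1, function(p) .tri_cor(d1, d2[p, p], method))
  p <- (1 + sum(r_null >= r_obs)) / (nrow(perms) + 1)
  list(r = r_obs, p = p, nperm = nrow(perms))
}

#' Analysis of similarities (ANOSIM)
#'
#' R = (mean between-group rank distance - mean within-group rank distance)
#' divided by n(n-1)/4, with a permutation p-value using the +1 correction.
#'
#' @param d distance matrix.
#' @param groups group labels, >=2 groups of >=2 samples.
#' @param nperm random permutations; ignored when `permutations` given.
#' @param seed integer seed.
#' @param permutations optional permutation matrix (one per row).
#' @return list(R, p, nperm).
#' @export
anosim_test <- function(d, groups, nperm = 999, seed = 1L, permutations = NULL) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2))
    stop("need >=2 groups each with >=2 samples")
  n <- nrow(d)
  rk <- d
  rk[] <- 0
  rk[lower.tri(rk)] <- rank(d[lower.tri(d)])
  rk <- rk + t(rk)
  stat <- function(g) {
    within <- outer(g, g, "==")[lower.tri(d)]
    r <- rk[lower.tri(rk)]
    (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
  }
  R_obs <- stat(groups)
  if (is.null(permutations)) {
    set.seed(seed)
    perms <- t(vapply(seq_len(nperm), function(i) sample.int(n), integer(n)))
  } else perms <- permutations
  R_null <- apply(perms, 1, function(p) stat(groups[p]))
  p <- (1 + sum(R_null >= R_obs)) / (nrow(perms) + 1)
  list(R = R_obs, p = p, nperm = nrow(perms))
}

#' SIMPER: per-taxon contributions to between-group Bray–Curtis
#'
#' For a pair of samples x, y the contribution of taxon i is
#' |x_i - y_i| / sum_j (x_j + y_j); contributions sum to the pair's
#' Bray–Curtis distance. Contributions are averaged over all between-group
#' pairs (pooled over group pairs when more than two groups are given).
#'
#' @param table samples x taxa abundance matrix.
#' @param groups group labels.
#' @return data.frame: asv_id, contribution (mean over between-group pairs),
#'   share (contribution / sum of contributions).
#' @export
simper_contrib <- function(table, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >=2 groups")
  if (any(rowSums(table) <= 0)) stop("all-zero sample(s)")
  n <- nrow(table)
  idx <- utils::combn(n, 2)
  between <- groups[idx[1L, ]] != groups[idx[2L, ]]
  if (!any(between)) stop("no between-group pairs")
  idx <- idx[, between, drop = FALSE]
  acc <- rep(0, ncol(table))
  for (k in seq_len(ncol(idx))) {
    xi <- table[idx[1L, k], ]; xj <- table[idx[2L, k], ]
    acc <- acc + abs(xi - xj) / sum(xi + xj)
  }
  contrib <- acc / ncol(idx)
  data.frame(asv_id = colnames(table), contribution = unname(contrib),
             share = unname(contrib / sum(contrib)), stringsAsFactors = FALSE)
}

#' Fit and compare richness-versus-duration regression models
#'
#' Candidates: linear a + bt; quadratic a + bt + ct^2; logarithmic
#' a + b ln(t + 1); and the restoration model a (1 - exp(-k t)) + c (an
#' initial increase followed by stabilization, fitted by nonlinear least
#' squares with a, k > 0). Models are compared by Gaussian AIC
#' n ln(RSS/n) + 2p and the lowest wins.
#'
#' @param duration numeric vector of restoration ages.
#' @param richness numeric response of the same length (>=5 points).
#' @return list with `models` (data.frame: model, p, RSS, AIC, converged),
#'   `best` (name of the AIC-minimal model) and `fits` (fitted model objects).
#' @export
fit_richness_models <- function(duration, richness) {
  stopifnot(length(duration) == length(richness))
  if (length(duration) < 5) stop("need >=5 points")
  n <- length(richness)
  dat <- data.frame(t = duration, y = richness)
  fits <- list(
    linear    = stats::lm(y ~ t, data = dat),
    quadratic = stats::lm(y ~ t + I(t^2), data = dat),
    logarithmic = stats::lm(y ~ log(t + 1), data = dat))
  rng <- diff(range(richness))
  restoration <- tryCatch(
    minpack.lm::nlsLM(y ~ a * (1 - exp(-k * t)) + c0, data = dat,
                      start = list(a = max(rng, 1e-6), k = 1 / max(stats::median(duration), 1),
                                   c0 = min(richness)),
                      lower = c(a = 1e-9, k = 1e-9, c0 = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      warning("restoration model did not converge: ", conditionMessage(e))
      NULL
    })
  if (!is.null(restoration)) fits$restoration <- restoration
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  p <- vapply(fits, function(f) length(stats::coef(f)), numeric(1))
  aic <- n * log(pmax(rss, .Machine$double.eps) / n) + 2 * p
  models <- data.frame(model = names(fits), p = p, RSS = rss, AIC = aic,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(models = models, best = models$model[which.min(models$AIC)], fits = fits)
}
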