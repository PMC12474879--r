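test_that("Bray-Curtis matches the A/B/C formula and its bounds", {
  tb <- rbind(s1 = c(2, 1, 0), s2 = c(1, 1, 1), s3 = c(2, 1, 0),
              s4 = c(0, 0, 5))
  colnames(tb) <- c("a", "b", "c")
  d <- bray_curtis(tb)
  expect_equal(d["s1", "s2"], 1 / 3, tolerance = 1e-12)  # A=2,B=1,C=1
  expect_equal(d["s1", "s3"], 0)
  expect_equal(d["s1", "s4"], 1)                          # disjoint
  expect_true(isSymmetric(d))
  expect_error(bray_curtis(rbind(tb, s5 = 0)), "s5")
})

test_that("distance operations agree with a naive double loop", {
  tb <- random_table(5, 8, seed = 11)
  d <- bray_curtis(tb)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(d[i, j], bc_pair(tb[i, ], tb[j, ]), tolerance = 1e-12)
})

test_that("Baselga partition separates replacement from nesting and sums to d", {
  # equal-total pure replacement
  tb <- rbind(s1 = c(5, 0), s2 = c(0, 5)); colnames(tb) <- c("a", "b")
  pp <- partition_beta(tb)$pairs
  expect_equal(pp$balanced, 1)
  expect_equal(pp$gradient, 0)
  # perfect nesting
  tb2 <- rbind(s1 = c(5, 5), s2 = c(5, 0)); colnames(tb2) <- c("a", "b")
  pp2 <- partition_beta(tb2)$pairs
  expect_equal(pp2$balanced, 0)
  expect_equal(pp2$gradient, pp2$total)

  # identity over 1000 random pairs
  set.seed(12)
  for (k in 1:1000) {
    x <- rpois(10, 3); y <- rpois(10, 3)
    if (sum(x) == 0 || sum(y) == 0) next
    m <- rbind(s1 = x, s2 = y); colnames(m) <- paste0("t", 1:10)
    pr <- partition_beta(m)$pairs
    expect_equal(pr$balanced + pr$gradient, pr$total, tolerance = 1e-12)
    expect_equal(pr$total, bc_pair(x, y), tolerance = 1e-12)
  }
  # summary triplet sums to 1
  sm <- partition_beta(random_table(6, 10, seed = 13))$summary
  expect_equal(sum(sm), 1, tolerance = 1e-12)
})

test_that("NMDS reaches near-zero stress on Euclidean-embeddable distances", {
  set.seed(14)
  pts <- matrix(rnorm(20), 10, 2)
  nm <- suppressWarnings(nmds_config(dist(pts), seed = 2))
  expect_lt(nm$stress, 0.01)
})

test_that("ANOSIM equals its rank formula, matches vegan and an exhaustive p", {
  tb <- random_table(6, 10, seed = 15)
  grp <- rep(c("A", "B"), each = 3)
  d <- bray_curtis(tb)
  res <- anosim_test(d, grp, nperm = 99, seed = 1)
  vg <- vegan::anosim(as.dist(d), grp, permutations = 9)
  expect_equal(res$R, unname(vg$statistic), tolerance = 1e-12)

  # perfectly separated groups -> R = 1
  tb2 <- rbind(a1 = c(9, 8, 0, 0), a2 = c(8, 9, 0, 0),
               b1 = c(0, 0, 9, 8), b2 = c(0, 0, 8, 9))
  colnames(tb2) <- paste0("t", 1:4)
  expect_equal(anosim_test(bray_curtis(tb2), c("A", "A", "B", "B"),
                           nperm = 49, seed = 1)$R, 1)

  # exhaustive permutation p equals the enumerated exceedance fraction
  perms <- all_perms(6)
  ex <- anosim_test(d, grp, permutations = perms)
  stat_of <- function(g) {
    rk <- matrix(0, 6, 6)
    rk[lower.tri(rk)] <- rank(d[lower.tri(d)])
    rk <- rk + t(rk)
    within <- outer(g, g, "==")[lower.tri(d)]
    r <- rk[lower.tri(rk)]
    (mean(r[!within]) - mean(r[within])) / (6 * 5 / 4)
  }
  r_all <- apply(perms, 1, function(p) stat_of(grp[p]))
  expect_equal(ex$p, (1 + sum(r_all >= ex$R)) / (nrow(perms) + 1))
})

test_that("Mantel statistic and exhaustive p match brute-force enumeration", {
  set.seed(16)
  tb <- random_table(5, 8, seed = 16)
  d1 <- bray_curtis(tb)
  dur <- c(0, 2, 5, 11, 20)
  d2 <- as.matrix(dist(dur))
  perms <- all_perms(5)
  got <- mantel_test(d1, d2, method = "pearson", permutations = perms)
  # independent brute force
  lower <- lower.tri(d1)
  r_obs <- cor(d1[lower], d2[lower])
  r_all <- apply(perms, 1, function(p) cor(d1[lower], d2[p, p][lower]))
  expect_equal(got$r, r_obs, tolerance = 1e-12)
  expect_equal(got$p, (1 + sum(r_all >= r_obs)) / (nrow(perms) + 1))
  # vegan cross-check of the statistic
  vg <- vegan::mantel(d1, d2, method = "pearson", permutations = 9)
  expect_equal(got$r, unname(vg$statistic), tolerance = 1e-12)

  expect_equal(mantel_test(d1, d1, nperm = 9, seed = 1)$r, 1)
  expect_error(mantel_test(d1, matrix(1, 5, 5), nperm = 9), "zero-variance")
})

test_that("SIMPER contributions decompose the pairwise distance", {
  # single differing ASV carries 100% of the contribution
  tb <- rbind(s1 = c(5, 5, 9), s2 = c(5, 5, 1))
  colnames(tb) <- c("a", "b", "c")
  sp <- simper_contrib(tb, c("A", "B"))
  expect_equal(sp$share[sp$asv_id == "c"], 1)

  # contributions sum to the pair's Bray-Curtis distance (hand expansion)
  x <- c(3, 0, 7); y <- c(1, 4, 2)
  tb2 <- rbind(s1 = x, s2 = y); colnames(tb2) <- c("a", "b", "c")
  sp2 <- simper_contrib(tb2, c("A", "B"))
  expect_equal(sp2$contribution,
               abs(x - y) / sum(x + y), tolerance = 1e-12)
  expect_equal(sum(sp2$contribution), bc_pair(x, y), tolerance = 1e-12)

  # vegan cross-check of averaged contributions over 2 groups
  tb3 <- random_table(6, 5, seed = 17)
  grp <- rep(c("A", "B"), each = 3)
  sp3 <- simper_contrib(tb3, grp)
  vg <- summary(vegan::simper(tb3, grp, permutations = 0))$A_B
  expect_equal(sp3$contribution[match(rownames(vg), sp3$asv_id)],
               unname(vg$average), tolerance = 1e-12)
})

test_that("model selection finds an exact line and the restoration curve", {
  t_ <- c(0, 1, 3, 4, 5, 6, 11, 20, 23, 26, 53)
  fm <- fit_richness_models(t_, 2 + 3 * t_)
  expect_equal(fm$best, "linear")
  expect_lt(fm$models$RSS[fm$models$model == "linear"], 1e-12)
  # an exact fit always beats a misfitting model on AIC
  expect_lt(fm$models$AIC[fm$models$model == "linear"],
            fm$models$AIC[fm$models$model == "logarithmic"])

  wins <- 0
  for (s in 1:100) {
    set.seed(s)
    y <- 10 * (1 - exp(-0.3 * t_)) + rnorm(length(t_), 0, 0.1)
    fit <- suppressWarnings(fit_richness_models(t_, y))
    wins <- wins + (fit$best == "restoration")
  }
  expect_gte(wins, 95)
})
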