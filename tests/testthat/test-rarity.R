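test_that("rarity classes follow the strict mean-relative-abundance thresholds", {
  # two samples of 100000 reads: asv_b sits exactly on the rare boundary
  tb <- rbind(s1 = c(a = 50000, b = 2, c = 28, d = 49970),
              s2 = c(a = 50000, b = 2, c = 28, d = 49970))
  lab <- classify_taxa(tb)
  expect_equal(as.character(lab$class[lab$asv_id == "a"]), "abundant")
  # mean relabund exactly 0.002% -> intermediate (strict inequality)
  expect_equal(lab$mean_relabund[lab$asv_id == "b"], 2e-5)
  expect_equal(as.character(lab$class[lab$asv_id == "b"]), "intermediate")
  # 0.028% exactly -> intermediate as well
  expect_equal(lab$mean_relabund[lab$asv_id == "c"], 2.8e-4)
  expect_equal(as.character(lab$class[lab$asv_id == "c"]), "intermediate")

  tb2 <- rbind(s1 = c(a = 5, b = 5), s2 = c(a = 7, b = 7))
  expect_equal(as.character(classify_taxa(tb2)$class), c("abundant", "abundant"))
})

test_that("class counts partition the ASVs and shares sum to one", {
  tb <- random_table(8, 40, seed = 2, depth = 5000)
  lab <- classify_taxa(tb, abundant_thresh = 0.05, rare_thresh = 0.01)
  expect_equal(sum(table(lab$class)), ncol(tb))
  shares <- tapply(lab$mean_relabund, lab$class, sum)
  expect_equal(sum(shares, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("occupancy equals the column-wise presence fraction", {
  tb <- tiny_table()
  occ <- occupancy(tb)
  manual <- apply(tb > 0, 2, sum) / nrow(tb)
  expect_equal(occ, manual[names(occ)])
  tb2 <- cbind(tb, ghost = 0)
  expect_warning(occ2 <- occupancy(tb2), "absent")
  expect_false("ghost" %in% names(occ2))
})

test_that("temporal responses recover forced and hand-computed correlations", {
  dur <- c(0, 1, 3, 4, 5, 6, 11, 20, 23, 26, 53)
  n <- length(dur)
  # constant sample totals, so relative abundances are counts / 1e4:
  # asv1 proportional to duration, asv2 constant, asv3 arbitrary
  tb <- cbind(asv1 = 10 * (1 + dur), asv2 = 500,
              asv3 = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5) * 10)
  tb <- cbind(tb, asv4 = 10000 - rowSums(tb))
  dimnames(tb) <- list(paste0("s", 1:n), paste0("asv", 1:4))
  meta <- data.frame(sample_id = rownames(tb), duration = dur,
                     stage = paste0("T", dur), replicate = 1,
                     row.names = rownames(tb))
  tr <- temporal_response(tb, meta)
  expect_equal(as.character(tr$response[1]), "positive")
  expect_gt(tr$r[1], 0.99)
  expect_equal(as.character(tr$response[2]), "stable")
  # hand-computed r via the covariance formula on the realized proportions
  p3 <- tb[, 3] / rowSums(tb)
  r_hand <- sum((p3 - mean(p3)) * (dur - mean(dur))) /
    sqrt(sum((p3 - mean(p3))^2) * sum((dur - mean(dur))^2))
  expect_equal(tr$r[3], r_hand, tolerance = 1e-12)
})

test_that("truncation profile is exact at degenerate cutoffs", {
  tb <- random_table(5, 10, seed = 4, depth = 300)
  # cutoff below the smallest ASV's share removes nothing
  smallest <- min(colSums(tb)) / sum(tb)
  pr <- suppressWarnings(multicola_profile(tb, cutoffs = smallest / 2, seed = 1))
  expect_equal(pr$n_removed, 0)
  expect_equal(pr$rho_abundant, 1)
  expect_equal(pr$procrustes_abundant, 1, tolerance = 1e-6)
  expect_true(pr$flag_rare)

  # ASVs absent everywhere leave the distances untouched
  tb2 <- cbind(`asv00` = 0L, tb)   # sorts first lexicographically, count 0
  pr2 <- multicola_profile(tb2, cutoffs = 1e-9, seed = 1, nmds = FALSE)
  expect_equal(pr2$rho_abundant, 1)
})

test_that("truncation-profile rho matches a brute-force pairwise computation", {
  tb <- random_table(4, 6, seed = 7, depth = 200)
  pr <- multicola_profile(tb, cutoffs = 0.5, seed = 1, nmds = FALSE)
  # independent path: rank ASVs ascending, drop until half the reads are gone
  tot <- colSums(tb)
  ord <- order(tot, colnames(tb))
  nrm <- sum(cumsum(tot[ord]) / sum(tot) <= 0.5)
  kept <- tb[, setdiff(seq_len(ncol(tb)), ord[seq_len(nrm)]), drop = FALSE]
  d_full <- d_kept <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    d_full[i, j] <- bc_pair(tb[i, ], tb[j, ])
    d_kept[i, j] <- bc_pair(kept[i, ], kept[j, ])
  }
  rho_brute <- cor(d_full[upper.tri(d_full)], d_kept[upper.tri(d_kept)],
                   method = "spearman")
  expect_equal(pr$rho_abundant, rho_brute, tolerance = 1e-12)
})

test_that("profile degrades from small to large cutoffs on skewed data", {
  sim <- generate_chronosequence(
    chronosequence_config(S = 200, depth = 2000, replicates = 2,
                          durations = c(0, 3, 11, 26, 53), seed = 3))
  pr <- multicola_profile(sim$table, cutoffs = c(0.02, 0.9), seed = 1,
                          nmds = FALSE)
  expect_gte(pr$rho_abundant[1], pr$rho_abundant[2])
})

test_that("Procrustes correlation is 1 for a transformed copy of itself", {
  set.seed(5)
  a <- matrix(rnorm(20), 10, 2)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  b <- sweep(a %*% rot * 2.5, 2, c(3, -1), "+")
  expect_equal(chronosere:::procrustes_cor(a, b), 1, tolerance = 1e-9)
})
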