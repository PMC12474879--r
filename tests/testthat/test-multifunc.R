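test_that("EMF z-scores are standardized and match hand arithmetic", {
  fn <- random_functions(paste0("s", 1:5), seed = 40)
  emf <- compute_emf(fn)
  expect_true(all(abs(colMeans(emf$z)) < 1e-9))
  expect_true(all(abs(apply(emf$z, 2, sd) - 1) < 1e-9))
  expect_lt(abs(mean(emf$index$EMF)), 1e-9)

  # hand z-scores for one function
  z_hand <- (log10(fn[, "SOC"]) - mean(log10(fn[, "SOC"]))) / sd(log10(fn[, "SOC"]))
  expect_equal(unname(emf$z[, "SOC"]), unname(z_hand), tolerance = 1e-12)
  # EMF is the mean across all 17 function z-scores
  expect_equal(emf$index$EMF, unname(rowMeans(emf$z)), tolerance = 1e-12)
  # subset indices average the right columns
  expect_equal(emf$index$PPI,
               unname(rowMeans(emf$z[, c("AGB", "PC", "PN", "PP")])),
               tolerance = 1e-12)

  # two samples force EMF_1 = -EMF_2
  emf2 <- compute_emf(fn[1:2, ])
  expect_equal(emf2$index$EMF[1], -emf2$index$EMF[2], tolerance = 1e-9)
})

test_that("EMF is invariant to rescaling a raw function column and offsets zeros", {
  fn <- random_functions(paste0("s", 1:6), seed = 41)
  e1 <- compute_emf(fn)
  fn2 <- fn; fn2[, "Cat"] <- fn2[, "Cat"] * 1000
  e2 <- compute_emf(fn2)
  expect_equal(e1$index$EMF, e2$index$EMF, tolerance = 1e-9)

  fn3 <- fn; fn3[1, "NH4"] <- 0
  expect_message(e3 <- compute_emf(fn3), "NH4")
  expect_equal(e3$z[1, "NH4"], min(e3$z[, "NH4"]))
  fn4 <- fn; fn4[1, "NH4"] <- -1
  expect_error(compute_emf(fn4), "negative")
})

test_that("richness-EMF regressions recover exact and shuffled relationships", {
  rich <- data.frame(abundant = c(5, 8, 11, 14, 17, 20, 23))
  emf <- 2 * rich$abundant
  rr <- richness_emf_regression(rich, emf)
  expect_equal(rr$r, 1, tolerance = 1e-12)
  expect_equal(rr$slope, 2, tolerance = 1e-12)
  expect_equal(sign(rr$slope), sign(cov(rich$abundant, emf)))

  # shuffled response: p roughly uniform -> significant in ~5% of reps
  set.seed(42)
  ps <- replicate(200, {
    richness_emf_regression(rich, sample(emf))$p
  })
  expect_gt(mean(ps > 0.05), 0.85)
  rr0 <- richness_emf_regression(data.frame(flat = rep(3, 7)), emf)
  expect_true(is.na(rr0$slope))
})

test_that("ASV-function associations count significant functions correctly", {
  set.seed(43)
  fn <- random_functions(paste0("s", 1:12), seed = 43)
  tb <- random_table(12, 6, seed = 44, depth = 2000)
  # constant sample totals so relative abundance is proportional to counts,
  # with asv1 tracking AGB exactly
  tb[, 1] <- round(1000 * fn[, "AGB"] / max(fn[, "AGB"]))
  tb[, 6] <- 5000 - rowSums(tb[, 1:5])
  stopifnot(all(tb[, 6] > 0))
  emf <- compute_emf(fn)
  prof <- asv_function_associations(tb, fn, emf$index$EMF)
  # asv1 vs AGB: |r| near 1 (rounding breaks exactness slightly)
  expect_gt(abs(prof$r["asv1", "AGB"]), 0.97)
  expect_gte(prof$k[["asv1"]], 1)
  # constant ASV -> k = 0, correlations NA
  tb2 <- cbind(tb, flat = 500L)
  prof2 <- asv_function_associations(tb2, fn, emf$index$EMF)
  expect_equal(prof2$k[["flat"]], 0)

  # counting identity: per-class proportions over k sum to the share of
  # that class's ASVs with at least one association
  lab <- classify_taxa(tb, abundant_thresh = 0.1, rare_thresh = 0.02)
  pk <- proportion_vs_k(prof, lab)
  for (cl in unique(pk$proportions$class)) {
    ids <- lab$asv_id[lab$class == cl]
    expect_equal(sum(pk$proportions$proportion[pk$proportions$class == cl]),
                 mean(prof$k[ids] >= 1), tolerance = 1e-12)
  }
})

test_that("degree versus |r(EMF)| regressions behave on exact inputs", {
  topo <- data.frame(asv_id = paste0("a", 1:8), degree = c(1:4, 1:4),
                     class = rep(c("abundant", "rare"), each = 4),
                     stringsAsFactors = FALSE)
  prof <- list(r_emf = setNames(c(0.1 * 1:4, rep(0.5, 4)), paste0("a", 1:8)))
  dr <- suppressWarnings(degree_vs_emf(topo, prof))  # flat |r| has zero sd
  ab <- dr[dr$class == "abundant", ]
  rr <- dr[dr$class == "rare", ]
  expect_equal(ab$slope, 0.1, tolerance = 1e-12)
  expect_equal(ab$r, 1, tolerance = 1e-12)
  expect_equal(rr$slope, 0, tolerance = 1e-12)
})

test_that("functions coupled to abundant richness yield the expected regression ordering", {
  sim <- generate_chronosequence(chronosequence_config(
    S = 400, depth = 4000, seed = 5))
  lab <- classify_taxa(sim$table)
  emf <- compute_emf(sim$functions)
  rich <- sapply(levels(lab$class), function(cl) {
    rowSums(sim$table[, lab$asv_id[lab$class == cl], drop = FALSE] > 0)
  })
  rr <- richness_emf_regression(rich, emf$index$EMF)
  ab <- rr[rr$class == "abundant", ]
  ra <- rr[rr$class == "rare", ]
  expect_gt(ab$slope, 0)
  expect_true(ab$significant)
  expect_gt(ab$r, ra$r)
})
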