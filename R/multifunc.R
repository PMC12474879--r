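#' Ecosystem multifunctionality indices
#'
#' Each function is log10-transformed and z-scored across samples; EMF is the
#' mean of the 17 z-scores per sample, and PPI, DRI and SNPI are the means
#' over the plant-productivity, decomposition-rate and soil-nutrient-pool
#' subsets. Zeros are offset by half the smallest positive value of that
#' function before the log when `offset_zeros = TRUE` (a message names the
#' columns); otherwise non-positive values are an error.
#'
#' @param functions samples x functions matrix containing at least the 17
#'   standard names.
#' @param groups named list of function subsets (default
#'   [emf_function_groups()]).
#' @param offset_zeros apply the half-minimum offset to zero values.
#' @return list with `index` (data.frame: sample_id, EMF, PPI, DRI, SNPI)
#'   and `z` (samples x functions z-score matrix, each column mean 0, sd 1).
#' @export
compute_emf <- function(functions, groups = emf_function_groups(),
                        offset_zeros = TRUE) {
  fl <- unlist(groups, use.names = FALSE)
  miss <- setdiff(fl, colnames(functions))
  if (length(miss)) stop("function table lacks: ", paste(miss, collapse = ", "))
  f <- functions[, fl, drop = FALSE]
  if (any(f < 0)) {
    bad <- colnames(f)[apply(f < 0, 2, any)]
    stop("negative function value(s) in: ", paste(bad, collapse = ", "))
  }
  haszero <- apply(f == 0, 2, any)
  if (any(haszero)) {
    if (!offset_zeros)
      stop("zero function value(s) in: ",
           paste(colnames(f)[haszero], collapse = ", "))
    for (j in which(haszero)) {
      pos <- f[, j][f[, j] > 0]
      if (!length(pos)) stop("function ", colnames(f)[j], " is all zero")
      f[, j][f[, j] == 0] <- min(pos) / 2
    }
    message("zero values offset by half the minimum positive value in: ",
            paste(colnames(f)[haszero], collapse = ", "))
  }
  z <- scale(log10(f))
  idx <- data.frame(sample_id = rownames(functions),
                    EMF = rowMeans(z), stringsAsFactors = FALSE)
  for (gn in names(groups))
    idx[[gn]] <- rowMeans(z[, groups[[gn]], drop = FALSE])
  rownames(idx) <- idx$sample_id
  list(index = idx, z = z)
}

#' Regression of multifunctionality on subcommunity richness
#'
#' Ordinary least squares of an EMF index on per-sample richness, reported
#' per rarity class with the solid/dashed significance convention at
#' p <= 0.05.
#'
#' @param richness data.frame or matrix of per-sample richness, one column
#'   per class, samples as rows (aligned with `emf`).
#' @param emf numeric EMF vector.
#' @return data.frame: class, slope, intercept, r, p, significant.
#' @export
richness_emf_regression <- function(richness, emf) {
  richness <- as.data.frame(richness)
  stopifnot(nrow(richness) == length(emf))
  if (nrow(richness) < 5) stop("need >=5 samples")
  res <- lapply(colnames(richness), function(cl) {
    x <- richness[[cl]]
    if (stats::sd(x) == 0)
      return(data.frame(class = cl, slope = NA_real_, intercept = NA_real_,
                        r = NA_real_, p = NA_real_, significant = NA,
                        stringsAsFactors = FALSE))
    fit <- stats::lm(emf ~ x)
    ct <- stats::cor.test(x, emf)
    data.frame(class = cl, slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r = unname(ct$estimate), p = ct$p.value,
               significant = ct$p.value <= 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-ASV associations with individual functions and multifunctionality
#'
#' Pearson correlation of every ASV's relative abundance with every function
#' and with EMF. The significant-function count k is the number of functions
#' with p < `alpha` (no multiple-testing correction, matching raw-alpha
#' usage; apply [stats::p.adjust()] to `p` for an FDR variant). Constant
#' ASVs get all-NA correlations and k = 0.
#'
#' @param table ASV table (relative abundances are taken internally).
#' @param functions samples x functions matrix.
#' @param emf numeric EMF vector aligned with samples.
#' @param alpha per-test significance level.
#' @return list: `r` and `p` (ASV x function matrices), `k` (named vector of
#'   significant-function counts), `r_emf` (named vector of |r| with EMF),
#'   `p_emf`.
#' @export
asv_function_associations <- function(table, functions, emf, alpha = 0.05) {
  al <- align_inputs(table, functions = functions)
  rel <- relative_abundance(al$table)
  fn <- al$functions
  cors <- function(yv) {
    apply(rel, 2, function(a) {
      if (stats::sd(a) == 0 || stats::sd(yv) == 0) return(c(NA_real_, NA_real_))
      ct <- stats::cor.test(a, yv)
      c(ct$estimate, ct$p.value)
    })
  }
  rmat <- matrix(NA_real_, ncol(rel), ncol(fn),
                 dimnames = list(colnames(rel), colnames(fn)))
  pmat <- rmat
  for (j in seq_len(ncol(fn))) {
    cc <- cors(fn[, j])
    rmat[, j] <- cc[1L, ]
    pmat[, j] <- cc[2L, ]
  }
  ce <- cors(emf)
  k <- rowSums(pmat < alpha, na.rm = TRUE)
  list(r = rmat, p = pmat, k = k,
       r_emf = abs(ce[1L, ]), p_emf = ce[2L, ])
}

#' Proportion of ASVs associated with k functions, per rarity class
#'
#' For each class and each k = 1..K, the proportion of the class's ASVs
#' significantly associated with exactly k functions, plus the least-squares
#' slope of proportion against k.
#'
#' @param profile result of [asv_function_associations()].
#' @param labels rarity classification ([classify_taxa()] output).
#' @return list(proportions = data.frame(class, k, proportion),
#'   slopes = data.frame(class, slope, r, p)).
#' @export
proportion_vs_k <- function(profile, labels) {
  K <- ncol(profile$r)
  cls <- labels$class[match(names(profile$k), labels$asv_id)]
  rows <- list(); slopes <- list()
  for (cl in levels(cls)) {
    kk <- profile$k[cls == cl & !is.na(cls)]
    if (!length(kk)) next
    prop <- vapply(seq_len(K), function(k) mean(kk == k), numeric(1))
    rows[[cl]] <- data.frame(class = cl, k = seq_len(K), proportion = prop,
                             stringsAsFactors = FALSE)
    fit <- stats::lm(prop ~ seq_len(K))
    ct <- stats::cor.test(seq_len(K), prop)
    slopes[[cl]] <- data.frame(class = cl,
                               slope = unname(stats::coef(fit)[2L]),
                               r = unname(ct$estimate), p = ct$p.value,
                               stringsAsFactors = FALSE)
  }
  list(proportions = do.call(rbind, unname(rows)),
       slopes = do.call(rbind, unname(slopes)))
}

#' Regression of |r(EMF)| on network degree, per rarity class
#'
#' @param topology [node_topology()] output (needs asv_id, degree, class).
#' @param profile [asv_function_associations()] output (supplies r_emf).
#' @param min_n classes with fewer nodes are skipped.
#' @return data.frame: class, n, slope, r, p.
#' @export
degree_vs_emf <- function(topology, profile, min_n = 3) {
  stopifnot(!is.null(topology$class))
  shared <- intersect(topology$asv_id, names(profile$r_emf))
  top <- topology[match(shared, topology$asv_id), ]
  remf <- profile$r_emf[shared]
  res <- list()
  for (cl in unique(top$class)) {
    ix <- which(top$class == cl & is.finite(remf))
    if (length(ix) < min_n) next
    x <- top$degree[ix]; y <- remf[ix]
    if (stats::sd(x) == 0) next
    fit <- stats::lm(y ~ x)
    ct <- stats::cor.test(x, y)
    res[[cl]] <- data.frame(class = cl, n = length(ix),
                            slope = unname(stats::coef(fit)[2L]),
                            r = unname(ct$estimate), p = ct$p.value,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, unname(res))
}

#' Mantel test of subcommunity composition against multifunctionality
#'
#' Bray–Curtis distances of a (sub)community against Euclidean distances of
#' the EMF index, via [mantel_test()].
#'
#' @param table ASV table restricted to the subcommunity of interest.
#' @param emf numeric EMF vector aligned with samples.
#' @param ... passed to [mantel_test()].
#' @return list(r, p, nperm).
#' @export
emf_composition_mantel <- function(table, emf, ...) {
  d1 <- bray_curtis(table)
  d2 <- as.matrix(stats::dist(emf))
  mantel_test(d1, d2, ...)
}
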