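#' Classify ASVs as abundant, intermediate or rare
#'
#' Classes are decided solely by each ASV's average relative abundance across
#' all samples: strictly above `abundant_thresh` is abundant, strictly below
#' `rare_thresh` is rare, everything else (boundaries included) is
#' intermediate. Defaults are the thresholds located by the truncation
#' profile on the study data: 0.028% and 0.002%.
#'
#' @param table ASV table.
#' @param abundant_thresh proportion above which a taxon is abundant.
#' @param rare_thresh proportion below which a taxon is rare.
#' @param mode "mean_proportion" (mean of per-sample proportions, default) or
#'   "pooled" (total count over total sequences); identical after rarefaction
#'   to even depth.
#' @return data.frame: asv_id, mean_relabund, occupancy, class (factor with
#'   levels abundant, intermediate, rare).
#' @export
classify_taxa <- function(table, abundant_thresh = 2.8e-4, rare_thresh = 2e-5,
                          mode = c("mean_proportion", "pooled")) {
  mode <- match.arg(mode)
  validate_asv_table(table)
  stopifnot(rare_thresh > 0, rare_thresh < abundant_thresh)
  mra <- switch(mode,
    mean_proportion = colMeans(relative_abundance(table)),
    pooled          = colSums(table) / sum(table))
  cls <- ifelse(mra > abundant_thresh, "abundant",
                ifelse(mra < rare_thresh, "rare", "intermediate"))
  data.frame(asv_id = colnames(table),
             mean_relabund = unname(mra),
             occupancy = unname(colMeans(table > 0)),
             class = factor(cls, levels = c("abundant", "intermediate", "rare")),
             stringsAsFactors = FALSE)
}

#' Per-ASV occupancy (fraction of samples occupied)
#'
#' @param table ASV table.
#' @param drop_absent drop ASVs with zero total count (with a warning).
#' @return named numeric vector of occupancies in (0, 1].
#' @export
occupancy <- function(table, drop_absent = TRUE) {
  occ <- colMeans(table > 0)
  absent <- colSums(table) == 0
  if (any(absent) && drop_absent) {
    warning(sum(absent), " ASV(s) absent from every sample dropped")
    occ <- occ[!absent]
  }
  occ
}

#' Per-ASV temporal response of relative abundance to restoration duration
#'
#' Pearson correlation of each ASV's relative abundance against duration;
#' positive/negative when significant at `alpha`, stable otherwise.
#' Zero-variance ASVs are reported stable with r = 0.
#'
#' @param table ASV table.
#' @param meta chronosequence metadata with durations for every sample.
#' @param alpha significance level.
#' @return data.frame: asv_id, r, p, response in \{positive, negative, stable\}.
#' @export
temporal_response <- function(table, meta, alpha = 0.05) {
  al <- align_inputs(table, meta)
  rel <- relative_abundance(al$table)
  t_ <- al$meta$duration
  if (length(unique(t_)) < 3)
    stop("need >=3 distinct durations for a temporal response")
  n <- length(t_)
  tz <- t_ - mean(t_)
  ss_t <- sum(tz^2)
  r <- as.numeric(crossprod(rel - rep(colMeans(rel), each = n), tz)) /
    sqrt(pmax(colSums((rel - rep(colMeans(rel), each = n))^2), 0) * ss_t)
  r[!is.finite(r)] <- 0
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  resp <- ifelse(p < alpha & r > 0, "positive",
                 ifelse(p < alpha & r < 0, "negative", "stable"))
  data.frame(asv_id = colnames(rel), r = r, p = p,
             response = factor(resp, levels = c("positive", "negative", "stable")),
             stringsAsFactors = FALSE)
}

# Symmetric Procrustes correlation between two configurations,
# sqrt(1 - m2) with m2 the symmetric Procrustes sum of squares.
procrustes_cor <- function(a, b) {
  pr <- vegan::procrustes(a, b, symmetric = TRUE)
  sqrt(max(0, 1 - pr$ss))
}

#' Multivariate cutoff level analysis (truncation profile)
#'
#' ASVs are ranked ascending by total count and removed, in rank order, until
#' each cutoff fraction of total sequences has been discarded (ties broken by
#' ASV id). For every cutoff two truncated datasets are formed — "abundant"
#' (rare ASVs removed) and "rare" (only the removed ASVs retained) — and each
#' is compared with the original by (i) Spearman rho between the
#' lower-triangle Bray–Curtis distances, and (ii) the symmetric Procrustes
#' correlation between 2-d NMDS configurations.
#'
#' @param table ASV table (>=3 samples).
#' @param cutoffs fractions of total sequences to remove (default 1–95% in 1%
#'   steps).
#' @param seed seed for the NMDS restarts.
#' @param nmds compute the Procrustes column (slower); when FALSE the
#'   procrustes columns are NA.
#' @return data.frame: cutoff, n_removed, rho_abundant, procrustes_abundant,
#'   rho_rare, procrustes_rare, flag_abundant, flag_rare (TRUE when the
#'   truncated dataset contains an all-zero sample, in which case those
#'   samples are excluded from the comparison rather than dropped silently).
#' @export
multicola_profile <- function(table, cutoffs = seq(0.01, 0.95, by = 0.01),
                              seed = 1L, nmds = TRUE) {
  validate_asv_table(table)
  if (nrow(table) < 3) stop("need >=3 samples")
  stopifnot(all(cutoffs > 0), all(cutoffs < 1))
  totals <- colSums(table)
  ord <- order(totals, colnames(table))   # ascending count, ties by id
  cum <- cumsum(totals[ord]) / sum(totals)
  d0 <- bray_curtis(table)
  nm0 <- if (nmds) nmds_config(d0, seed = seed) else NULL

  one <- function(keep) {
    sub <- table[, keep, drop = FALSE]
    ok <- rowSums(sub) > 0
    flag <- !all(ok)
    if (sum(ok) < 3 || ncol(sub) < 1)
      return(list(rho = NA_real_, pro = NA_real_, flag = TRUE))
    dsub <- bray_curtis(sub[ok, , drop = FALSE])
    dref <- d0[ok, ok]
    rho <- stats::cor(dref[lower.tri(dref)], dsub[lower.tri(dsub)],
                      method = "spearman")
    pro <- NA_real_
    if (nmds) {
      ref_pts <- if (all(ok)) nm0$points else nmds_config(as.dist(dref), seed = seed)$points
      pro <- procrustes_cor(ref_pts, nmds_config(dsub, seed = seed)$points)
    }
    list(rho = rho, pro = pro, flag = flag)
  }

  res <- lapply(cutoffs, function(cf) {
    n_rm <- sum(cum <= cf)
    removed <- ord[seq_len(n_rm)]
    kept <- if (n_rm) setdiff(seq_along(totals), removed) else seq_along(totals)
    ab <- one(kept)
    # with nothing removed the rare dataset is empty; it is flagged, not dropped
    rr <- if (n_rm) one(removed) else list(rho = NA_real_, pro = NA_real_, flag = TRUE)
    data.frame(cutoff = cf, n_removed = n_rm,
               rho_abundant = ab$rho, procrustes_abundant = ab$pro,
               rho_rare = rr$rho, procrustes_rare = rr$pro,
               flag_abundant = ab$flag, flag_rare = rr$flag)
  })
  do.call(rbind, res)
}
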