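#' Levins' niche breadth
#'
#' With p_i the fraction of an ASV's use of resource state i (sum 1),
#' B = 1 / sum p_i^2 and the normalized B_N = (B - 1) / (N - 1). B spans
#' 1 (single-state specialist) to N (perfectly even use of N states).
#' Resource states default to sample groups (e.g. the 11 stage means, which
#' damps replicate noise); pass `states = NULL` to treat every sample as its
#' own state.
#'
#' @param table ASV table.
#' @param states factor of length nrow(table) grouping samples into resource
#'   states, or NULL for per-sample states.
#' @return data.frame: asv_id, B, B_N. ASVs with zero total are dropped.
#' @export
levins_breadth <- function(table, states = NULL) {
  validate_asv_table(table)
  rel <- relative_abundance(table)
  if (!is.null(states)) {
    states <- as.factor(states)
    stopifnot(length(states) == nrow(table))
    rel <- apply(rel, 2, function(v) tapply(v, states, mean))
    if (is.null(dim(rel))) rel <- matrix(rel, nrow = 1)
  }
  N <- nrow(rel)
  if (N < 2) stop("niche breadth undefined with a single resource state")
  tot <- colSums(rel)
  keep <- tot > 0
  if (!all(keep)) warning(sum(!keep), " absent ASV(s) dropped")
  p <- sweep(rel[, keep, drop = FALSE], 2, tot[keep], "/")
  B <- 1 / colSums(p^2)
  data.frame(asv_id = colnames(table)[keep], B = unname(B),
             B_N = unname((B - 1) / (N - 1)), stringsAsFactors = FALSE)
}

#' Levins' breadth over binned environmental variables
#'
#' Treats each measured function as an environmental gradient: samples are
#' cut into `bins` equal-frequency bins per function, an ASV's use of each
#' bin is its mean relative abundance there, and Levins' B is computed per
#' function then averaged across functions.
#'
#' @param table ASV table.
#' @param functions samples x functions matrix.
#' @param bins equal-frequency bins per function.
#' @return data.frame: asv_id, B (mean across functions), B_N.
#' @export
levins_breadth_binned <- function(table, functions, bins = 5) {
  al <- align_inputs(table, functions = functions)
  table <- al$table; functions <- al$functions
  per_fun <- vapply(seq_len(ncol(functions)), function(j) {
    qs <- unique(stats::quantile(functions[, j], probs = seq(0, 1, length.out = bins + 1)))
    st <- cut(functions[, j], breaks = qs, include.lowest = TRUE)
    b <- levins_breadth(table, states = st)
    stats::setNames(b$B_N, b$asv_id)[colnames(table)]
  }, numeric(ncol(table)))
  bn <- rowMeans(per_fun, na.rm = TRUE)
  keep <- !is.na(bn)
  data.frame(asv_id = colnames(table)[keep], B_N = unname(bn[keep]),
             stringsAsFactors = FALSE)
}

#' Environmental tolerance index (OMI-style Tol)
#'
#' Samples are placed in the principal-component space of the z-scored
#' function matrix (axes with positive eigenvalue retained). Each ASV's
#' position is the abundance-weighted mean of its occupied sample scores and
#' its tolerance is the abundance-weighted mean squared Euclidean distance of
#' those scores from the position. Tolerance is 0 for an ASV present in a
#' single sample and invariant to uniform scaling of the ASV's abundances.
#'
#' @param table ASV table.
#' @param functions samples x functions matrix; constant columns are dropped
#'   with a warning.
#' @return data.frame: asv_id, tolerance. Absent ASVs are dropped.
#' @export
tolerance_index <- function(table, functions) {
  al <- align_inputs(table, functions = functions)
  table <- al$table; functions <- al$functions
  sds <- apply(functions, 2, stats::sd)
  if (any(sds == 0)) {
    warning("constant function column(s) dropped: ",
            paste(colnames(functions)[sds == 0], collapse = ", "))
    functions <- functions[, sds > 0, drop = FALSE]
  }
  z <- scale(functions)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  keep_ax <- pc$sdev^2 > 1e-12
  S <- pc$x[, keep_ax, drop = FALSE]
  # weights from the ASV's own abundance vector, so uniformly scaling an
  # ASV's counts leaves its tolerance unchanged
  tot <- colSums(table)
  present <- tot > 0
  tol <- vapply(which(present), function(j) {
    w <- table[, j] / tot[j]
    m <- colSums(S * w)
    sum(w * rowSums((S - rep(m, each = nrow(S)))^2))
  }, numeric(1))
  data.frame(asv_id = colnames(table)[present], tolerance = unname(tol),
             stringsAsFactors = FALSE)
}

# Dunn's post-hoc z statistics on ranked data with tie correction
.dunn_pairs <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  N <- length(values)
  rk <- rank(values)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(rk, groups, mean)
  ns <- table(groups)
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  z <- apply(pairs, 2, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
               (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
    (mr[[pr[1L]]] - mr[[pr[2L]]]) / se
  })
  data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ], z = z,
             p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# compact letter display from a logical "significantly different" matrix
.letter_display <- function(diff_mat, ordering) {
  g <- rownames(diff_mat)
  letters_out <- stats::setNames(rep("", length(g)), g)
  groupsets <- list()
  for (gi in ordering) {
    placed <- FALSE
    for (k in seq_along(groupsets)) {
      if (!any(diff_mat[gi, groupsets[[k]]])) {
        groupsets[[k]] <- c(groupsets[[k]], gi)
        placed <- TRUE
      }
    }
    if (!placed) groupsets[[length(groupsets) + 1L]] <- gi
  }
  for (k in seq_along(groupsets))
    for (gi in groupsets[[k]])
      letters_out[gi] <- paste0(letters_out[gi], letters[k])
  letters_out
}

#' Kruskal–Wallis test with Dunn post-hoc comparisons
#'
#' Kruskal–Wallis H (tie-corrected, via [stats::kruskal.test()]) followed by
#' Dunn's z tests for all group pairs with Bonferroni correction (p
#' multiplied by the number of pairs, capped at 1) and a compact letter
#' display (groups sharing a letter are not significantly different).
#'
#' @param values numeric vector.
#' @param groups group labels (>=2 nonempty groups).
#' @param alpha significance level for the letter display.
#' @param correction only "bonferroni" is implemented.
#' @return list(H, df, p, pairs, letters).
#' @export
kruskal_dunn <- function(values, groups, alpha = 0.05,
                         correction = "bonferroni") {
  stopifnot(correction == "bonferroni")
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need >=2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  kw <- stats::kruskal.test(values, groups)
  dn <- .dunn_pairs(values, groups)
  dn$p_adj <- pmin(1, dn$p * nrow(dn))
  lev <- levels(groups)
  diff_mat <- matrix(FALSE, nlevels(groups), nlevels(groups),
                     dimnames = list(lev, lev))
  for (k in seq_len(nrow(dn))) {
    sig <- dn$p_adj[k] < alpha
    diff_mat[dn$group_i[k], dn$group_j[k]] <- sig
    diff_mat[dn$group_j[k], dn$group_i[k]] <- sig
  }
  ordering <- names(sort(tapply(rank(values), groups, mean), decreasing = TRUE))
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, pairs = dn,
       letters = .letter_display(diff_mat, ordering))
}
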