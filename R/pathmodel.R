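#' Construct a path model specification
#'
#' A directed acyclic edge list over named variables, optionally with
#' composite-variable definitions (each composite is built from several
#' observed predictors via [make_composite()] before fitting).
#'
#' @param edges data.frame with columns `from`, `to`.
#' @param composites optional named list; each element is
#'   list(predictors = character(), response = character()).
#' @return object of class "path_spec".
#' @export
path_spec <- function(edges, composites = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% colnames(edges)))
  vars <- unique(c(edges$from, edges$to))
  ord <- topo_sort_dag(edges, vars)   # errors on cycles
  structure(list(edges = edges, vars = vars, order = ord,
                 composites = composites), class = "path_spec")
}

# Kahn topological sort; error when the edge list has a cycle.
topo_sort_dag <- function(edges, vars) {
  indeg <- stats::setNames(rep(0L, length(vars)), vars)
  for (v in edges$to) indeg[v] <- indeg[v] + 1L
  out <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  edges_left <- edges
  while (length(avail)) {
    v <- avail[1L]; avail <- avail[-1L]
    out <- c(out, v)
    ch <- edges_left$to[edges_left$from == v]
    edges_left <- edges_left[edges_left$from != v, , drop = FALSE]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(out) != length(vars)) stop("path model specification is cyclic")
  out
}

#' The default chronosequence path model
#'
#' duration -> cover, pH, EMF; cover, pH -> richness; cover, pH, richness ->
#' EMF; richness -> degree; degree -> EMF. "richness" and "degree" are
#' composites of the per-class values when fitted through
#' [run_chronosequence()].
#'
#' @return a "path_spec".
#' @export
default_path_spec <- function() {
  path_spec(data.frame(
    from = c("duration", "duration", "duration", "cover", "pH",
             "cover", "pH", "richness", "richness", "degree"),
    to   = c("cover", "pH", "EMF", "richness", "richness",
             "EMF", "EMF", "EMF", "degree", "EMF"),
    stringsAsFactors = FALSE))
}

#' Build a composite variable from several predictors
#'
#' Predictors and response are z-scored; the composite is the weighted sum
#' of the predictors using their standardized OLS coefficients on the
#' response as weights, re-standardized to unit variance.
#'
#' @param data data.frame holding the variables.
#' @param predictors character vector of predictor names.
#' @param response single response name.
#' @return list(weights, scores).
#' @export
make_composite <- function(data, predictors, response) {
  X <- scale(as.matrix(data[, predictors, drop = FALSE]))
  y <- as.numeric(scale(data[[response]]))
  if (length(predictors) > 1) {
    sv <- svd(X)
    if (min(sv$d) <= 0 || max(sv$d) / min(sv$d) > 1e8)
      stop("collinear composite predictors: ",
           paste(predictors, collapse = ", "))
  }
  w <- stats::coef(stats::lm(y ~ X - 1))
  names(w) <- predictors
  sc <- as.numeric(X %*% w)
  list(weights = w, scores = as.numeric(scale(sc)))
}

# Shipley-style independence basis set: unique non-adjacent ordered pairs,
# the topologically later variable regressed on the earlier plus its parents.
basis_set <- function(spec) {
  adj <- paste(spec$edges$from, spec$edges$to)
  adj <- c(adj, paste(spec$edges$to, spec$edges$from))
  ord <- spec$order
  out <- list()
  for (i in seq_along(ord)) for (j in seq_along(ord)) {
    if (j <= i) next
    a <- ord[i]; b <- ord[j]
    if (paste(a, b) %in% adj) next
    parents <- spec$edges$from[spec$edges$to == b]
    out[[length(out) + 1L]] <- list(x = a, y = b,
                                    cond = setdiff(parents, a))
  }
  out
}

#' Fit a piecewise path model
#'
#' One OLS regression per endogenous variable on its declared parents, on
#' z-scored data so coefficients are standardized. Goodness of fit is
#' Shipley's d-separation test: for every independence claim in the basis
#' set the p-value of the omitted predictor is collected and Fisher's
#' C = -2 sum ln p is referred to chi-squared with 2k degrees of freedom.
#'
#' @param spec "path_spec" object.
#' @param data data.frame with complete cases for all spec variables.
#' @return object of class "path_fit": list(coefficients = data.frame(from,
#'   to, estimate, se, p), r_squared, fisher_c = list(C, df, p), basis,
#'   n).
#' @export
fit_path_model <- function(spec, data) {
  stopifnot(inherits(spec, "path_spec"))
  miss <- setdiff(spec$vars, colnames(data))
  if (length(miss)) stop("data lacks variable(s): ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[, spec$vars]), spec$vars, drop = FALSE]
  dz <- as.data.frame(scale(d))
  endo <- unique(spec$edges$to)
  coefs <- list(); r2 <- stats::setNames(numeric(0), character(0))
  for (v in endo) {
    parents <- spec$edges$from[spec$edges$to == v]
    fit <- stats::lm(stats::reformulate(parents, response = v), data = dz)
    sm <- summary(fit)
    ct <- sm$coefficients
    coefs[[v]] <- data.frame(from = parents, to = v,
                             estimate = ct[parents, 1L],
                             se = ct[parents, 2L],
                             p = ct[parents, 4L],
                             row.names = NULL, stringsAsFactors = FALSE)
    r2[v] <- sm$r.squared
  }
  bs <- basis_set(spec)
  pvals <- vapply(bs, function(cl) {
    fit <- stats::lm(stats::reformulate(c(cl$x, cl$cond), response = cl$y),
                     data = dz)
    summary(fit)$coefficients[cl$x, 4L]
  }, numeric(1))
  C <- if (length(pvals)) -2 * sum(log(pmax(pvals, 1e-300))) else 0
  df <- 2L * length(pvals)
  p <- if (df) stats::pchisq(C, df, lower.tail = FALSE) else 1
  structure(list(coefficients = do.call(rbind, unname(coefs)),
                 r_squared = r2,
                 fisher_c = list(C = C, df = df, p = p),
                 basis = bs, n = nrow(dz)),
            class = "path_fit")
}

#' @export
print.path_fit <- function(x, ...) {
  cat("Piecewise path model (n =", x$n, ")\n\nStandardized coefficients:\n")
  print(x$coefficients, digits = 3)
  cat("\nR-squared:\n")
  print(round(x$r_squared, 3))
  cat(sprintf("\nFisher's C = %.3f, df = %d, p = %.3f\n",
              x$fisher_c$C, x$fisher_c$df, x$fisher_c$p))
  invisible(x)
}
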