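#' Configuration for the synthetic chronosequence generator
#'
#' Defaults mirror the study design the analysis targets: 11 restoration
#' stages (0, 1, 3, 4, 5, 6, 11, 20, 23, 26, 53 years) with 5 replicate
#' samples each, a species pool with a strongly skewed lognormal abundance
#' distribution, a birth–death phylogeny carrying a Brownian environmental
#' optimum (so selection regimes are phylogenetically detectable), richness
#' that saturates with duration for the abundant tier and grows linearly for
#' the rare tier, and 17 positive-valued functions driven by duration and
#' abundant-tier richness.
#'
#' @param durations restoration ages in years (strictly increasing).
#' @param replicates samples per stage (>= 2).
#' @param S pool size (>= 50).
#' @param meanlog,sdlog lognormal pool-abundance parameters.
#' @param birth,death birth–death rates of the pool phylogeny.
#' @param regime assembly regime.
#' @param selection_strength Gaussian filter width w in trait-sd units
#'   (smaller = stronger selection).
#' @param env_optimum magnitude of the environmental optimum in trait-sd
#'   units: homogeneous selection filters every sample toward
#'   `+env_optimum`, variable selection moves the optimum from
#'   `-env_optimum` to `+env_optimum` across stages. An extreme optimum
#'   selects a phylogenetically clustered subset (Brownian traits make
#'   extreme values clade-restricted), which is what lets the betaNTI null
#'   detect selection.
#' @param migration per-generation migration rate from the pool under
#'   dispersal limitation.
#' @param drift_generations,drift_ne serial-drift chain length and effective
#'   population size under dispersal limitation.
#' @param depth reads per sample.
#' @param abundant_frac top fraction of pool taxa (by pool abundance)
#'   forming the saturating "abundant" availability tier.
#' @param avail_abundant c(p0, tau): availability p0 + (1-p0)(1-exp(-t/tau)).
#' @param avail_rare c(q0, slope): availability min(q0 + slope t, 0.95).
#' @param fun_duration_effect,fun_richness_effect,fun_noise_sd coefficients
#'   of the log10-scale linear model behind the 17 functions.
#' @param seed master seed; all substreams derive from it.
#' @return list of class "chrono_config".
#' @export
chronosequence_config <- function(durations = c(0, 1, 3, 4, 5, 6, 11, 20, 23, 26, 53),
                                  replicates = 5,
                                  S = 2000,
                                  meanlog = 0, sdlog = 2,
                                  birth = 1, death = 0.4,
                                  regime = c("variable_selection",
                                             "homogeneous_selection",
                                             "dispersal_limitation", "drift"),
                                  selection_strength = 0.8,
                                  env_optimum = 1.5,
                                  migration = 0.02,
                                  drift_generations = 15, drift_ne = 1000,
                                  depth = 10000,
                                  abundant_frac = 0.2,
                                  avail_abundant = c(p0 = 0.7, tau = 5),
                                  avail_rare = c(q0 = 0.08, slope = 0.01),
                                  fun_duration_effect = 0.25,
                                  fun_richness_effect = 0.8,
                                  fun_noise_sd = 0.5,
                                  seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(all(diff(durations) > 0), replicates >= 2, S >= 50,
            depth > 0, abundant_frac > 0, abundant_frac < 1)
  structure(as.list(environment()), class = "chrono_config")
}

#' Named scenario presets for the generator
#'
#' "default" (variable selection at moderate strength), and the four
#' controllable regimes: "homogeneous_selection" (strong selection toward a
#' common optimum), "variable_selection" (strong selection toward
#' stage-specific optima), "dispersal_limitation" (isolated serial drift
#' with weak migration) and "drift" (pure multinomial sampling).
#'
#' @param name preset name.
#' @param ... overrides passed to [chronosequence_config()].
#' @return "chrono_config" object.
#' @export
chronosequence_preset <- function(name = c("default", "homogeneous_selection",
                                           "variable_selection",
                                           "dispersal_limitation", "drift"),
                                  ...) {
  name <- match.arg(name)
  switch(name,
    default = chronosequence_config(...),
    homogeneous_selection = chronosequence_config(
      regime = "homogeneous_selection", selection_strength = 0.25,
      env_optimum = 2, ...),
    variable_selection = chronosequence_config(
      regime = "variable_selection", selection_strength = 0.4, ...),
    dispersal_limitation = chronosequence_config(
      regime = "dispersal_limitation", migration = 0.005,
      drift_generations = 25, drift_ne = 400, ...),
    drift = chronosequence_config(regime = "drift", ...))
}

#' Generate a synthetic restoration chronosequence with ground truth
#'
#' @param config a [chronosequence_config()] (default settings when
#'   omitted).
#' @return list: table (ASV counts), tree (phylo), meta (sample metadata
#'   with duration, stage, replicate, cover, pH), functions (17 per-sample
#'   functions), truth (tier membership, regime, trait values, stage optima,
#'   function effects, config).
#' @export
generate_chronosequence <- function(config = chronosequence_config()) {
  stopifnot(inherits(config, "chrono_config"))
  cg <- config
  S <- cg$S
  n_stage <- length(cg$durations)
  n <- n_stage * cg$replicates
  ids <- paste0("ASV", formatC(seq_len(S), width = 5, flag = "0"))

  set.seed(cg$seed + 1L)                       # tree substream
  tree <- ape::rphylo(S, birth = cg$birth, death = cg$death)
  tree$tip.label <- ids

  set.seed(cg$seed + 2L)                       # trait substream
  trait <- phytools::fastBM(tree, sig2 = 1)
  trait <- (trait - mean(trait)) / stats::sd(trait)

  set.seed(cg$seed + 3L)                       # pool substream
  pool <- stats::rlnorm(S, cg$meanlog, cg$sdlog)
  names(pool) <- ids
  pool_relab <- pool / sum(pool)
  n_ab <- max(4L, round(cg$abundant_frac * S))
  abundant_tier <- ids[order(pool, decreasing = TRUE)[seq_len(n_ab)]]
  is_ab <- ids %in% abundant_tier

  dur <- rep(cg$durations, each = cg$replicates)
  stage <- rep(paste0("T", formatC(cg$durations, width = 2, flag = "0")),
               each = cg$replicates)
  repl <- rep(seq_len(cg$replicates), times = n_stage)
  sample_ids <- paste0(stage, "R", repl)

  # stage environmental optima: constant under homogeneous selection,
  # spanning the trait range under variable selection
  env_stage <- switch(cg$regime,
    homogeneous_selection = rep(cg$env_optimum, n_stage),
    variable_selection = seq(-cg$env_optimum, cg$env_optimum,
                             length.out = n_stage),
    rep(0, n_stage))

  set.seed(cg$seed + 4L)                       # availability substream
  p_ab <- cg$avail_abundant[["p0"]] +
    (1 - cg$avail_abundant[["p0"]]) * (1 - exp(-dur / cg$avail_abundant[["tau"]]))
  p_rr <- pmin(cg$avail_rare[["q0"]] + cg$avail_rare[["slope"]] * dur, 0.95)
  avail <- matrix(0L, n, S, dimnames = list(sample_ids, ids))
  for (i in seq_len(n)) {
    pr <- ifelse(is_ab, p_ab[i], p_rr[i])
    avail[i, ] <- stats::rbinom(S, 1L, pr)
  }

  counts <- matrix(0L, n, S, dimnames = list(sample_ids, ids))
  for (i in seq_len(n)) {
    set.seed(cg$seed + 100L + i)               # per-sample assembly substream
    st <- match(stage[i], unique(stage))
    base <- pool_relab * avail[i, ]
    if (sum(base) == 0) base <- pool_relab     # degenerate mask guard
    base <- base / sum(base)
    pr <- switch(cg$regime,
      homogeneous_selection = ,
      variable_selection = {
        w <- cg$selection_strength
        sel <- exp(-(trait - env_stage[st])^2 / (2 * w^2))
        b <- base * sel
        b / sum(b)
      },
      dispersal_limitation = {
        p <- base
        for (g in seq_len(cg$drift_generations)) {
          drawn <- stats::rmultinom(1, cg$drift_ne, p)[, 1] / cg$drift_ne
          p <- (1 - cg$migration) * drawn + cg$migration * base
        }
        p
      },
      drift = base)
    counts[i, ] <- stats::rmultinom(1, cg$depth, pr)[, 1]
  }

  meta <- data.frame(sample_id = sample_ids, duration = dur, stage = stage,
                     replicate = repl, stringsAsFactors = FALSE)
  set.seed(cg$seed + 5L)                       # covariate substream
  meta$cover <- pmax(0.5, 2 + 43 * (1 - exp(-dur / 8)) + stats::rnorm(n, 0, 3))
  meta$pH <- 8.6 - 0.012 * dur + stats::rnorm(n, 0, 0.08)
  rownames(meta) <- sample_ids

  set.seed(cg$seed + 6L)                       # function substream
  env_sig <- as.numeric(scale(1 - exp(-dur / 10)))
  ab_rich <- as.numeric(scale(rowSums(counts[, abundant_tier, drop = FALSE] > 0)))
  fnames <- emf_function_names()
  base_level <- seq(0.5, 2.5, length.out = length(fnames))
  functions <- sapply(seq_along(fnames), function(k) {
    lf <- base_level[k] + cg$fun_duration_effect * env_sig +
      cg$fun_richness_effect * ab_rich +
      stats::rnorm(n, 0, cg$fun_noise_sd)
    10^lf
  })
  dimnames(functions) <- list(sample_ids, fnames)

  truth <- list(abundant_tier = abundant_tier, regime = cg$regime,
                trait = trait, env_stage = env_stage,
                pool_relab = pool_relab,
                function_effects = c(duration = cg$fun_duration_effect,
                                     richness = cg$fun_richness_effect),
                config = cg)
  list(table = counts, tree = tree, meta = meta, functions = functions,
       truth = truth)
}

#' Default standardized effects for the chronosequence path model
#'
#' @return data.frame: from, to, beta (edges of [default_path_spec()]).
#' @export
default_path_effects <- function() {
  sp <- default_path_spec()
  data.frame(sp$edges,
             beta = c(0.8, -0.6, 0.2, 0.5, -0.3, 0.2, -0.2, 0.4, 0.6, 0.2),
             stringsAsFactors = FALSE)
}

#' Generate linear-Gaussian data from a path model with known
#' standardized effects
#'
#' Variables are generated in topological order; every variable has unit
#' variance, so the generating `beta` values are the standardized path
#' coefficients an OLS fit should recover.
#'
#' @param effects data.frame with columns from, to, beta.
#' @param n sample size.
#' @param seed integer seed.
#' @return data.frame of n rows with one column per variable.
#' @export
generate_pathmodel_data <- function(effects = default_path_effects(),
                                    n = 55, seed = 1L) {
  stopifnot(all(c("from", "to", "beta") %in% colnames(effects)))
  vars <- unique(c(effects$from, effects$to))
  ord <- topo_sort_dag(effects, vars)          # errors on cycles
  set.seed(seed)
  X <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  Sigma <- diag(length(vars)); dimnames(Sigma) <- list(vars, vars)
  for (v in ord) {
    parents <- effects$from[effects$to == v]
    if (!length(parents)) {
      X[, v] <- stats::rnorm(n)
      next
    }
    b <- effects$beta[effects$to == v][match(parents, effects$from[effects$to == v])]
    lin_var <- as.numeric(t(b) %*% Sigma[parents, parents, drop = FALSE] %*% b)
    if (lin_var > 1 + 1e-8)
      stop("standardized effects into '", v, "' imply variance > 1")
    X[, v] <- X[, parents, drop = FALSE] %*% b +
      stats::rnorm(n, 0, sqrt(max(0, 1 - lin_var)))
    done <- ord[seq_len(match(v, ord) - 1L)]
    for (u in done)
      Sigma[u, v] <- Sigma[v, u] <- sum(Sigma[u, parents] * b)
  }
  as.data.frame(X)
}

#' Write a generated chronosequence to the four standard input files
#'
#' @param sim output of [generate_chronosequence()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly. Writes asv_table.tsv, metadata.tsv,
#'   functions.tsv, tree.nwk and ground_truth.json.
#' @export
write_chronosequence <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_asv_table(sim$table, file.path(dir, "asv_table.tsv"))
  write_sample_table(sim$meta[, setdiff(colnames(sim$meta), "sample_id")],
                     file.path(dir, "metadata.tsv"))
  write_sample_table(sim$functions, file.path(dir, "functions.tsv"))
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  truth <- sim$truth
  truth$trait <- NULL; truth$pool_relab <- NULL
  truth$config <- truth$config[!vapply(truth$config, is.function, logical(1))]
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
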