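#' Configuration for a full chronosequence analysis run
#'
#' @param abundant_thresh,rare_thresh rarity thresholds (proportions).
#' @param rho_min,alpha network edge thresholds.
#' @param n_null null randomizations per pair for betaNTI and RC_bray.
#' @param sparcc_resample,sparcc_boot SparCC resampling/bootstrap counts.
#' @param assembly_pairs "within_stage" (default) or "all" sample pairs.
#' @param seed master seed.
#' @param skip character vector of stages to skip, from
#'   \{"niche", "commstats", "assembly", "network", "emf", "pathmodel"\}.
#' @return list of class "run_config".
#' @export
run_config <- function(abundant_thresh = 2.8e-4, rare_thresh = 2e-5,
                       rho_min = 0.3, alpha = 0.05,
                       n_null = 999, sparcc_resample = 100, sparcc_boot = 99,
                       assembly_pairs = c("within_stage", "all"),
                       seed = 1L, skip = character(0)) {
  assembly_pairs <- match.arg(assembly_pairs)
  stopifnot(rare_thresh > 0, rare_thresh < abundant_thresh,
            rho_min >= 0, rho_min <= 1, alpha > 0, alpha <= 1, n_null >= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full subcommunity analysis end-to-end
#'
#' Orchestrates classification, niche breadth, community statistics,
#' assembly-process partitioning, co-occurrence network, multifunctionality
#' and the path model over an aligned set of inputs, optionally writing
#' every stage's tables plus a manifest to `out_dir`.
#'
#' @param table ASV count table.
#' @param meta chronosequence metadata.
#' @param tree rooted phylogeny covering the table's ASVs.
#' @param functions per-sample function matrix.
#' @param config a [run_config()].
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return named list with one element per stage plus `manifest`.
#' @export
run_chronosequence <- function(table, meta, tree, functions,
                               config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  al <- align_inputs(table, meta, functions, tree)
  table <- al$table; meta <- al$meta; functions <- al$functions
  res <- list()

  labels <- classify_taxa(table, config$abundant_thresh, config$rare_thresh)
  res$labels <- labels
  classes <- levels(labels$class)
  sub_tables <- lapply(stats::setNames(classes, classes), function(cl) {
    tb <- table[, labels$asv_id[labels$class == cl], drop = FALSE]
    tb[, colSums(tb) > 0, drop = FALSE]
  })

  emf <- compute_emf(functions)
  res$emf <- emf$index

  if (!"niche" %in% config$skip) {
    lev <- levins_breadth(table, states = meta$stage)
    tol <- tolerance_index(table, functions)
    nb <- merge(lev, tol, by = "asv_id", all = TRUE)
    nb$class <- labels$class[match(nb$asv_id, labels$asv_id)]
    res$niche <- nb
  }

  # samples without reads of a class are excluded from that class's
  # distance-based analyses
  occupied <- function(tb) tb[rowSums(tb) > 0, , drop = FALSE]

  if (!"commstats" %in% config$skip) {
    cs <- lapply(sub_tables, function(tb) {
      rich <- rowSums(tb > 0)
      tb <- occupied(tb)
      mt_ <- meta[rownames(tb), ]
      part <- partition_beta(tb)
      fm <- fit_richness_models(meta$duration, rich)
      dd <- as.matrix(stats::dist(mt_$duration))
      mt <- mantel_test(bray_curtis(tb), dd, seed = config$seed)
      an <- anosim_test(bray_curtis(tb), mt_$stage, seed = config$seed)
      list(beta_partition = part$summary, richness_model = fm$best,
           model_table = fm$models, mantel = mt, anosim = an,
           richness = rich)
    })
    res$commstats <- cs
  }

  if (!"assembly" %in% config$skip) {
    res$assembly <- lapply(sub_tables, function(tb) {
      tb <- occupied(tb)
      mt_ <- meta[rownames(tb), ]
      if (config$assembly_pairs == "within_stage") {
        sw <- stagewise_assembly(tb, tree, mt_, n_null = config$n_null,
                                 seed = config$seed)
        list(pairs = sw$pairs, stage_fractions = sw$fractions,
             fractions = partition_processes(sw$pairs))
      } else {
        pw <- assembly_analysis(tb, tree, n_null = config$n_null,
                                seed = config$seed)
        list(pairs = pw, fractions = partition_processes(pw))
      }
    })
  }

  if (!"network" %in% config$skip) {
    tr <- temporal_response(table, meta, alpha = config$alpha)
    keep <- tr$asv_id[tr$response != "stable"]
    net <- NULL; topo <- NULL; keystones <- NULL; stage_deg <- NULL
    if (length(keep) >= 4) {
      sub <- table[, keep, drop = FALSE]
      rho <- sparcc(sub, n_resample = config$sparcc_resample,
                    seed = config$seed)
      pv <- sparcc_pvalues(sub, rho, n_boot = config$sparcc_boot,
                           n_resample = max(2, config$sparcc_resample %/% 10),
                           seed = config$seed)
      net <- build_network(rho, pv, labels = labels,
                           rho_min = config$rho_min, alpha = config$alpha)
      if (igraph::ecount(net) > 0) {
        topo <- node_topology(net)
        keystones <- modules_zipi(net, seed = config$seed)
      }
      sn <- suppressWarnings(
        stage_subnetworks(sub, meta, labels = labels,
                          n_resample = max(10, config$sparcc_resample %/% 2),
                          n_boot = max(19, config$sparcc_boot %/% 5),
                          seed = config$seed))
      stage_deg <- sn$summary
    } else warning("fewer than 4 temporally responsive ASVs; network skipped")
    res$network <- list(graph = net, topology = topo, keystones = keystones,
                        stage_summary = stage_deg,
                        n_responsive = length(keep))
  }

  if (!"emf" %in% config$skip) {
    rich_cl <- vapply(sub_tables, function(tb) rowSums(tb > 0),
                      numeric(nrow(table)))
    res$emf_richness <- richness_emf_regression(rich_cl, res$emf$EMF)
    prof <- asv_function_associations(table, functions, res$emf$EMF,
                                      alpha = config$alpha)
    res$asv_functions <- list(profile = prof,
                              proportions = proportion_vs_k(prof, labels))
    res$emf_mantel <- lapply(sub_tables, function(tb) {
      tb <- occupied(tb)
      emf_composition_mantel(tb, res$emf$EMF[match(rownames(tb), rownames(res$emf))],
                             seed = config$seed)
    })
    if (!is.null(res$network$topology))
      res$degree_emf <- degree_vs_emf(res$network$topology, prof)
  }

  if (!"pathmodel" %in% config$skip) {
    rich_cl <- as.data.frame(vapply(sub_tables, function(tb) rowSums(tb > 0),
                                    numeric(nrow(table))))
    dat <- data.frame(duration = meta$duration, cover = meta$cover,
                      pH = meta$pH, EMF = res$emf$EMF)
    rc <- make_composite(cbind(rich_cl, EMF = dat$EMF),
                         predictors = colnames(rich_cl), response = "EMF")
    dat$richness <- rc$scores
    spec <- default_path_spec()
    deg_ok <- !is.null(res$network$stage_summary) &&
      !is.null(res$network$topology)
    if (deg_ok) {
      sm <- res$network$stage_summary
      dat$degree <- sm$mean_degree[match(meta$stage, sm$stage)]
      deg_ok <- !anyNA(dat$degree) && stats::sd(dat$degree) > 0
    }
    if (!deg_ok) {
      ed <- spec$edges
      spec <- path_spec(ed[ed$from != "degree" & ed$to != "degree", ])
    }
    res$pathmodel <- list(fit = fit_path_model(spec, dat),
                          richness_weights = rc$weights)
  }

  res$manifest <- list(
    package_version = as.character(utils::packageVersion("chronosere")),
    n_samples = nrow(table), n_asvs = ncol(table),
    config = config[!vapply(config, is.function, logical(1))],
    timestamp = NULL)
  if (!is.null(out_dir)) write_run_outputs(res, out_dir)
  res
}

# Write the machine-readable outputs of a run; manifest carries md5 sums.
write_run_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(res$labels, file.path(out_dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$niche))
    utils::write.table(res$niche, file.path(out_dir, "niche.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$emf, file.path(out_dir, "emf.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$assembly)) {
    fr <- t(vapply(res$assembly, `[[`, numeric(5), "fractions"))
    utils::write.table(data.frame(class = rownames(fr), fr,
                                  check.names = FALSE),
                       file.path(out_dir, "assembly_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$network$topology))
    utils::write.table(res$network$topology,
                       file.path(out_dir, "network_topology.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  summary_json <- list(
    manifest = res$manifest,
    assembly_fractions = lapply(res$assembly, `[[`, "fractions"),
    emf_richness = res$emf_richness,
    pathmodel = if (!is.null(res$pathmodel))
      list(coefficients = res$pathmodel$fit$coefficients,
           fisher_c = res$pathmodel$fit$fisher_c))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  files <- list.files(out_dir, full.names = TRUE)
  md5 <- tools::md5sum(setdiff(files, file.path(out_dir, "manifest.json")))
  names(md5) <- basename(names(md5))
  jsonlite::write_json(list(manifest = res$manifest, md5 = as.list(md5)),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}
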