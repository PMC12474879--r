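#' Validate an ASV count table
#'
#' An ASV table is a plain numeric matrix of non-negative integer counts with
#' samples as rows and ASVs as columns, both dimensions named. This is the
#' internal orientation used throughout the package; on disk the common
#' amplicon convention (ASVs as rows) is used instead.
#'
#' @param x matrix to validate.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_asv_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("ASV table must be a numeric matrix (samples x ASVs)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("ASV table must have sample rownames and ASV colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate ASV ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) stop("ASV table contains missing values")
  if (any(x < 0)) stop("ASV table contains negative counts")
  if (any(abs(x - round(x)) > 1e-8)) stop("ASV table contains non-integer counts")
  invisible(x)
}

#' Read an ASV count table from a tab-separated file
#'
#' The file follows the common amplicon convention: first column holds ASV
#' ids, remaining columns are samples. The table is transposed on read so the
#' in-memory orientation is samples x ASVs.
#'
#' @param path path to a UTF-8, tab-separated file with a header row.
#' @return numeric count matrix, samples x ASVs.
#' @export
read_asv_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(raw) < 2) stop("ASV table needs an id column plus >=1 sample column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate ASV ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat),
                                 dimnames = dimnames(mat)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric count at ASV '%s', sample '%s' in %s",
                 ids[bad[1L]], colnames(mat)[bad[2L]], path))
  }
  rownames(num) <- ids
  x <- t(num)
  validate_asv_table(x)
  x
}

#' Write an ASV count table to a tab-separated file
#'
#' @param x ASV table (samples x ASVs).
#' @param path output path; written with ASVs as rows.
#' @param id_column header for the id column.
#' @export
write_asv_table <- function(x, path, id_column = "ASV_ID") {
  validate_asv_table(x)
  out <- data.frame(colnames(x), t(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1L] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample chronosequence metadata
#'
#' Expects columns `sample_id` and `duration` (restoration age in years,
#' non-negative); optional `stage` and `replicate` columns are derived from
#' `duration` when absent.
#'
#' @param path tab-separated file with a header row.
#' @return data.frame with columns sample_id, duration, stage, replicate.
#' @export
read_chrono_meta <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "duration")
  miss <- setdiff(need, colnames(m))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  m$duration <- as.numeric(m$duration)
  if (anyNA(m$duration) || any(m$duration < 0))
    stop("durations must be non-negative numbers")
  if (is.null(m$stage)) m$stage <- paste0("T", m$duration)
  if (is.null(m$replicate))
    m$replicate <- stats::ave(seq_len(nrow(m)), m$stage, FUN = seq_along)
  rownames(m) <- m$sample_id
  m
}

#' The 17 default ecosystem function names
#'
#' Plant productivity (AGB, PC, PN, PP), decomposition rate (DNA, Suc, bGlu,
#' Cel, Ure, ALP, Cat) and soil nutrient pools (SOC, NH4, NO3, STN, SAP, STP).
#' `bGlu` is the ASCII column name used for beta-glucosidase activity.
#'
#' @return character vector of 17 function names.
#' @export
emf_function_names <- function() {
  unname(unlist(emf_function_groups()))
}

#' Function subsets behind the PPI, DRI and SNPI indices
#'
#' @return named list of character vectors (PPI, DRI, SNPI).
#' @export
emf_function_groups <- function() {
  list(PPI  = c("AGB", "PC", "PN", "PP"),
       DRI  = c("DNA", "Suc", "bGlu", "Cel", "Ure", "ALP", "Cat"),
       SNPI = c("SOC", "NH4", "NO3", "STN", "SAP", "STP"))
}

#' Read a per-sample ecosystem function table
#'
#' @param path tab-separated file, first column sample ids, one column per
#'   function.
#' @param functions required function names (default the 17 standard ones).
#' @return numeric matrix samples x functions, restricted to `functions`.
#' @export
read_function_table <- function(path, functions = emf_function_names()) {
  f <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         quote = "")
  miss <- setdiff(functions, colnames(f))
  if (length(miss))
    stop("function table lacks: ", paste(miss, collapse = ", "))
  x <- as.matrix(f[, functions, drop = FALSE])
  if (!is.numeric(x) || anyNA(x)) stop("function table has non-numeric entries")
  x
}

#' Write a per-sample table (metadata or functions) as TSV
#' @param x data.frame or matrix with sample rownames.
#' @param path output path.
#' @param id_column header for the id column.
#' @export
write_sample_table <- function(x, path, id_column = "sample_id") {
  out <- data.frame(rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out)[1L] <- id_column
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny of ASVs
#'
#' @param path newick file.
#' @param asv_ids optional ids that must all be present as tips.
#' @return an [ape::read.tree()] "phylo" object.
#' @export
read_phylo <- function(path, asv_ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree from ", path)
  if (!is.null(asv_ids)) {
    miss <- setdiff(asv_ids, tree$tip.label)
    if (length(miss))
      stop("tree lacks tips for ASV(s): ", paste(miss, collapse = ", "))
  }
  tree
}

#' Align ASV table, metadata, functions and tree on shared ids
#'
#' Sample ids are intersected across table, metadata and functions; ASV ids
#' must all be present in the tree when one is given. The intersection is
#' taken silently apart from an informational message; an empty intersection
#' is an error.
#'
#' @param table ASV table.
#' @param meta chronosequence metadata (or NULL).
#' @param functions function matrix (or NULL).
#' @param tree phylogeny (or NULL).
#' @return list(table, meta, functions, tree) restricted to shared samples.
#' @export
align_inputs <- function(table, meta = NULL, functions = NULL, tree = NULL) {
  validate_asv_table(table)
  samples <- rownames(table)
  if (!is.null(meta)) {
    miss <- setdiff(samples, meta$sample_id)
    if (length(miss))
      stop("metadata missing sample(s): ", paste(miss, collapse = ", "))
    samples <- intersect(samples, meta$sample_id)
  }
  if (!is.null(functions)) samples <- intersect(samples, rownames(functions))
  if (!length(samples)) stop("no samples shared across inputs")
  if (length(samples) < nrow(table))
    message("restricting to ", length(samples), " shared samples")
  table <- table[samples, , drop = FALSE]
  if (!is.null(meta)) meta <- meta[samples, , drop = FALSE]
  if (!is.null(functions)) functions <- functions[samples, , drop = FALSE]
  if (!is.null(tree)) {
    miss <- setdiff(colnames(table), tree$tip.label)
    if (length(miss))
      stop("tree lacks tips for ASV(s): ", paste(utils::head(miss, 10), collapse = ", "),
           if (length(miss) > 10) sprintf(" ... (%d total)", length(miss)))
  }
  list(table = table, meta = meta, functions = functions, tree = tree)
}

#' Rarefy an ASV table to even depth
#'
#' Each sample is subsampled without replacement (multivariate hypergeometric
#' draw) to exactly `depth` reads; one draw per sample.
#'
#' @param x ASV table.
#' @param depth target reads per sample; must not exceed any sample's total.
#' @param seed integer seed making the draw reproducible.
#' @return rarefied ASV table with every row summing to `depth`.
#' @export
rarefy <- function(x, depth, seed = 1L) {
  validate_asv_table(x)
  totals <- rowSums(x)
  low <- totals < depth
  if (any(low))
    stop("depth ", depth, " exceeds total reads of sample(s): ",
         paste(rownames(x)[low], collapse = ", "))
  set.seed(seed)
  out <- x
  for (i in seq_len(nrow(x))) {
    ci <- x[i, ]
    reads <- rep.int(seq_along(ci), ci)
    keep <- reads[sample.int(length(reads), depth)]
    out[i, ] <- tabulate(keep, nbins = length(ci))
  }
  out
}

#' Convert counts to per-sample relative abundances
#'
#' @param x ASV table (or any non-negative samples x taxa matrix).
#' @return matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(x) {
  totals <- rowSums(x)
  if (any(totals <= 0))
    stop("all-zero sample(s): ",
         paste(rownames(x)[totals <= 0], collapse = ", "))
  x / totals
}
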