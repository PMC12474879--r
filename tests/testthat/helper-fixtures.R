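# Shared fixtures, all built in code.

# 4 samples x 6 ASVs with a skewed column-total profile
tiny_table <- function() {
  m <- matrix(c(
    50, 20, 5, 2, 1, 0,
    40, 25, 8, 0, 2, 1,
    60, 15, 4, 3, 0, 0,
    45, 30, 6, 1, 1, 2), nrow = 4, byrow = TRUE)
  dimnames(m) <- list(paste0("s", 1:4), paste0("asv", 1:6))
  m
}

# the 3-tip reference tree: d(A,B) = 3, d(B,C) = 2
toy_tree <- function() ape::read.tree(text = "(A:1,(B:1,C:1):1);")

# random count table with fixed seed
random_table <- function(n = 6, p = 12, seed = 1, depth = 500) {
  set.seed(seed)
  m <- t(sapply(seq_len(n), function(i)
    rmultinom(1, depth, rgamma(p, 0.5))[, 1]))
  dimnames(m) <- list(paste0("s", seq_len(n)), paste0("asv", seq_len(p)))
  m
}

# independent-minded Bray-Curtis for one pair (oracle)
bc_pair <- function(x, y) sum(abs(x - y)) / sum(x + y)

# metadata for a table whose samples split evenly into `k` stages
stages_meta <- function(table, durations) {
  n <- nrow(table)
  k <- length(durations)
  stopifnot(n %% k == 0)
  data.frame(sample_id = rownames(table),
             duration = rep(durations, each = n / k),
             stage = rep(paste0("T", durations), each = n / k),
             replicate = rep(seq_len(n / k), times = k),
             row.names = rownames(table), stringsAsFactors = FALSE)
}

# function matrix with the 17 standard names, positive, seeded
random_functions <- function(samples, seed = 1) {
  set.seed(seed)
  f <- matrix(rlnorm(length(samples) * 17, 1, 0.4), length(samples), 17,
              dimnames = list(samples, emf_function_names()))
  f
}

# all permutations of 1..n as a matrix (n small)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
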