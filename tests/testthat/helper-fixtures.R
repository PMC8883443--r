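# Shared fixtures built in code; all randomness is seeded locally.

random_count_matrix <- function(n_genes, n_cells, lambda = 5, seed = 1L) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("c", seq_len(n_cells))))
  count_matrix(m)
}

# chance-corrected agreement between two partitions
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# default mapping simulation used across mapping tests
default_mapping_sim <- function(n_cells = 500L, r = 20, lambda = 0.1,
                                seed = 11L, depth_spread = 0) {
  ref <- make_reference(default_hox_specs(), grid_size = 201L)
  sim <- simulate_cells(ref, n_cells = n_cells, r = r, lambda_bg = lambda,
                        depth_spread = depth_spread, seed = seed)
  list(ref = ref, counts = sim$counts, truth = sim$truth)
}
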