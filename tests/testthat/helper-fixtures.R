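# Small in-code fixtures shared across test files.

tiny_symmetric <- function(K, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::runif(K * K, -1, 1), K, K)
    m <- (m + t(m)) / 2
    diag(m) <- 1
    m
  })
}

tiny_stack <- function(N = 8, K = 6, seed = 1) {
  withr::with_seed(seed, {
    mats <- lapply(seq_len(N), function(s) fc_matrix(tiny_symmetric(K, seed + s)))
    stack_cohort(mats, rep(c("HC", "SZ"), length.out = N))
  })
}

# a subnetwork object built directly from an edge list (i > j), for tests
# that do not need the decomposition upstream
manual_subnetwork <- function(K, edges, values, component = 1L) {
  map <- edge_index_map(K)
  idx <- vapply(seq_len(nrow(edges)), function(r)
    which(map$i == edges[r, 1] & map$j == edges[r, 2]), integer(1))
  mask <- logical(map$E)
  mask[idx] <- TRUE
  ica <- numeric(map$E)
  ica[idx] <- values
  structure(list(component = component, edge_mask = mask, ica_values = ica,
                 retained_fraction = mean(mask)),
            class = "subnetwork")
}

default_cohort <- function(seed = 7) generate_cohort(synthetic_config(seed = seed))
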