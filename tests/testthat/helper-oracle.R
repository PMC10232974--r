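# Brute-force graph-metric oracle, independent of the package implementation
# (pure-R exhaustive simple-path enumeration and direct triple loops). Only
# feasible for small graphs (n <= 8).

oracle_shortest <- function(W, from, to) {
  n <- nrow(W)
  best <- Inf
  recurse <- function(node, visited, acc) {
    if (acc >= best) return()
    if (node == to) { best <<- acc; return() }
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && W[node, nxt] > 0)
        recurse(nxt, `[<-`(visited, nxt, TRUE), acc + 1 / W[node, nxt])
    }
  }
  recurse(from, `[<-`(logical(n), from, TRUE), 0)
  best
}

oracle_length_matrix <- function(W) {
  n <- nrow(W)
  D <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    D[a, b] <- D[b, a] <- oracle_shortest(W, a, b)
  D
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  if (n < 2) return(0)
  D <- oracle_length_matrix(W)
  off <- D[row(D) != col(D)]
  mean(ifelse(is.finite(off), 1 / off, 0))
}

oracle_metrics <- function(W) {
  n <- nrow(W)
  D <- oracle_length_matrix(W)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  L_net <- if (any(finite)) mean(off[finite]) else NA_real_
  E_global <- mean(ifelse(finite, 1 / off, 0))
  S <- sum(W) / n
  C_i <- numeric(n)
  E_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    acc <- 0
    for (j in nb) for (l in nb)
      if (j != l) acc <- acc + (W[i, j] * W[i, l] * W[j, l])^(1 / 3)
    C_i[i] <- acc / (k * (k - 1))
    E_i[i] <- oracle_efficiency(W[nb, nb, drop = FALSE])
  }
  list(L_net = L_net, S = S, E_global = E_global,
       E_local = mean(E_i), C_net = mean(C_i))
}

random_small_graph <- function(n, density = 0.6) {
  W <- matrix(0, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n)
    if (stats::runif(1) < density)
      W[a, b] <- W[b, a] <- stats::runif(1, min = 1e-6, max = 1)
  W
}
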