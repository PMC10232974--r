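#' Build a weighted graph from a connectivity matrix, restricted to a
#' subnetwork's edges
#'
#' The subnetwork graph keeps the subject's *original* absolute
#' connectivity values at the retained edge locations and zeros elsewhere.
#'
#' @param connectivity An `fc_matrix`, or a K x K symmetric matrix of
#'   absolute weights, or an edge vector of length E.
#' @param subnetwork A `subnetwork` (NULL keeps the whole-brain graph).
#' @param map Edge index map (required when `connectivity` is an edge
#'   vector; inferred otherwise).
#' @return K x K symmetric nonnegative weight matrix with zero diagonal.
#' @export
subnetwork_graph <- function(connectivity, subnetwork = NULL, map = NULL) {
  if (inherits(connectivity, "fc_matrix")) connectivity <- connectivity$values
  if (is.matrix(connectivity)) {
    if (is.null(map)) map <- edge_index_map(nrow(connectivity))
    v <- abs(connectivity[cbind(map$i, map$j)])
  } else {
    if (is.null(map)) stop("subnetwork_graph: map required for edge vectors")
    v <- abs(as.numeric(connectivity))
    if (length(v) != map$E) stop("subnetwork_graph: edge vector length != E")
  }
  if (!is.null(subnetwork)) {
    if (!any(subnetwork$edge_mask))
      warning("subnetwork_graph: empty mask, empty graph")
    v[!subnetwork$edge_mask] <- 0
  }
  devectorize(v, map$K, diag_value = 0)
}

# all-pairs shortest path lengths; edge length is 1/w ("reciprocal", the
# connectivity-toolbox convention: strong correlations are short) or the raw
# weight itself ("raw", the literal minimum-weight-summation reading, kept
# for comparison)
shortest_lengths <- function(W, length_mode = c("reciprocal", "raw")) {
  length_mode <- match.arg(length_mode)
  K <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    D <- matrix(Inf, K, K); diag(D) <- 0; return(D)
  }
  len <- if (length_mode == "reciprocal") 1 / igraph::E(g)$weight
         else igraph::E(g)$weight
  igraph::distances(g, weights = len)
}

#' Characteristic path length and global efficiency
#'
#' Edge lengths are reciprocal weights `1/w` by default (strong connections
#' are short); shortest paths use Dijkstra over nonnegative lengths. The
#' characteristic path length `L_net` is the mean shortest-path length over
#' ordered node pairs, excluding disconnected (infinite) pairs with a flag;
#' global efficiency `E_global` is the mean of `1/L_ij` over all ordered
#' pairs, disconnected pairs contributing 0.
#'
#' @param W K x K symmetric nonnegative weight matrix, zero diagonal.
#' @param length_mode `"reciprocal"` (default) or `"raw"`.
#' @return List: `L_net` (NA with flag if no pair is connected),
#'   `E_global`, `n_disconnected_pairs` (ordered count).
#' @export
path_metrics <- function(W, length_mode = "reciprocal") {
  K <- nrow(W)
  if (K < 2) stop("path_metrics: need at least 2 nodes")
  D <- shortest_lengths(W, length_mode)
  off <- D[row(D) != col(D)]
  finite <- is.finite(off)
  L_net <- if (any(finite)) mean(off[finite]) else NA_real_
  E_global <- mean(ifelse(finite, 1 / off, 0))
  list(L_net = L_net, E_global = E_global,
       n_disconnected_pairs = sum(!finite))
}

#' Network strength
#'
#' Mean nodal strength: `S = (1/K) * sum_i sum_{j != i} w_ij` — each edge
#' is counted from both endpoints, as in the printed definition (a
#' per-edge-once variant is available via `per_edge_once = TRUE`).
#'
#' @param W K x K symmetric nonnegative weight matrix, zero diagonal.
#' @param per_edge_once Halve the double-counting (default FALSE).
#' @return Scalar strength.
#' @export
graph_strength <- function(W, per_edge_once = FALSE) {
  s <- sum(W) / nrow(W)
  if (per_edge_once) s / 2 else s
}

#' Onnela clustering coefficient and local efficiency
#'
#' The weighted clustering of node i is
#' `C_i = 2/(k_i (k_i - 1)) * sum_{j<k in G_i} (w_ij w_ik w_jk)^(1/3)`
#' (weights are absolute correlations, already in [0, 1], so no further
#' normalization); `C_i = 0` when node i has fewer than 2 neighbors, and
#' `C_net` averages over all K nodes. Local efficiency of node i is the
#' efficiency (mean inverse shortest-path length, reciprocal edge lengths)
#' of the subgraph induced by i's neighbors with i removed; nodes with
#' fewer than 2 neighbors contribute 0, and `E_local` is the node mean.
#'
#' @param W K x K symmetric nonnegative weight matrix in [0, 1], zero
#'   diagonal.
#' @return List: `C_net`, `E_local`, and the per-node vectors `C_i`,
#'   `E_i_local`.
#' @export
clustering_and_local_efficiency <- function(W) {
  K <- nrow(W)
  W3 <- W^(1 / 3)
  tri <- diag(W3 %*% W3 %*% W3)   # 2 * sum over unordered neighbor pairs
  k <- rowSums(W > 0)
  C_i <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  E_i <- numeric(K)
  for (i in seq_len(K)) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) next
    E_i[i] <- path_metrics(W[nb, nb, drop = FALSE])$E_global
  }
  list(C_net = mean(C_i), E_local = mean(E_i), C_i = C_i, E_i_local = E_i)
}

#' All five weighted topology metrics of one graph
#'
#' @param W K x K symmetric nonnegative weight matrix, zero diagonal (e.g.
#'   from [subnetwork_graph()]).
#' @param length_mode Passed to [path_metrics()].
#' @return Object of class `graph_metric_set`: `L_net`, `S`, `E_global`,
#'   `E_local`, `C_net` (plus `n_disconnected_pairs`).
#' @export
graph_metrics <- function(W, length_mode = "reciprocal") {
  if (!isTRUE(all.equal(W, t(W))) || any(W < 0) || any(diag(W) != 0))
    stop("graph_metrics: need a symmetric nonnegative matrix with zero diagonal")
  pm <- path_metrics(W, length_mode)
  cl <- clustering_and_local_efficiency(W)
  structure(list(L_net = pm$L_net, S = graph_strength(W),
                 E_global = pm$E_global, E_local = cl$E_local,
                 C_net = cl$C_net,
                 n_disconnected_pairs = pm$n_disconnected_pairs),
            class = "graph_metric_set")
}

#' @export
print.graph_metric_set <- function(x, ...) {
  cat(sprintf("L_net=%.4f S=%.4f E_global=%.4f E_local=%.4f C_net=%.4f\n",
              x$L_net, x$S, x$E_global, x$E_local, x$C_net))
  invisible(x)
}

metric_names <- c("L_net", "S", "E_global", "E_local", "C_net")

#' Per-subject graph metrics for the whole brain and each subnetwork
#'
#' @param stack A `cohort_stack`.
#' @param subnetworks A `subnetwork_set` (may be empty for whole brain
#'   only).
#' @return data.frame: `subject_id`, `group`, `network` ("whole_brain" or
#'   "subnetwork_<i>"), and the five metric columns.
#' @export
cohort_graph_metrics <- function(stack, subnetworks = list()) {
  nets <- list(whole_brain = NULL)
  for (sn in subnetworks) nets[[paste0("subnetwork_", sn$component)]] <- sn
  rows <- list()
  for (s in seq_len(nrow(stack$X))) {
    for (nm in names(nets)) {
      W <- subnetwork_graph(stack$X[s, ], nets[[nm]], map = stack$map)
      gm <- graph_metrics(W)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = stack$subject_ids[s],
        group = as.character(stack$labels[s]), network = nm,
        L_net = gm$L_net, S = gm$S, E_global = gm$E_global,
        E_local = gm$E_local, C_net = gm$C_net)
    }
  }
  do.call(rbind, rows)
}

#' Group comparison of graph metrics
#'
#' Two-sample pooled t-test and Cohen's d per network and metric, at the
#' graph-analysis significance level (0.05 by default, unlike the 0.005
#' subnetwork level).
#'
#' @param metrics_df Output of [cohort_graph_metrics()].
#' @param alpha Significance level (default 0.05).
#' @return data.frame: `network`, `metric`, group means/SDs, `t`, `p`,
#'   `cohens_d`, `significant`.
#' @export
group_graph_comparison <- function(metrics_df, alpha = 0.05) {
  rows <- list()
  for (nm in unique(metrics_df$network)) {
    sub <- metrics_df[metrics_df$network == nm, ]
    for (met in metric_names) {
      # subjects whose graph leaves a metric undefined (e.g. L_net of an
      # edgeless subnetwork graph) are excluded from that metric's test
      hc <- sub[[met]][sub$group == "HC"]
      sz <- sub[[met]][sub$group == "SZ"]
      hc <- hc[is.finite(hc)]
      sz <- sz[is.finite(sz)]
      if (length(hc) < 2 || length(sz) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          network = nm, metric = met, mean_hc = NA_real_, sd_hc = NA_real_,
          mean_sz = NA_real_, sd_sz = NA_real_, t = NA_real_, p = NA_real_,
          cohens_d = NA_real_, significant = FALSE)
        next
      }
      st <- ttest_and_effect(hc, sz, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        network = nm, metric = met, mean_hc = st$mean_hc, sd_hc = st$sd_hc,
        mean_sz = st$mean_sz, sd_sz = st$sd_sz, t = st$t, p = st$p,
        cohens_d = st$cohens_d, significant = st$significant)
    }
  }
  do.call(rbind, rows)
}
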