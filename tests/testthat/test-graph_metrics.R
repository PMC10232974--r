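line3 <- function(w = 0.5) {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- w
  W[2, 3] <- W[3, 2] <- w
  W
}

triangle3 <- function(w = 0.5) {
  W <- matrix(w, 3, 3); diag(W) <- 0; W
}

test_that("hand-derived values on the 3-node line and triangle", {
  pm <- path_metrics(line3(0.5))
  expect_equal(pm$L_net, 8 / 3)          # lengths 2, 2, 4
  expect_equal(pm$E_global, 5 / 12)      # (1/2 + 1/2 + 1/4) / 3
  expect_equal(graph_strength(line3(0.5)), 2 / 3)  # nodal strengths .5, 1, .5
  cl <- clustering_and_local_efficiency(line3(0.5))
  expect_equal(cl$C_net, 0)              # no triangles
  expect_equal(cl$E_local, 0)

  clt <- clustering_and_local_efficiency(triangle3(0.5))
  expect_equal(clt$C_i, rep(0.5, 3))     # (0.125)^(1/3)
  expect_equal(clt$C_net, 0.5)
  expect_equal(clustering_and_local_efficiency(triangle3(1))$C_net, 1)

  # complete graph with unit weights: L_net = 1, E_global = 1, S = K - 1
  K <- 5
  W1 <- matrix(1, K, K); diag(W1) <- 0
  pmc <- path_metrics(W1)
  expect_equal(pmc$L_net, 1)
  expect_equal(pmc$E_global, 1)
  expect_equal(graph_strength(W1), K - 1)
})

test_that("scale equivariance and invariances hold", {
  withr::with_seed(51, W <- random_small_graph(7, density = 0.7))
  pm1 <- path_metrics(W)
  pm2 <- path_metrics(2 * W)
  expect_equal(pm2$L_net, pm1$L_net / 2)
  expect_equal(pm2$E_global, pm1$E_global * 2)
  # node relabeling leaves every metric unchanged
  perm <- c(3, 1, 7, 2, 6, 4, 5)
  gm1 <- graph_metrics(W)
  gm2 <- graph_metrics(W[perm, perm])
  for (m in c("L_net", "S", "E_global", "E_local", "C_net"))
    expect_equal(gm2[[m]], gm1[[m]])
  # bounds for weights in [0, 1]
  expect_true(gm1$C_net >= 0 && gm1$C_net <= 1)
  expect_true(gm1$E_global >= 0 && gm1$E_global <= 1)
})

test_that("disconnected graphs are flagged, not fatal", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.5
  pm <- path_metrics(W)
  expect_equal(pm$n_disconnected_pairs, 10L)  # ordered pairs not 1-2
  expect_equal(pm$L_net, 2)                   # only the connected pair counts
  expect_equal(pm$E_global, (0.5 + 0.5) / 12)
  # fully isolated graph
  pm0 <- path_metrics(matrix(0, 3, 3))
  expect_true(is.na(pm0$L_net))
  expect_equal(pm0$E_global, 0)
})

test_that("the raw length mode reads weights as lengths literally", {
  pm <- path_metrics(line3(0.5), length_mode = "raw")
  # direct 1-2 costs 0.5, but no shorter detour exists
  expect_equal(pm$L_net, (0.5 + 0.5 + 1) / 3)
})

test_that("subnetwork graphs keep original weights at retained edges only", {
  g <- default_cohort(seed = 37)
  st <- g$cohort
  sn <- manual_subnetwork(st$map$K,
                          rbind(c(2, 1), c(5, 3), c(10, 4)), c(1, -2, 0.5))
  W <- subnetwork_graph(st$X[1, ], sn, map = st$map)
  expect_equal(W[2, 1], st$X[1, 1], ignore_attr = TRUE)
  expect_equal(sum(W > 0), 6L)  # 3 edges, both triangle halves
  expect_equal(W, t(W))
  # full mask reproduces the whole-brain graph
  full <- manual_subnetwork(st$map$K, cbind(st$map$i, st$map$j),
                            rep(1, st$map$E))
  expect_equal(subnetwork_graph(st$X[1, ], full, map = st$map),
               subnetwork_graph(st$X[1, ], NULL, map = st$map))
})

test_that("group comparison separates a planted strength deficit", {
  # two groups of graphs identical except SZ edge weights attenuated inside
  # a planted block: that subnetwork's strength differs, whole brain less so
  withr::with_seed(61, {
    K <- 15; map <- edge_index_map(K)
    base <- matrix(stats::runif(24 * map$E, 0.2, 0.6), 24, map$E)
    block <- which(map$i <= 5 & map$j <= 5)
    base[13:24, block] <- base[13:24, block] * 0.6
  })
  st <- structure(list(X = base,
                       labels = factor(rep(c("HC", "SZ"), each = 12),
                                       levels = c("HC", "SZ")),
                       subject_ids = sprintf("s%02d", 1:24),
                       node_names = sprintf("n%03d", seq_len(K)), map = map),
                  class = "cohort_stack")
  sn <- structure(list(component = 1L,
                       edge_mask = seq_len(map$E) %in% block,
                       ica_values = as.numeric(seq_len(map$E) %in% block),
                       retained_fraction = length(block) / map$E),
                  class = "subnetwork")
  gm <- cohort_graph_metrics(st, structure(list(sn), class = "subnetwork_set"))
  cmp <- group_graph_comparison(gm)
  s_sub <- cmp[cmp$network == "subnetwork_1" & cmp$metric == "S", ]
  expect_true(s_sub$significant)
  expect_gt(s_sub$mean_hc, s_sub$mean_sz)
})
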