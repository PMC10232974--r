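two_group_stack <- function(X, labels, K) {
  map <- edge_index_map(K)
  stopifnot(ncol(X) == map$E)
  structure(list(X = X, labels = factor(labels, levels = c("HC", "SZ")),
                 subject_ids = sprintf("s%02d", seq_len(nrow(X))),
                 node_names = sprintf("n%03d", seq_len(K)), map = map),
            class = "cohort_stack")
}

test_that("method A projects restricted vectors onto |V_HC - V_SZ|", {
  # K = 3, mask = first two edges; group means V_HC = (.5, .3), V_SZ = (.3, .1)
  X <- rbind(c(0.5, 0.3, 0.9),
             c(0.5, 0.3, 0.1),
             c(0.3, 0.1, 0.5),
             c(0.3, 0.1, 0.2),
             c(0.4, 0.2, 0.7))
  st <- two_group_stack(X, c("HC", "HC", "SZ", "SZ", "HC"), K = 3)
  sn <- manual_subnetwork(3, rbind(c(2, 1), c(3, 1)), c(1, 1))
  pa <- project_method_A(sn, st)
  v_hc <- colMeans(X[c(1, 2, 5), 1:2]); v_sz <- colMeans(X[3:4, 1:2])
  expect_equal(unname(pa$diff), abs(v_hc - v_sz), ignore_attr = TRUE)
  # subject with restricted vector (0.4, 0.2) against Diff = (0.2, 0.2):
  # hand inner product 0.4*0.2 + 0.2*0.2 = 0.12
  st2 <- two_group_stack(X[1:4, ], c("HC", "HC", "SZ", "SZ"), K = 3)
  pa2 <- project_method_A(sn, st2)
  expect_equal(unname(pa2$scores), drop(X[1:4, 1:2] %*% c(0.2, 0.2)))
  expect_equal(sum(c(0.4, 0.2) * pa2$diff), 0.12)
  # identical group means -> all scores 0
  Xnull <- rbind(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.8))
  stn <- two_group_stack(Xnull, c("HC", "SZ"), K = 3)
  expect_equal(unname(project_method_A(sn, stn)$scores), c(0, 0))
  # method A ignores ICA magnitudes entirely
  sn_big <- manual_subnetwork(3, rbind(c(2, 1), c(3, 1)), c(7, -2))
  expect_equal(project_method_A(sn_big, st)$scores, pa$scores)
  # empty mask errors
  empty <- manual_subnetwork(3, matrix(numeric(0), 0, 2), numeric(0))
  expect_error(project_method_A(empty, st), "empty")
})

test_that("method B is the inner product with the ICA-value vector", {
  X <- rbind(c(0.5, 0.2, 0.9), c(1.0, 0.4, 1.0))
  st <- two_group_stack(X, c("HC", "SZ"), K = 3)
  sn <- manual_subnetwork(3, rbind(c(2, 1), c(3, 1)), c(1, -1))
  pb <- project_method_B(sn, st)
  expect_equal(unname(pb$scores), c(0.5 - 0.2, 1.0 - 0.4))
  # linearity: doubling the subject vector doubles the score
  expect_equal(pb$scores[[2]], sum(2 * X[1, 1:2] * c(1, -1)))
  # all-zero ICA vector -> all scores 0
  zero <- manual_subnetwork(3, rbind(c(2, 1)), 0)
  expect_equal(unname(project_method_B(zero, st)$scores), c(0, 0))
})

test_that("pooled t and Cohen's d match closed forms", {
  st <- ttest_and_effect(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$cohens_d, -3)
  expect_equal(abs(st$t), 3 * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(st$p, 2 * stats::pt(-3 * sqrt(3 / 2), df = 4), tolerance = 1e-12)
  # identical groups
  st0 <- ttest_and_effect(c(1, 2, 3), c(1, 2, 3))
  expect_equal(st0$t, 0)
  expect_equal(st0$cohens_d, 0)
  expect_false(st0$significant)
  # degenerate: zero variance in both groups, unequal means
  expect_error(ttest_and_effect(c(1, 1), c(2, 2)), "zero variance")
  # cross-check the pooled-t p-value against a permutation t-test
  withr::with_seed(41, {
    a <- stats::rnorm(8); b <- stats::rnorm(8) + 1
    tobs <- abs(ttest_and_effect(a, b)$t)
    pool <- c(a, b)
    tperm <- replicate(4000, {
      idx <- sample(16, 8)
      abs(ttest_and_effect(pool[idx], pool[-idx])$t)
    })
    p_perm <- mean(tperm >= tobs)
  })
  expect_lt(abs(ttest_and_effect(a, b)$p - p_perm), 0.02)
})

test_that("subnetwork_stats covers both methods at alpha 0.005", {
  g <- default_cohort(seed = 29)
  dec <- suppressWarnings(
    decompose_cohort(g$cohort, R = 4, n_select = 3, seed = 77))
  subs <- prune_components(dec$selected, pruning_config(0.2))
  tab <- subnetwork_stats(subs, g$cohort)
  expect_equal(nrow(tab), 6L)
  expect_setequal(unique(tab$method), c("A", "B"))
  expect_equal(tab$significant, tab$p < 0.005)
  prj <- attr(tab, "projections")
  expect_equal(unname(prj[[1]]$B$scores),
               unname(drop(g$cohort$X %*% subs[[1]]$ica_values)))
})

test_that("discriminant links find a planted strong edge and respect cuts", {
  withr::with_seed(43, {
    K <- 6; map <- edge_index_map(K)
    X <- matrix(stats::runif(24 * map$E, 0.3, 0.5), 24, map$E)
    X[13:24, 4] <- X[13:24, 4] + 0.3   # strong group shift on edge 4
  })
  st <- two_group_stack(X, rep(c("HC", "SZ"), each = 12), K = 6)
  ica <- numeric(map$E); ica[4] <- 4; ica[7] <- 3.6; ica[2] <- 1
  sn <- structure(list(component = 1L, edge_mask = ica != 0, ica_values = ica,
                       retained_fraction = mean(ica != 0)),
                  class = "subnetwork")
  links <- discriminant_links(sn, st)
  expect_equal(attr(links, "n_tested"), 2L)  # |ICA| > 3.5: edges 4 and 7 only
  expect_equal(links$edge[1], 4)             # planted edge first (lowest p)
  expect_true(all(links$p < 0.01))
  # infinite cut -> empty result with warning
  expect_warning(l0 <- discriminant_links(sn, st, ica_cut = Inf), "no edge")
  expect_equal(nrow(l0), 0L)
})

test_that("under label shuffling the surviving fraction matches p_cut", {
  withr::with_seed(47, {
    K <- 10; map <- edge_index_map(K)
    X <- matrix(stats::runif(30 * map$E, 0.2, 0.6), 30, map$E)
    ica <- numeric(map$E); ica[sample(map$E, 20)] <- 4
    sn <- structure(list(component = 1L, edge_mask = ica != 0,
                         ica_values = ica, retained_fraction = mean(ica != 0)),
                    class = "subnetwork")
    surv <- replicate(40, {
      st <- two_group_stack(X, sample(rep(c("HC", "SZ"), each = 15)), K = K)
      nrow(discriminant_links(sn, st, p_cut = 0.05))
    })
  })
  # 40 replicates x 20 null edges at p_cut 0.05: mean fraction ~ 0.05
  frac <- mean(surv) / 20
  expect_lt(abs(frac - 0.05), 0.03)
})
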