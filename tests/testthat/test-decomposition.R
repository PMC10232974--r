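make_reduced <- function(Xp) {
  structure(list(Xprime = Xp, C = nrow(Xp)), class = "reduced_features")
}

laplace_sources <- function(C, E, seed) {
  withr::with_seed(seed,
    matrix(sign(stats::runif(C * E) - 0.5) * stats::rexp(C * E), C, E))
}

test_that("subject-dimension PCA honours the variance target", {
  # rank-1 world: all rows multiples of one vector -> C = 1, 100% explained
  withr::with_seed(2, {
    v <- stats::runif(50)
    X <- outer(c(1, 2, 3.5, -1, 0.2), v)
  })
  st <- structure(list(X = X, subject_ids = sprintf("s%d", 1:5)),
                  class = "cohort_stack")
  red <- pca_reduce(st, 0.90)
  expect_equal(red$C, 1L)
  expect_equal(red$explained_variance, 1.0)

  # full-rank world at target 1.0: centering leaves N - 1 dimensions
  st2 <- tiny_stack(N = 7, K = 8)
  red2 <- pca_reduce(st2, 1.0)
  expect_equal(red2$C, 6L)

  # independent oracle: prcomp's cumulative variances give the same C, and
  # the reduced rows capture >= 90% of the centered sum of squares
  st3 <- tiny_stack(N = 10, K = 10, seed = 4)
  red3 <- pca_reduce(st3, 0.90)
  pc <- prcomp(st3$X, center = TRUE, scale. = FALSE)
  C_oracle <- which(cumsum(pc$sdev^2) / sum(pc$sdev^2) >= 0.90)[1]
  expect_equal(red3$C, C_oracle)
  Xc <- scale(st3$X, center = TRUE, scale = FALSE)
  expect_gte(sum(red3$Xprime^2) / sum(Xc^2), 0.90)
  # projector applied to the original stack reproduces Xprime
  expect_equal(red3$projector %*% Xc, red3$Xprime, ignore_attr = TRUE)
})

test_that("Infomax recovers planted Laplace sources and is deterministic", {
  S_true <- laplace_sources(2, 2000, seed = 5)
  A_true <- withr::with_seed(6, matrix(stats::rnorm(4), 2, 2))
  red <- make_reduced(A_true %*% S_true)
  d <- infomax_ica(red, seed = 9)
  expect_true(d$converged)
  cors <- abs(stats::cor(t(d$S), t(S_true)))
  expect_true(all(apply(cors, 2, max) > 0.99))
  # exact affine reconstruction and unit-variance convention
  expect_lt(norm(d$A %*% d$S - red$Xprime, "F") / norm(red$Xprime, "F"), 1e-6)
  expect_equal(apply(d$S, 1, stats::sd), c(1, 1))
  # sign convention: largest-magnitude entry of each row positive
  for (r in 1:2) expect_gt(d$S[r, which.max(abs(d$S[r, ]))], 0)
  # same seed -> identical decomposition; different seed -> same product A*S
  d2 <- infomax_ica(red, seed = 9)
  expect_identical(d$A, d2$A)
  expect_identical(d$S, d2$S)
  d3 <- infomax_ica(red, seed = 10)
  expect_equal(d3$A %*% d3$S, d$A %*% d$S, tolerance = 1e-6)
})

test_that("RAICAR scores self-matching runs at 1 and ranks noise last", {
  S <- laplace_sources(3, 800, seed = 8)
  # pre-apply the representative sign convention so identity is exact
  for (r in 1:3) if (S[r, which.max(abs(S[r, ]))] < 0) S[r, ] <- -S[r, ]
  base <- structure(list(A = diag(3), S = S, converged = TRUE),
                    class = "fc_decomposition")
  ranked <- raicar_align(list(base, base, base))
  expect_equal(ranked$table$reproducibility, rep(1, 3))
  expect_equal(ranked$table$component, 1:3)
  expect_identical(ranked$S, S)

  # every run shares components 1-2 (slightly jittered); each run's third
  # row is independent noise -> the noise component matches nowhere
  jitter_run <- function(seed) {
    withr::with_seed(seed, {
      Sr <- S
      Sr[1:2, ] <- Sr[1:2, ] + matrix(stats::rnorm(2 * 800, sd = 0.05), 2)
      Sr[3, ] <- stats::rnorm(800)
      structure(list(A = diag(3), S = Sr, converged = TRUE),
                class = "fc_decomposition")
    })
  }
  runs <- lapply(1:4, jitter_run)
  r2 <- raicar_align(runs, match_threshold = 0.8)
  expect_equal(r2$table$component[3], 3L)       # noise ranked last
  expect_equal(r2$table$match_count[3], 0L)
  expect_true(all(r2$table$match_count[1:2] == 3L))
  expect_true(all(diff(r2$table$reproducibility) <= 0))
  expect_true(all(r2$table$reproducibility >= 0 & r2$table$reproducibility <= 1))

  # monotonicity: appending a copy of the reference run never lowers a score
  r3 <- raicar_align(c(runs, runs[r2$reference_run]), match_threshold = 0.8)
  sc2 <- r2$table$reproducibility[order(r2$table$component)]
  sc3 <- r3$table$reproducibility[order(r3$table$component)]
  expect_true(all(sc3 >= sc2 - 1e-12))

  expect_error(raicar_align(runs[1]), "2 runs")
})

test_that("component selection keeps the top-ranked rows", {
  S <- laplace_sources(4, 300, seed = 12)
  base <- structure(list(A = diag(4), S = S, converged = TRUE),
                    class = "fc_decomposition")
  ranked <- raicar_align(list(base, base))
  all4 <- select_components(ranked, 4)
  expect_identical(all4$S, ranked$S)
  top2 <- select_components(ranked, 2)
  expect_equal(nrow(top2$S), 2L)
  expect_equal(dim(top2$A), c(4L, 2L))
  expect_error(select_components(ranked, 0), "outside")
  expect_error(select_components(ranked, 5), "outside")
})

test_that("the full decomposition recovers planted sources on a cohort", {
  g <- default_cohort(seed = 17)
  dec <- suppressWarnings(
    decompose_cohort(g$cohort, R = 5, n_select = 4, seed = 99))
  cors <- abs(stats::cor(t(dec$selected$S), t(g$truth$sources)))
  expect_true(all(apply(cors, 2, max) > 0.9))
})
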