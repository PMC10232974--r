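#' Subject-dimension PCA of the cohort stack
#'
#' Removes each edge's cohort mean (column centering), then reduces the
#' subject dimension by SVD, keeping the smallest number of components C
#' whose cumulative explained variance reaches `variance_target`. The
#' reduced feature matrix `Xprime = projector %*% X_centered` has C rows
#' (C < N) and E columns.
#'
#' Two conventions make the reduction a pure function of the *set* of
#' subjects: the SVD is computed with rows in canonical `subject_id` order
#' (so shuffling input subjects changes nothing downstream), and each
#' reduced row's sign is fixed so its largest-magnitude entry is positive.
#'
#' @param stack A `cohort_stack` with N >= 3 subjects.
#' @param variance_target Cumulative variance fraction to retain, in (0, 1].
#' @return Object of class `reduced_features`: `Xprime` (C x E),
#'   `projector` (C x N, columns in the original subject order), `center`
#'   (per-edge means), `C`, `explained_variance` (cumulative at C),
#'   `variance_fractions` (all singular-value variance shares).
#' @export
pca_reduce <- function(stack, variance_target = 0.90) {
  stopifnot(inherits(stack, "cohort_stack"))
  if (variance_target <= 0 || variance_target > 1)
    stop("pca_reduce: variance_target must be in (0, 1]")
  N <- nrow(stack$X)
  if (N < 3) stop("pca_reduce: need at least 3 subjects")
  ord <- order(stack$subject_ids)
  center <- colMeans(stack$X)
  Xc <- sweep(stack$X, 2L, center)[ord, , drop = FALSE]
  sv <- svd(Xc, nu = N, nv = 0)
  ev <- sv$d^2
  frac <- ev / sum(ev)
  cum <- cumsum(frac)
  C <- which(cum >= variance_target - 1e-12)[1]
  if (is.na(C) || ev[1] <= .Machine$double.eps)
    stop("pca_reduce: degenerate stack (no variance to retain)")
  C <- min(C, N - 1L)  # centering removes one dimension
  proj_sorted <- t(sv$u[, seq_len(C), drop = FALSE])
  Xp <- proj_sorted %*% Xc
  # sign convention: largest-|entry| of each reduced row positive
  for (r in seq_len(C)) {
    k <- which.max(abs(Xp[r, ]))
    if (Xp[r, k] < 0) {
      Xp[r, ] <- -Xp[r, ]
      proj_sorted[r, ] <- -proj_sorted[r, ]
    }
  }
  projector <- matrix(0, C, N)
  projector[, ord] <- proj_sorted
  structure(list(Xprime = Xp, projector = projector, center = center,
                 C = C, explained_variance = cum[C], variance_fractions = frac,
                 variance_target = variance_target),
            class = "reduced_features")
}

#' Infomax independent component analysis of the reduced features
#'
#' Natural-gradient Infomax with the logistic nonlinearity. The reduced
#' rows are mean-removed and PCA-whitened internally; the unmixing matrix is
#' initialized from a seeded random orthonormal matrix and updated by
#' `dW = lrate * (I + (1 - 2*g(Y)) %*% t(Y)/E) %*% W` until the update norm
#' drops below `tol` or `max_iter` is reached. On divergence the learning
#' rate is halved and the run restarts from the last stable state.
#'
#' Output conventions (all downstream thresholds are interpreted under
#' them): rows of `S` have unit variance, each row's largest-magnitude
#' entry is positive, and the affine identity `A %*% S == Xprime` holds
#' exactly (the removed row means are folded back into `S` as per-row
#' constants, which leaves correlations and variances untouched).
#'
#' @param reduced A `reduced_features` from [pca_reduce()] (C >= 2).
#' @param seed Integer seed for the initial unmixing matrix.
#' @param max_iter Maximum iterations (default 1000).
#' @param tol Convergence tolerance on the update norm (default 1e-7).
#' @param lrate Initial learning rate (default 0.1).
#' @return Object of class `fc_decomposition`: `A` (C x C mixing), `S`
#'   (C x E sources, the "ICA values"), `converged`, `iterations`,
#'   `run_seed`.
#' @export
infomax_ica <- function(reduced, seed, max_iter = 1000L, tol = 1e-7,
                        lrate = 0.1) {
  stopifnot(inherits(reduced, "reduced_features"))
  Xp <- reduced$Xprime
  C <- nrow(Xp)
  E <- ncol(Xp)
  if (C < 2) stop("infomax_ica: need C >= 2 components")
  m <- rowMeans(Xp)
  Xm <- Xp - m
  cv <- Xm %*% t(Xm) / E
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values))
    stop("infomax_ica: reduced features are rank-deficient; lower variance_target")
  Wwh <- diag(1 / sqrt(eg$values), C) %*% t(eg$vectors)
  dewh <- eg$vectors %*% diag(sqrt(eg$values), C)
  Z <- Wwh %*% Xm

  W <- withr::with_seed(seed, qr.Q(qr(matrix(stats::rnorm(C * C), C, C))))
  I <- diag(C)
  lr <- lrate
  W_good <- W
  dW_prev <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Y <- W %*% Z
    g <- 1 / (1 + exp(-Y))
    dW <- lr * (I + (1 - 2 * g) %*% t(Y) / E) %*% W
    if (!all(is.finite(dW)) || max(abs(dW)) > 1e6) {
      lr <- lr / 2          # halve on divergence, restart from stable state
      W <- W_good
      dW_prev <- NULL
      next
    }
    # anneal when the update direction turns sharply (oscillation)
    if (!is.null(dW_prev) &&
        sum(dW * dW_prev) < 0.1 * sqrt(sum(dW^2) * sum(dW_prev^2)))
      lr <- lr * 0.9
    dW_prev <- dW
    W <- W + dW
    W_good <- W
    if (max(abs(dW)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("infomax_ica: no convergence in ", max_iter,
            " iterations (final update ", format(max(abs(dW))), ")")

  S0 <- W %*% Z
  A0 <- dewh %*% solve(W)
  # fold the removed row means back: A0 %*% (S0 + c) == Xp with c = A0^-1 m
  S <- S0 + drop(solve(A0, m))
  sdr <- apply(S, 1, stats::sd)
  S <- S / sdr
  A <- A0 * rep(sdr, each = C)
  for (r in seq_len(C)) {
    k <- which.max(abs(S[r, ]))
    if (S[r, k] < 0) { S[r, ] <- -S[r, ]; A[, r] <- -A[, r] }
  }
  structure(list(A = A, S = S, converged = converged, iterations = it,
                 run_seed = seed),
            class = "fc_decomposition")
}

#' Run an ensemble of Infomax ICA decompositions
#'
#' @param reduced A `reduced_features`.
#' @param R Number of runs (reference analyses use 100; tests use ~10).
#' @param seed Master seed; per-run seeds are drawn deterministically.
#' @param ... Passed to [infomax_ica()].
#' @return List of `fc_decomposition` objects.
#' @export
run_ica_ensemble <- function(reduced, R = 100L, seed = 1L, ...) {
  seeds <- derive_seeds(seed, R)
  runs <- lapply(seeds, function(s)
    withCallingHandlers(infomax_ica(reduced, seed = s, ...),
                        warning = function(w) {
                          if (grepl("no convergence", conditionMessage(w)))
                            invokeRestart("muffleWarning")
                        }))
  n_bad <- sum(!vapply(runs, `[[`, TRUE, "converged"))
  if (n_bad > 0)
    warning("run_ica_ensemble: ", n_bad, "/", R, " runs hit max_iter before ",
            "reaching tol (flagged in each run's `converged`); components in ",
            "the near-Gaussian residual subspace converge slowly and are ",
            "down-ranked by RAICAR")
  runs
}

#' Derive a deterministic family of sub-seeds from one master seed
#' @param seed Master seed (integer).
#' @param n Number of sub-seeds.
#' @return Integer vector of length n, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

#' Align and rank components across ICA runs (modified RAICAR)
#'
#' Classic RAICAR matches components across repeated ICA runs by
#' correlation and averages the matched rows, which makes the final edge
#' values run-dependent. This modification avoids any averaging: one
#' *reference run* is chosen (the run whose components achieve the highest
#' total matched absolute correlation with all other runs, i.e. the most
#' central run), and each of its components is scored by both the number of
#' runs in which a similar component appears and how similar it is:
#'
#'   score = (match_count / (R - 1)) * mean_abs_corr
#'
#' where a run "matches" when its best-partner absolute Pearson correlation
#' over the E ICA values reaches `match_threshold`, and `mean_abs_corr`
#' averages those matched correlations (0 when nothing matches). Components
#' are ranked by descending score, ties broken by `mean_abs_corr` then by
#' component index; the representative rows are the reference run's own,
#' unaveraged.
#'
#' @param runs List of >= 2 `fc_decomposition` objects with identical C.
#' @param match_threshold Absolute correlation needed to count a run as a
#'   match (default 0.8).
#' @return Object of class `ranked_components`: `S` (C x E reference
#'   sources in rank order), `A` (C x C reference mixing, columns in rank
#'   order), `table` (data.frame: rank, component, reproducibility,
#'   match_count, mean_abs_corr), `reference_run`, `R`.
#' @export
raicar_align <- function(runs, match_threshold = 0.8) {
  R <- length(runs)
  if (R < 2) stop("raicar_align: need at least 2 runs")
  C <- nrow(runs[[1]]$S)
  for (r in runs) if (nrow(r$S) != C)
    stop("raicar_align: runs disagree on C")
  tS <- lapply(runs, function(r) t(r$S))
  abscor <- function(a, b) abs(stats::cor(tS[[a]], tS[[b]]))
  # reference = run maximizing total best-match correlation against others;
  # each unordered pair is correlated once and read from both sides
  totals <- numeric(R)
  for (a in seq_len(R - 1L)) {
    for (b in (a + 1L):R) {
      M <- abscor(a, b)
      totals[a] <- totals[a] + sum(apply(M, 1, max))
      totals[b] <- totals[b] + sum(apply(M, 2, max))
    }
  }
  ref <- which.max(totals)

  match_count <- integer(C)
  sum_corr <- numeric(C)
  for (b in seq_len(R)) {
    if (b == ref) next
    best <- apply(abscor(ref, b), 1, max)
    hit <- best >= match_threshold
    match_count <- match_count + hit
    sum_corr <- sum_corr + ifelse(hit, best, 0)
  }
  mean_abs_corr <- ifelse(match_count > 0, sum_corr / match_count, 0)
  score <- (match_count / (R - 1)) * mean_abs_corr
  # round for ranking only: last-bit correlation noise must not break the
  # deterministic tie order of equally reproducible components
  ord <- order(-round(score, 12), -round(mean_abs_corr, 12), seq_len(C))

  S <- runs[[ref]]$S[ord, , drop = FALSE]
  A <- runs[[ref]]$A[, ord, drop = FALSE]
  # representative sign convention (already applied per run, re-assert)
  for (r in seq_len(C)) {
    k <- which.max(abs(S[r, ]))
    if (S[r, k] < 0) { S[r, ] <- -S[r, ]; A[, r] <- -A[, r] }
  }
  tab <- data.frame(rank = seq_len(C), component = ord,
                    reproducibility = score[ord],
                    match_count = match_count[ord],
                    mean_abs_corr = mean_abs_corr[ord])
  structure(list(S = S, A = A, table = tab, reference_run = ref, R = R,
                 match_threshold = match_threshold),
            class = "ranked_components")
}

#' @export
print.ranked_components <- function(x, ...) {
  cat("ranked_components:", nrow(x$S), "components from", x$R,
      "ICA runs (reference run", x$reference_run, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Keep the top-n ranked components
#'
#' Reference analyses keep the first eight subnetworks; the reproducibility
#' ranking alone decides, and block connectedness is reported elsewhere as
#' a diagnostic only.
#'
#' @param ranked A `ranked_components`.
#' @param n Number of components to keep (default 8).
#' @return A `ranked_components` restricted to the first n ranks.
#' @export
select_components <- function(ranked, n = 8L) {
  stopifnot(inherits(ranked, "ranked_components"))
  C <- nrow(ranked$S)
  if (n < 1 || n > C)
    stop("select_components: n = ", n, " outside 1..C = ", C)
  out <- ranked
  out$S <- ranked$S[seq_len(n), , drop = FALSE]
  out$A <- ranked$A[, seq_len(n), drop = FALSE]
  out$table <- ranked$table[seq_len(n), , drop = FALSE]
  out
}

#' Full decomposition convenience wrapper
#'
#' PCA reduction, R seeded Infomax runs, RAICAR alignment, top-n selection.
#'
#' @param stack A `cohort_stack`.
#' @param variance_target PCA retention target (default 0.90).
#' @param R Number of ICA runs (default 100).
#' @param n_select Components to keep (default 8; capped at C).
#' @param match_threshold RAICAR match threshold (default 0.8).
#' @param seed Master seed.
#' @param ... Passed to [infomax_ica()].
#' @return List with `reduced`, `runs`, `ranked`, `selected`.
#' @export
decompose_cohort <- function(stack, variance_target = 0.90, R = 100L,
                             n_select = 8L, match_threshold = 0.8,
                             seed = 1L, ...) {
  reduced <- pca_reduce(stack, variance_target)
  runs <- run_ica_ensemble(reduced, R = R, seed = seed, ...)
  ranked <- raicar_align(runs, match_threshold = match_threshold)
  selected <- select_components(ranked, n = min(n_select, reduced$C))
  list(reduced = reduced, runs = runs, ranked = ranked, selected = selected)
}
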