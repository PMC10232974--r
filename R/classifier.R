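#' Fit the z-score scoring model
#'
#' For each selected subnetwork, stores the mean and standard deviation of
#' the method-B projections within each training group (HC and SZ). These
#' four moments per subnetwork are the only fitted quantities.
#'
#' @param projections N x m matrix (or data.frame) of method-B projection
#'   scores, one column per subnetwork (typically the SZ-specific set).
#' @param labels Factor/character of HC/SZ training labels (each group
#'   n >= 2 with nonzero variance).
#' @return Object of class `score_model`: data.frame `moments` with one
#'   row per subnetwork (`mu_hc`, `sd_hc`, `mu_sz`, `sd_sz`).
#' @export
fit_score_model <- function(projections, labels) {
  P <- as.matrix(projections)
  labels <- as.character(labels)
  if (nrow(P) != length(labels)) stop("fit_score_model: rows != labels")
  hc <- labels == "HC"; sz <- labels == "SZ"
  if (sum(hc) < 2 || sum(sz) < 2)
    stop("fit_score_model: each group needs >= 2 training subjects")
  moments <- data.frame(
    subnetwork = if (!is.null(colnames(P))) colnames(P) else
      paste0("sn", seq_len(ncol(P))),
    mu_hc = colMeans(P[hc, , drop = FALSE]),
    sd_hc = apply(P[hc, , drop = FALSE], 2, stats::sd),
    mu_sz = colMeans(P[sz, , drop = FALSE]),
    sd_sz = apply(P[sz, , drop = FALSE], 2, stats::sd),
    row.names = NULL)
  if (any(moments$sd_hc == 0) || any(moments$sd_sz == 0))
    stop("fit_score_model: zero variance in a training group")
  structure(list(moments = moments), class = "score_model")
}

#' Score subjects against the fitted model
#'
#' Each subject gets, per subnetwork, two z-scores — distance from the HC
#' and from the SZ training distributions — combined as
#' `s_i = |z_HC| - |z_SZ|`, which is positive exactly when the subject lies
#' closer (in z units) to the SZ distribution. The total score is the sum
#' over subnetworks; the predicted label is HC when the total is strictly
#' below zero and SZ otherwise.
#'
#' @param model A `score_model`.
#' @param projections N x m matrix of method-B projections (columns aligned
#'   with the model's subnetworks).
#' @return data.frame: per-subnetwork scores `s_1..s_m`, `total`,
#'   `predicted` (factor HC/SZ).
#' @export
score_subjects <- function(model, projections) {
  P <- as.matrix(projections)
  m <- nrow(model$moments)
  if (ncol(P) != m) stop("score_subjects: projection columns != model subnetworks")
  S <- sapply(seq_len(m), function(i) {
    abs((P[, i] - model$moments$mu_hc[i]) / model$moments$sd_hc[i]) -
      abs((P[, i] - model$moments$mu_sz[i]) / model$moments$sd_sz[i])
  })
  S <- matrix(S, nrow = nrow(P))
  total <- rowSums(S)
  out <- as.data.frame(S)
  names(out) <- paste0("s_", seq_len(m))
  out$total <- total
  out$predicted <- factor(ifelse(total < 0, "HC", "SZ"), levels = c("HC", "SZ"))
  rownames(out) <- rownames(P)
  out
}

#' Confusion-matrix and ranking performance metrics
#'
#' SZ is the positive class. Confusion counts use the fixed threshold 0 on
#' the total score; PPV and NPV are prevalence-adjusted from sensitivity
#' and specificity (post-test probabilities), so the prevalence must be
#' supplied explicitly; AUC is the Mann-Whitney probability that a random
#' SZ total exceeds a random HC total, ties counting one half.
#'
#' @param scores Numeric total scores (higher = more SZ-like).
#' @param labels True labels (HC/SZ), both classes present.
#' @param prevalence Assumed disease prevalence in the target population
#'   (e.g. 0.5 for a matched case-control design).
#' @return Object of class `performance_metrics`: TP, TN, FP, FN,
#'   accuracy, balanced_accuracy, precision, sensitivity, specificity,
#'   PPV, NPV, AUC, prevalence.
#' @export
evaluate_classifier <- function(scores, labels, prevalence = 0.5) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("evaluate_classifier: both classes must be present")
  pred_sz <- scores >= 0
  is_sz <- labels == "SZ"
  TP <- sum(pred_sz & is_sz); TN <- sum(!pred_sz & !is_sz)
  FP <- sum(pred_sz & !is_sz); FN <- sum(!pred_sz & is_sz)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  sz <- scores[is_sz]; hc <- scores[!is_sz]
  cmp <- outer(sz, hc, function(a, b) (a > b) + 0.5 * (a == b))
  pv <- ppv_npv(sens, spec, prevalence)
  structure(list(
    TP = TP, TN = TN, FP = FP, FN = FN,
    accuracy = (TP + TN) / length(scores),
    balanced_accuracy = (sens + spec) / 2,
    precision = if (TP + FP > 0) TP / (TP + FP) else NaN,
    sensitivity = sens, specificity = spec,
    PPV = unname(pv["PPV"]), NPV = unname(pv["NPV"]),
    AUC = mean(cmp), prevalence = prevalence),
    class = "performance_metrics")
}

#' Prevalence-adjusted predictive values
#'
#' `PPV = sens * prev / (sens * prev + (1 - spec) * (1 - prev))`;
#' `NPV = spec * (1 - prev) / ((1 - sens) * prev + spec * (1 - prev))`.
#'
#' @param sensitivity,specificity Rates in [0, 1].
#' @param prevalence Disease prevalence in [0, 1].
#' @return Named numeric vector `c(PPV=, NPV=)`.
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  c(PPV = sensitivity * prevalence /
      (sensitivity * prevalence + (1 - specificity) * (1 - prevalence)),
    NPV = specificity * (1 - prevalence) /
      ((1 - sensitivity) * prevalence + specificity * (1 - prevalence)))
}

#' ROC curve points from continuous scores
#'
#' Sweeps every distinct score as a threshold (predict SZ when
#' `score >= threshold`).
#'
#' @param scores Numeric total scores.
#' @param labels True labels (HC/SZ).
#' @return data.frame of (`fpr`, `tpr`, `threshold`) sorted for trapezoid
#'   integration; attribute `auc` holds the trapezoid area.
#' @export
roc_points <- function(scores, labels) {
  is_sz <- as.character(labels) == "SZ"
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(th, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !is_sz) / sum(!is_sz),
      tpr = sum(pred & is_sz) / sum(is_sz))
  }, numeric(2)))
  out <- data.frame(fpr = pts[, 1], tpr = pts[, 2], threshold = th)
  auc <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) + utils::tail(out$tpr, -1)) / 2)
  attr(out, "auc") <- auc
  out
}

stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- sample(which(labels == g))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of the scoring classifier
#'
#' Per repeat, subjects are partitioned into k stratified folds (seeded);
#' per fold, the score model is fitted on the training subjects only and
#' evaluated on the held-out fold — test subjects never contribute to the
#' fitted moments. (The subnetworks themselves are fixed upstream from the
#' full cohort; that residual leakage is inherent to the design and
#' documented.) Metrics are averaged over all k x repeats folds.
#'
#' @param projections N x m matrix of method-B projections.
#' @param labels True labels (HC/SZ).
#' @param k Folds (default 6).
#' @param repeats Repetitions (default 10).
#' @param seed Integer seed.
#' @param prevalence Prevalence for PPV/NPV (default 0.5).
#' @param stratified Stratify folds by group (default TRUE; the
#'   unstratified variant draws folds ignoring labels).
#' @return List: `mean` (named vector of per-metric means over folds),
#'   `folds` (data.frame of per-fold metrics), `n_folds_used`,
#'   `n_folds_skipped`.
#' @export
cross_validate <- function(projections, labels, k = 6L, repeats = 10L,
                           seed = 1L, prevalence = 0.5, stratified = TRUE) {
  P <- as.matrix(projections)
  labels <- as.character(labels)
  metric_cols <- c("accuracy", "balanced_accuracy", "precision",
                   "sensitivity", "specificity", "PPV", "NPV", "AUC")
  rows <- list()
  skipped <- 0L
  withr::with_seed(as.integer(seed), {
    for (rep in seq_len(repeats)) {
      fold <- if (stratified) stratified_folds(labels, k) else
        sample(rep_len(seq_len(k), length(labels)))
      for (f in seq_len(k)) {
        test <- fold == f
        if (length(unique(labels[test])) < 2 ||
            length(unique(labels[!test])) < 2) {
          warning("cross_validate: fold lacking a class skipped")
          skipped <- skipped + 1L
          next
        }
        model <- fit_score_model(P[!test, , drop = FALSE], labels[!test])
        sc <- score_subjects(model, P[test, , drop = FALSE])
        pm <- evaluate_classifier(sc$total, labels[test], prevalence)
        rows[[length(rows) + 1L]] <-
          data.frame(repeat_ = rep, fold = f,
                     as.list(unlist(pm[metric_cols])))
      }
    }
  })
  folds <- do.call(rbind, rows)
  names(folds) <- c("repeat_", "fold", metric_cols)
  list(mean = colMeans(folds[metric_cols], na.rm = TRUE), folds = folds,
       n_folds_used = nrow(folds), n_folds_skipped = skipped)
}
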