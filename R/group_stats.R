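#' Method-A projection: location-only subnetwork scores
#'
#' Only the *location* of a subnetwork's preserved connections is used, not
#' their ICA values. Each subject's edge vector is restricted to the mask;
#' the group mean vectors `V_HC` and `V_SZ` of those restricted vectors are
#' formed; `Diff = |V_HC - V_SZ|`; and every subject is scored by the inner
#' product of their restricted vector with `Diff`. Note the acknowledged
#' circularity: the group means are computed from the same subjects that
#' are subsequently projected.
#'
#' @param subnetwork A `subnetwork` (from [prune_components()]).
#' @param stack A `cohort_stack`.
#' @return Object of class `projection_result`: `method = "A"`, `scores`
#'   (named by subject), `diff` (the |V_HC - V_SZ| vector over retained
#'   edges), `labels`.
#' @export
project_method_A <- function(subnetwork, stack) {
  stopifnot(inherits(stack, "cohort_stack"))
  mask <- subnetwork$edge_mask
  if (!any(mask)) stop("project_method_A: empty subnetwork mask")
  if (!all(levels(stack$labels) %in% as.character(unique(stack$labels))))
    stop("project_method_A: both groups must be non-empty")
  Xm <- stack$X[, mask, drop = FALSE]
  v_hc <- colMeans(Xm[stack$labels == "HC", , drop = FALSE])
  v_sz <- colMeans(Xm[stack$labels == "SZ", , drop = FALSE])
  d <- abs(v_hc - v_sz)
  scores <- drop(Xm %*% d)
  names(scores) <- stack$subject_ids
  structure(list(method = "A", scores = scores, diff = d,
                 labels = stack$labels),
            class = "projection_result")
}

#' Method-B projection: ICA-value-weighted subnetwork scores
#'
#' Each subject's full edge vector is projected (inner product) onto the
#' subnetwork's pruned, zero-filled ICA-value vector, so the degree of
#' contribution of each retained edge matters. No group averaging is
#' involved, which makes this method more robust to within-group
#' inter-individual variation.
#'
#' @param subnetwork A `subnetwork`.
#' @param stack A `cohort_stack`.
#' @return A `projection_result` with `method = "B"`.
#' @export
project_method_B <- function(subnetwork, stack) {
  stopifnot(inherits(stack, "cohort_stack"))
  scores <- drop(stack$X %*% subnetwork$ica_values)
  names(scores) <- stack$subject_ids
  structure(list(method = "B", scores = scores, labels = stack$labels),
            class = "projection_result")
}

#' Two-sample pooled t-test with Cohen's d
#'
#' Student's t with pooled variance (groups in the reference design are
#' matched in size; Welch is available by flag). Cohen's d divides the mean
#' difference HC - SZ by the pooled standard deviation
#' `sqrt(((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2))`.
#'
#' @param scores_hc,scores_sz Numeric score vectors (each n >= 2).
#' @param alpha Significance level (default 0.005, the Bonferroni-style
#'   level used throughout the subnetwork tests).
#' @param welch Use Welch's unequal-variance t instead (default FALSE).
#' @return Object of class `stat_result`: `t`, `p` (two-sided), `cohens_d`,
#'   `significant`, `alpha`, group means and SDs.
#' @export
ttest_and_effect <- function(scores_hc, scores_sz, alpha = 0.005,
                             welch = FALSE) {
  n1 <- length(scores_hc); n2 <- length(scores_sz)
  if (n1 < 2 || n2 < 2) stop("ttest_and_effect: each group needs n >= 2")
  s1 <- stats::sd(scores_hc); s2 <- stats::sd(scores_sz)
  pooled <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (pooled == 0) {
    if (mean(scores_hc) == mean(scores_sz))
      return(structure(list(t = 0, p = 1, cohens_d = 0, significant = FALSE,
                            alpha = alpha, mean_hc = mean(scores_hc),
                            mean_sz = mean(scores_sz), sd_hc = s1, sd_sz = s2),
                       class = "stat_result"))
    stop("ttest_and_effect: zero variance in both groups with unequal means")
  }
  tt <- stats::t.test(scores_hc, scores_sz, var.equal = !welch)
  structure(list(t = unname(tt$statistic), p = tt$p.value,
                 cohens_d = (mean(scores_hc) - mean(scores_sz)) / pooled,
                 significant = tt$p.value < alpha, alpha = alpha,
                 mean_hc = mean(scores_hc), mean_sz = mean(scores_sz),
                 sd_hc = s1, sd_sz = s2),
            class = "stat_result")
}

stat_from_projection <- function(prj, alpha = 0.005, welch = FALSE) {
  ttest_and_effect(prj$scores[prj$labels == "HC"],
                   prj$scores[prj$labels == "SZ"], alpha = alpha,
                   welch = welch)
}

#' Group statistics for every subnetwork under both projection methods
#'
#' @param subnetworks A `subnetwork_set`.
#' @param stack A `cohort_stack`.
#' @param alpha Significance level (default 0.005).
#' @return data.frame with one row per subnetwork x method: `subnetwork`,
#'   `method`, `mean_hc`, `sd_hc`, `mean_sz`, `sd_sz`, `t`, `p`,
#'   `cohens_d`, `significant`. Attribute `projections` holds the raw
#'   `projection_result`s (a list of lists `A`/`B`).
#' @export
subnetwork_stats <- function(subnetworks, stack, alpha = 0.005) {
  rows <- list()
  projections <- list()
  for (s in subnetworks) {
    pa <- project_method_A(s, stack)
    pb <- project_method_B(s, stack)
    projections[[s$component]] <- list(A = pa, B = pb)
    for (prj in list(pa, pb)) {
      st <- stat_from_projection(prj, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        subnetwork = s$component, method = prj$method,
        mean_hc = st$mean_hc, sd_hc = st$sd_hc,
        mean_sz = st$mean_sz, sd_sz = st$sd_sz,
        t = st$t, p = st$p, cohens_d = st$cohens_d,
        significant = st$significant)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "projections") <- projections
  attr(out, "alpha") <- alpha
  out
}

#' Discriminant links of a subnetwork
#'
#' Edges with absolute ICA value above `ica_cut` (interpreted on the
#' unit-variance source convention, i.e. roughly a z-score scale) are
#' selected; for each, a two-sample pooled t-test compares the original
#' connectivity values between groups, and edges with `p < p_cut` are
#' returned sorted by p.
#'
#' @param subnetwork A `subnetwork`.
#' @param stack A `cohort_stack`.
#' @param ica_cut Absolute ICA-value threshold (default 3.5).
#' @param p_cut Per-edge p-value threshold (default 0.01).
#' @param rsn_map Optional node -> RSN data.frame to annotate endpoints.
#' @return data.frame: `edge`, `node_i`, `node_j`, (`rsn_i`, `rsn_j`,)
#'   `ica_value`, `t`, `p`; zero rows when nothing survives. Attribute
#'   `n_tested` counts the edges passing `ica_cut`.
#' @export
discriminant_links <- function(subnetwork, stack, ica_cut = 3.5,
                               p_cut = 0.01, rsn_map = NULL) {
  stopifnot(inherits(stack, "cohort_stack"))
  cand <- which(abs(subnetwork$ica_values) > ica_cut)
  if (!length(cand)) {
    warning("discriminant_links: no edge passes |ICA| > ", ica_cut)
    out <- data.frame(edge = integer(), node_i = character(),
                      node_j = character(), ica_value = numeric(),
                      t = numeric(), p = numeric())
    attr(out, "n_tested") <- 0L
    return(out)
  }
  hc <- stack$labels == "HC"
  res <- lapply(cand, function(e) {
    st <- ttest_and_effect(stack$X[hc, e], stack$X[!hc, e], alpha = p_cut)
    data.frame(edge = e,
               node_i = stack$node_names[stack$map$i[e]],
               node_j = stack$node_names[stack$map$j[e]],
               ica_value = subnetwork$ica_values[e], t = st$t, p = st$p)
  })
  out <- do.call(rbind, res)
  out <- out[out$p < p_cut, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  if (!is.null(rsn_map)) {
    out$rsn_i <- rsn_map$rsn[match(out$node_i, rsn_map$node_name)]
    out$rsn_j <- rsn_map$rsn[match(out$node_j, rsn_map$node_name)]
  }
  rownames(out) <- NULL
  attr(out, "n_tested") <- length(cand)
  out
}
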