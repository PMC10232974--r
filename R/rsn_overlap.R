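#' Nodal strength map of a subnetwork
#'
#' A node's strength is the sum of the absolute ICA values of its incident
#' retained edges. The normalized map divides by the maximum strength
#' (range [0, 1]); an all-equal nonzero map normalizes to all 1.
#'
#' @param subnetwork A `subnetwork`.
#' @param map The cohort's `edge_index_map`.
#' @param node_names Optional node identifiers for naming.
#' @return List of class `nodal_strength_map`: `strength` (length K),
#'   `normalized` (length K), `empty` flag.
#' @export
nodal_strength <- function(subnetwork, map, node_names = NULL) {
  w <- abs(subnetwork$ica_values)
  strength <- numeric(map$K)
  on <- w > 0
  for (e in which(on)) {
    strength[map$i[e]] <- strength[map$i[e]] + w[e]
    strength[map$j[e]] <- strength[map$j[e]] + w[e]
  }
  empty <- all(strength == 0)
  if (empty) warning("nodal_strength: empty subnetwork, all-zero map")
  normalized <- if (empty) strength else strength / max(strength)
  if (!is.null(node_names)) names(strength) <- names(normalized) <- node_names
  structure(list(strength = strength, normalized = normalized, empty = empty),
            class = "nodal_strength_map")
}

#' Overlap of a subnetwork with the seven resting-state networks
#'
#' The overlap with RSN r is the percentage of total (unnormalized) nodal
#' strength carried by nodes assigned to r, the denominator running over
#' all labeled nodes (label `"None"` — subcortex — is excluded), so the
#' seven percentages sum to 100.
#'
#' @param strength_map A `nodal_strength_map` (or a plain strength vector).
#' @param rsn_labels Character vector of per-node RSN labels (Vis, SM, DA,
#'   VA, Limb, FP, DMN, None), aligned with the node order.
#' @return Named numeric vector of 7 percentages; `NaN` with a warning when
#'   all strength sits on unlabeled nodes.
#' @export
overlap_percentage <- function(strength_map, rsn_labels) {
  s <- if (inherits(strength_map, "nodal_strength_map"))
    strength_map$strength else as.numeric(strength_map)
  if (length(s) != length(rsn_labels))
    stop("overlap_percentage: ", length(s), " strengths vs ",
         length(rsn_labels), " labels")
  labeled <- rsn_labels != "None"
  denom <- sum(s[labeled])
  out <- vapply(rsn_names(), function(r) 100 * sum(s[rsn_labels == r]) / denom,
                numeric(1))
  if (denom == 0) {
    warning("overlap_percentage: no strength on labeled nodes; overlap undefined")
    out[] <- NaN
  }
  out
}

overlap_from_positions <- function(pos, w, map, rsn_labels) {
  strength <- numeric(map$K)
  ii <- map$i[pos]; jj <- map$j[pos]
  for (k in seq_along(pos)) {
    strength[ii[k]] <- strength[ii[k]] + w[k]
    strength[jj[k]] <- strength[jj[k]] + w[k]
  }
  labeled <- rsn_labels != "None"
  denom <- sum(strength[labeled])
  if (denom == 0) return(rep(NaN, 7L))
  vapply(rsn_names(), function(r)
    100 * sum(strength[rsn_labels == r]) / denom, numeric(1))
}

#' Permutation test of RSN overlap
#'
#' Null model: the subnetwork's retained connection weights are reassigned
#' to a uniformly random set of edge positions of the same cardinality over
#' all E positions, and the overlap is recomputed; repeated `n_perm` times.
#' `p(r) = #(null overlap >= observed) / n_perm` (no +1 correction by
#' default, matching the count-divided-by-permutations definition;
#' `correct = TRUE` adds it). Relocating over all positions — rather than
#' shuffling weights within the retained mask (`mode = "within_mask"`) —
#' is the default because within-mask shuffles preserve nodal membership
#' and so cannot test anatomical specificity.
#'
#' @param subnetwork A `subnetwork`.
#' @param map The cohort's `edge_index_map`.
#' @param rsn_labels Per-node RSN labels.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param mode `"relocate"` (default) or `"within_mask"`.
#' @param correct Add the +1 small-sample correction (default FALSE).
#' @param alpha Significance level (default 0.005).
#' @return data.frame: `rsn`, `observed` (%), `p`, `significant`;
#'   attributes `n_perm`, `mode`.
#' @export
permutation_overlap_test <- function(subnetwork, map, rsn_labels,
                                     n_perm = 1000L, seed = 1L,
                                     mode = c("relocate", "within_mask"),
                                     correct = FALSE, alpha = 0.005) {
  mode <- match.arg(mode)
  if (n_perm < 1) stop("permutation_overlap_test: n_perm must be >= 1")
  pos <- which(subnetwork$edge_mask)
  w <- abs(subnetwork$ica_values[pos])
  obs <- overlap_from_positions(pos, w, map, rsn_labels)
  exceed <- integer(7L)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(n_perm)) {
      newpos <- if (mode == "relocate") sample.int(map$E, length(pos))
                else pos
      neww <- if (mode == "relocate") w else sample(w)
      ov <- overlap_from_positions(newpos, neww, map, rsn_labels)
      exceed <- exceed + (!is.nan(ov) & ov >= obs)
    }
  })
  p <- if (correct) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  out <- data.frame(rsn = rsn_names(), observed = obs, p = p,
                    significant = p < alpha, row.names = NULL)
  attr(out, "n_perm") <- n_perm
  attr(out, "mode") <- mode
  out
}

#' Overlap table for a set of subnetworks
#'
#' @param subnetworks A `subnetwork_set`.
#' @param map The cohort's `edge_index_map`.
#' @param rsn_labels Per-node RSN labels.
#' @param n_perm Permutations per subnetwork (default 1000).
#' @param seed Master seed (per-subnetwork seeds derived from it).
#' @param ... Passed to [permutation_overlap_test()].
#' @return data.frame: `subnetwork`, `rsn`, `observed`, `p`, `significant`.
#' @export
overlap_table <- function(subnetworks, map, rsn_labels, n_perm = 1000L,
                          seed = 1L, ...) {
  seeds <- derive_seeds(seed, length(subnetworks))
  rows <- lapply(seq_along(subnetworks), function(k) {
    res <- permutation_overlap_test(subnetworks[[k]], map, rsn_labels,
                                    n_perm = n_perm, seed = seeds[k], ...)
    cbind(subnetwork = subnetworks[[k]]$component, res)
  })
  do.call(rbind, rows)
}
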