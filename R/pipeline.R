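#' Full pipeline configuration
#'
#' Aggregates every stage's tunables with the reference defaults: 90% PCA
#' variance retention, 100 ICA runs, RAICAR match threshold 0.8, the first
#' 8 ranked components, pruning threshold 0.2 (relative_max), significance
#' levels 0.005 (subnetworks and overlap), 0.05 (graph metrics), 0.01
#' (per-edge links), |ICA| cut 3.5, 1000 overlap permutations, 6-fold
#' cross-validation repeated 10 times, prevalence 0.5. All stage seeds are
#' derived deterministically from one master seed.
#'
#' @param variance_target PCA retention (default 0.90).
#' @param ica_runs Number of ICA runs R (default 100).
#' @param match_threshold RAICAR match threshold (default 0.8).
#' @param n_components Components/subnetworks to keep (default 8).
#' @param prune_threshold Pruning tau (default 0.2).
#' @param prune_mode "relative_max" or "cumulative".
#' @param alpha_subnetwork,alpha_overlap,alpha_graph,alpha_links
#'   Significance levels (defaults 0.005, 0.005, 0.05, 0.01).
#' @param ica_cut Discriminant-link |ICA| threshold (default 3.5).
#' @param n_perm Overlap permutations (default 1000).
#' @param cv_k,cv_repeats Cross-validation shape (defaults 6, 10).
#' @param prevalence Prevalence for PPV/NPV (default 0.5).
#' @param seed Master seed (default 1).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(variance_target = 0.90, ica_runs = 100L,
                            match_threshold = 0.8, n_components = 8L,
                            prune_threshold = 0.2,
                            prune_mode = "relative_max",
                            alpha_subnetwork = 0.005, alpha_overlap = 0.005,
                            alpha_graph = 0.05, alpha_links = 0.01,
                            ica_cut = 3.5, n_perm = 1000L, cv_k = 6L,
                            cv_repeats = 10L, prevalence = 0.5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(variance_target > 0, variance_target <= 1,
            ica_runs >= 2, prune_threshold > 0, prune_threshold < 1,
            n_perm >= 1, cv_k >= 2, prevalence >= 0, prevalence <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full subnetwork pipeline on a cohort
#'
#' Orchestrates decomposition (PCA + repeated Infomax ICA + RAICAR),
#' pruning, group statistics under both projection methods, RSN overlap
#' with a permutation null, whole-brain and subnetwork graph metrics, and
#' the z-score classifier with repeated stratified cross-validation. The
#' classifier uses the subnetworks significant under method B at the
#' subnetwork level (the SZ-specific rule); if none is significant it falls
#' back, with a warning, to the single lowest-p method-B subnetwork.
#' Fully deterministic given the config's master seed.
#'
#' @param stack A `cohort_stack`.
#' @param rsn_labels Per-node RSN labels aligned with the stack's node
#'   order (NULL skips the overlap stage).
#' @param config A [pipeline_config()].
#' @param out_dir If non-NULL, report tables are written there as TSV plus
#'   a JSON summary.
#' @return Object of class `fc_pipeline_report`: list with `normality`,
#'   `decomposition` (reduced/ranked/selected), `subnetworks`, `stats`,
#'   `links`, `overlap`, `graph_metrics`, `graph_comparison`, `classifier`
#'   (`model`, `scores`, `insample`, `cv`, `subnetworks_used`), `config`.
#' @export
run_pipeline <- function(stack, rsn_labels = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(stack, "cohort_stack"),
            inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 3L)  # ICA ensemble, overlap, CV

  normality <- normality_screen(stack)

  dec <- decompose_cohort(stack, variance_target = config$variance_target,
                          R = config$ica_runs,
                          n_select = config$n_components,
                          match_threshold = config$match_threshold,
                          seed = seeds[1])

  subnetworks <- prune_components(
    dec$selected, pruning_config(config$prune_threshold, config$prune_mode))
  nonempty <- vapply(subnetworks, function(s) any(s$edge_mask), TRUE)
  if (!all(nonempty)) {
    warning("run_pipeline: dropping empty subnetwork(s) ",
            paste(which(!nonempty), collapse = ", "),
            " (no edge reaches the pruning threshold)")
    subnetworks <- structure(subnetworks[nonempty], class = "subnetwork_set",
                             config = attr(subnetworks, "config"),
                             contributions = attr(subnetworks, "contributions"))
  }

  stats_tab <- subnetwork_stats(subnetworks, stack,
                                alpha = config$alpha_subnetwork)

  rsn_df <- if (is.data.frame(rsn_labels)) rsn_labels else
    if (!is.null(rsn_labels))
      data.frame(node_name = stack$node_names, rsn = rsn_labels) else NULL
  links <- lapply(subnetworks, discriminant_links, stack = stack,
                  ica_cut = config$ica_cut, p_cut = config$alpha_links,
                  rsn_map = rsn_df)
  names(links) <- paste0("subnetwork_",
                         vapply(subnetworks, `[[`, 0L, "component"))

  overlap <- if (!is.null(rsn_df)) {
    labels_vec <- rsn_df$rsn[match(stack$node_names, rsn_df$node_name)]
    overlap_table(subnetworks, stack$map, labels_vec, n_perm = config$n_perm,
                  seed = seeds[2], alpha = config$alpha_overlap)
  } else NULL

  gm <- cohort_graph_metrics(stack, subnetworks)
  gcmp <- group_graph_comparison(gm, alpha = config$alpha_graph)

  # SZ-specific rule: subnetworks significant under method B
  b_rows <- stats_tab[stats_tab$method == "B", ]
  use <- b_rows$subnetwork[b_rows$significant]
  if (!length(use)) {
    warning("run_pipeline: no subnetwork significant under method B; ",
            "falling back to the lowest-p one for the classifier")
    use <- b_rows$subnetwork[which.min(b_rows$p)]
  }
  projections <- attr(stats_tab, "projections")
  P <- sapply(use, function(i) projections[[i]]$B$scores)
  P <- matrix(P, nrow = nrow(stack$X),
              dimnames = list(stack$subject_ids, paste0("sn", use)))
  model <- fit_score_model(P, stack$labels)
  sc <- score_subjects(model, P)
  insample <- evaluate_classifier(sc$total, stack$labels, config$prevalence)
  cv <- cross_validate(P, stack$labels, k = config$cv_k,
                       repeats = config$cv_repeats, seed = seeds[3],
                       prevalence = config$prevalence)

  report <- structure(list(
    normality = normality,
    decomposition = dec[c("reduced", "ranked", "selected")],
    subnetworks = subnetworks, stats = stats_tab, links = links,
    overlap = overlap, graph_metrics = gm, graph_comparison = gcmp,
    classifier = list(model = model, scores = sc, insample = insample,
                      cv = cv, subnetworks_used = use,
                      labels = stack$labels),
    config = config), class = "fc_pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.fc_pipeline_report <- function(x, ...) {
  cat("fc_pipeline_report\n")
  cat("  components kept:", nrow(x$decomposition$selected$S), "of",
      x$decomposition$ranked$R, "ICA runs\n")
  sig <- x$stats[x$stats$significant, c("subnetwork", "method", "p")]
  cat("  significant subnetworks (alpha ",
      attr(x$stats, "alpha"), "):\n", sep = "")
  if (nrow(sig)) print(sig, row.names = FALSE) else cat("    none\n")
  cat("  classifier subnetworks:", paste(x$classifier$subnetworks_used,
                                         collapse = ", "), "\n")
  cat(sprintf("  CV accuracy %.3f, balanced %.3f, AUC %.3f (%d folds)\n",
              x$classifier$cv$mean["accuracy"],
              x$classifier$cv$mean["balanced_accuracy"],
              x$classifier$cv$mean["AUC"], x$classifier$cv$n_folds_used))
  invisible(x)
}

#' Write the report tables of a pipeline run
#'
#' Emits stable TSV tables (ranking, stats, links, overlap, graph metrics
#' and comparison, subnetwork edge lists, classifier scores and ROC) plus a
#' JSON summary.
#'
#' @param report An `fc_pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$normality, "normality.tsv")
  wt(report$decomposition$ranked$table, "component_ranking.tsv")
  wt(report$stats, "subnetwork_stats.tsv")
  for (nm in names(report$links))
    if (nrow(report$links[[nm]])) wt(report$links[[nm]],
                                     paste0("links_", nm, ".tsv"))
  if (!is.null(report$overlap)) wt(report$overlap, "rsn_overlap.tsv")
  wt(report$graph_metrics, "graph_metrics_per_subject.tsv")
  wt(report$graph_comparison, "graph_comparison.tsv")
  wt(cbind(subject_id = rownames(report$classifier$scores),
           report$classifier$scores), "classifier_scores.tsv")
  roc <- roc_points(report$classifier$scores$total, report$classifier$labels)
  wt(roc, "roc_points.tsv")
  wt(report$classifier$cv$folds, "cv_folds.tsv")
  summary <- list(
    schema_version = "1.0",
    n_subjects = nrow(report$classifier$scores),
    n_components = nrow(report$decomposition$selected$S),
    retained_fraction = vapply(report$subnetworks, `[[`, 0,
                               "retained_fraction"),
    significant_A = report$stats$subnetwork[report$stats$method == "A" &
                                              report$stats$significant],
    significant_B = report$stats$subnetwork[report$stats$method == "B" &
                                              report$stats$significant],
    classifier_subnetworks = report$classifier$subnetworks_used,
    insample = unclass(report$classifier$insample),
    cv_mean = as.list(report$classifier$cv$mean),
    seed = report$config$seed)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
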