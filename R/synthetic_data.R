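#' Configuration of a synthetic two-group cohort
#'
#' Describes the generative world used throughout the test surface: a small
#' number of latent edge-space components shared across subjects, with
#' subject-specific loadings, a group mean shift on designated components'
#' loadings, additive edge noise, and clipping to the absolute-correlation
#' range `[0, 1]`.
#'
#' Loadings are Laplace-distributed (super-Gaussian), matching the logistic
#' nonlinearity assumed by Infomax ICA. Each component's active edges are
#' concentrated within a contiguous node block, so the planted subnetworks
#' are anatomically compact and overlap a known planted RSN.
#'
#' @param K Node count (default 30).
#' @param n_hc,n_sz Group sizes (default 20 each).
#' @param n_components Number of latent components (default 4).
#' @param effect_components Indices of components whose loadings shift
#'   between groups (default 1).
#' @param effect_size Loading mean shift between groups, in units of the
#'   loading SD (default 1.5).
#' @param noise_sd Additive edge noise SD (default 0.05).
#' @param sparsity Fraction of edges active per component (default 0.15).
#' @param baseline Mean edge weight added to every edge (default 0.45,
#'   a typical cortical |r|).
#' @param amplitude SD of the nonzero source values (default 0.08); with
#'   unit-SD loadings this keeps `baseline + signal + noise` mostly inside
#'   `[0, 1]` so clipping is rare.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(K = 30, n_hc = 20, n_sz = 20, n_components = 4,
                             effect_components = 1L, effect_size = 1.5,
                             noise_sd = 0.05, sparsity = 0.15,
                             baseline = 0.45, amplitude = 0.08, seed = 1L) {
  cfg <- list(K = as.integer(K), n_hc = as.integer(n_hc),
              n_sz = as.integer(n_sz), n_components = as.integer(n_components),
              effect_components = as.integer(effect_components),
              effect_size = effect_size, noise_sd = noise_sd,
              sparsity = sparsity, baseline = baseline, amplitude = amplitude,
              seed = as.integer(seed))
  if (cfg$n_components > cfg$n_hc + cfg$n_sz)
    stop("synthetic_config: n_components exceeds cohort size")
  if (cfg$sparsity <= 0 || cfg$sparsity > 1)
    stop("synthetic_config: sparsity must be in (0, 1]")
  if (length(cfg$effect_components) &&
      (min(cfg$effect_components) < 1 || max(cfg$effect_components) > cfg$n_components))
    stop("synthetic_config: effect_components out of range")
  class(cfg) <- "synthetic_config"
  cfg
}

rlaplace <- function(n, location = 0, scale = 1) {
  u <- stats::runif(n) - 0.5
  location - scale * sign(u) * log(1 - 2 * abs(u))
}

# planted node -> RSN assignment: seven contiguous blocks plus a trailing
# "None" block (~12% of nodes) standing in for subcortex
planted_rsn_map <- function(K, node_names) {
  n_none <- max(1L, round(0.12 * K))
  n_lab <- K - n_none
  rsn <- rep("None", K)
  cuts <- round(seq(0, n_lab, length.out = 8L))
  for (r in 1:7) if (cuts[r + 1] > cuts[r])
    rsn[(cuts[r] + 1):cuts[r + 1]] <- rsn_names()[r]
  data.frame(node_name = node_names, rsn = rsn, stringsAsFactors = FALSE)
}

#' Generate a synthetic two-group cohort with planted component structure
#'
#' `X = loadings %*% sources + baseline + noise`, clipped to `[0, 1]`.
#' Each source is spatially blocky: its `round(sparsity * E)` nonzero edges
#' lie within a contiguous node block, so the planted subnetwork is
#' "connected". Loadings of effect components are shifted in the SZ group by
#' `effect_size` loading SDs. Deterministic given `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return List with elements `cohort` (a `cohort_stack`) and `truth`
#'   (class `ground_truth`): `sources` (n_components x E), `loadings`
#'   (N x n_components), `rsn_map` (node -> RSN data.frame), and the config.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    K <- config$K
    map <- edge_index_map(K)
    E <- map$E
    n_active <- round(config$sparsity * E)
    if (n_active < 1) stop("generate_cohort: sparsity yields 0 active edges")
    N <- config$n_hc + config$n_sz
    node_names <- sprintf("n%03d", seq_len(K))

    # blocky sources: smallest contiguous node block holding n_active edges
    block_size <- which(choose(seq_len(K), 2) >= n_active)[1]
    if (is.na(block_size))
      stop("generate_cohort: sparsity too high for K (not enough edges in any block)")
    sources <- matrix(0, config$n_components, E)
    block_nodes <- vector("list", config$n_components)
    starts <- round(seq(1, K - block_size + 1,
                        length.out = config$n_components))
    for (c in seq_len(config$n_components)) {
      nodes <- starts[c]:(starts[c] + block_size - 1L)
      block_nodes[[c]] <- nodes
      in_block <- which(map$i %in% nodes & map$j %in% nodes)
      active <- sample(in_block, n_active)
      # half-normal magnitudes: a component modulates its member edges
      # coherently (connectivity-strength shifts are one-directional), which
      # is also what makes the location-only projection (method A) sensitive
      sources[c, active] <- abs(stats::rnorm(n_active, sd = config$amplitude))
    }

    loadings <- matrix(rlaplace(N * config$n_components, scale = 1 / sqrt(2)),
                       N, config$n_components)   # scale 1/sqrt(2) -> SD 1
    sz_rows <- (config$n_hc + 1):N
    for (c in config$effect_components)
      loadings[sz_rows, c] <- loadings[sz_rows, c] + config$effect_size

    X <- loadings %*% sources + config$baseline
    X <- X + matrix(stats::rnorm(N * E, sd = config$noise_sd), N, E)
    X <- pmin(pmax(X, 0), 1)

    labels <- c(rep("HC", config$n_hc), rep("SZ", config$n_sz))
    ids <- c(sprintf("HC%03d", seq_len(config$n_hc)),
             sprintf("SZ%03d", seq_len(config$n_sz)))
    mats <- lapply(seq_len(N), function(s)
      fc_matrix(devectorize(X[s, ], K, diag_value = 1), node_names = node_names))
    cohort <- stack_cohort(mats, labels, subject_ids = ids)

    truth <- structure(list(sources = sources, loadings = loadings,
                            block_nodes = block_nodes,
                            rsn_map = planted_rsn_map(K, node_names),
                            config = config),
                       class = "ground_truth")
    list(cohort = cohort, truth = truth)
  })
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_num_tsv <- function(m, path, col_names = NULL) {
  m <- as.matrix(m)
  ch <- matrix(fmt_num(m), nrow(m), ncol(m))
  if (!is.null(col_names)) ch <- rbind(col_names, ch)
  writeLines(apply(ch, 1, paste, collapse = "\t"), path)
  invisible(path)
}

#' Write a synthetic cohort as a plain-text fixture set
#'
#' Emits one delimited matrix file per subject (17 significant digits, so a
#' re-read reproduces the stack bit-exactly), a labels TSV, the planted
#' node-to-RSN TSV, the ground-truth loading and source tables, and a JSON
#' manifest echoing the config.
#'
#' @param cohort A `cohort_stack`.
#' @param truth Matching `ground_truth` (may be NULL to skip truth tables).
#' @param directory Output directory (created if needed).
#' @return The manifest as a list, invisibly; written to `manifest.json`.
#' @export
write_fixture_set <- function(cohort, truth, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  N <- nrow(cohort$X)
  K <- cohort$map$K
  files <- character(N)
  for (s in seq_len(N)) {
    m <- devectorize(cohort$X[s, ], K, diag_value = 1)
    files[s] <- file.path(directory, paste0(cohort$subject_ids[s], ".tsv"))
    write_num_tsv(m, files[s], col_names = cohort$node_names)
  }
  labels_path <- file.path(directory, "labels.tsv")
  utils::write.table(data.frame(subject_id = cohort$subject_ids,
                                group = as.character(cohort$labels)),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(K = K, n_subjects = N,
                   subject_files = basename(files), labels = "labels.tsv")
  if (!is.null(truth)) {
    rsn_path <- file.path(directory, "rsn_map.tsv")
    utils::write.table(truth$rsn_map, rsn_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_num_tsv(truth$loadings, file.path(directory, "truth_loadings.tsv"))
    write_num_tsv(truth$sources, file.path(directory, "truth_sources.tsv"))
    manifest$rsn_map <- "rsn_map.tsv"
    manifest$truth <- c("truth_loadings.tsv", "truth_sources.tsv")
    manifest$config <- unclass(truth$config)
  }
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a fixture directory written by [write_fixture_set()]
#' @param directory Fixture directory containing `manifest.json`.
#' @return A `cohort_stack`.
#' @export
read_cohort <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  labels <- read_labels(file.path(directory, manifest$labels))
  mats <- lapply(manifest$subject_files, function(f)
    read_fc_matrix(file.path(directory, f), expected_K = manifest$K))
  stack_cohort(mats, labels$group, subject_ids = labels$subject_id)
}
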