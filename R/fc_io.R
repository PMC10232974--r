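#' Canonical edge indexing for a K-node connectome
#'
#' Fixes the bijection between the strict lower triangle of a symmetric
#' K x K matrix and a linear edge index. The order is row-major: node i
#' ascending from 2 to K, and within each i, j ascending from 1 to i - 1.
#' Every vectorized object in the package (cohort stacks, ICA sources,
#' subnetwork masks) uses this order.
#'
#' @param K Number of nodes (parcels). Must be >= 2.
#' @return An object of class `edge_index_map` with elements `K`, `E`
#'   (`= K*(K-1)/2`), and integer vectors `i`, `j` of length `E` giving the
#'   matrix coordinates of each edge (always `i > j`).
#' @examples
#' m <- edge_index_map(4)
#' cbind(m$i, m$j)   # (2,1) (3,1) (3,2) (4,1) (4,2) (4,3)
#' @export
edge_index_map <- function(K) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop("edge_index_map: K must be an integer >= 2")
  i <- rep.int(2:K, times = 1:(K - 1L))
  j <- sequence(1:(K - 1L))
  structure(list(K = K, E = (K * (K - 1L)) %/% 2L, i = i, j = j),
            class = "edge_index_map")
}

#' Construct a validated connectivity matrix
#'
#' @param values K x K numeric matrix of Pearson correlations. Must be
#'   symmetric within `tol` (it is then symmetrized as `(M + t(M))/2`) with
#'   all entries in `[-1, 1]`.
#' @param node_names Optional character vector of K node identifiers;
#'   defaults to existing dimnames or `"n001"...`.
#' @param tol Maximum tolerated absolute asymmetry before failing.
#' @return An object of class `fc_matrix`: list with `values` and
#'   `node_names`. The diagonal is ignored by all downstream operations.
#' @export
fc_matrix <- function(values, node_names = NULL, tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("fc_matrix: matrix is not square (", nrow(values), " x ", ncol(values), ")")
  if (!is.numeric(values) || anyNA(values))
    stop("fc_matrix: matrix has non-numeric or missing entries")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop("fc_matrix: asymmetry ", format(asym), " exceeds tolerance ", format(tol))
  values <- (values + t(values)) / 2
  if (any(values < -1 | values > 1))
    stop("fc_matrix: entries outside [-1, 1] (max |r| = ",
         format(max(abs(values))), ")")
  K <- nrow(values)
  if (is.null(node_names)) {
    node_names <- rownames(values)
    if (is.null(node_names)) node_names <- sprintf("n%03d", seq_len(K))
  }
  if (length(node_names) != K)
    stop("fc_matrix: node_names length ", length(node_names), " != K = ", K)
  dimnames(values) <- list(node_names, node_names)
  structure(list(values = values, node_names = node_names), class = "fc_matrix")
}

#' Read one subject's functional connectivity matrix from a delimited file
#'
#' Accepts whitespace-, comma-, or tab-delimited numeric tables with or
#' without a header row of node names (autodetected). Validates squareness,
#' symmetry (tolerance 1e-8, then exact symmetrization) and the Pearson
#' range `[-1, 1]`.
#'
#' @param path Path to the file.
#' @param expected_K If non-NULL, fail unless the matrix is exactly this size.
#' @return An `fc_matrix`.
#' @export
read_fc_matrix <- function(path, expected_K = NULL) {
  if (!file.exists(path)) stop("read_fc_matrix: no such file: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- if (sep == ",") strsplit(first, ",")[[1]] else
    strsplit(trimws(first), "[ \t]+")[[1]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  tab <- utils::read.table(path, sep = sep, header = header,
                           check.names = FALSE, row.names = NULL)
  # a leading row-name column (non-numeric) is dropped
  if (ncol(tab) > 0 && !is.numeric(tab[[1]]) && all(vapply(tab[-1], is.numeric, TRUE)))
    tab <- tab[-1]
  if (!all(vapply(tab, is.numeric, TRUE)))
    stop("read_fc_matrix: non-numeric entries in ", path)
  m <- as.matrix(tab)
  rownames(m) <- NULL
  if (!is.null(expected_K) && (nrow(m) != expected_K || ncol(m) != expected_K))
    stop("read_fc_matrix: expected ", expected_K, " x ", expected_K,
         ", found ", nrow(m), " x ", ncol(m), " in ", path)
  nn <- if (header) colnames(m) else NULL
  fc_matrix(m, node_names = nn)
}

#' Vectorize the lower triangle of a connectivity matrix
#'
#' Returns the absolute values of the strict lower triangle in the canonical
#' [edge_index_map()] order. Absolute values encode connection strength
#' regardless of correlation sign; all downstream modules see weights in
#' `[0, 1]`.
#'
#' @param m An `fc_matrix` or a plain symmetric matrix.
#' @param map Optional precomputed `edge_index_map`.
#' @return Numeric vector of length `K*(K-1)/2`.
#' @export
vectorize_lower <- function(m, map = NULL) {
  v <- if (inherits(m, "fc_matrix")) m$values else as.matrix(m)
  if (is.null(map)) map <- edge_index_map(nrow(v))
  abs(v[cbind(map$i, map$j)])
}

#' Rebuild a symmetric matrix from a canonical edge vector
#'
#' Inverse of [vectorize_lower()] up to the absolute value: off-diagonal
#' entries are filled symmetrically, the diagonal with `diag_value`.
#'
#' @param v Edge vector of length `K*(K-1)/2`.
#' @param K Node count.
#' @param diag_value Value placed on the diagonal (default 0; downstream
#'   graph code requires 0).
#' @return K x K symmetric numeric matrix.
#' @export
devectorize <- function(v, K, diag_value = 0) {
  map <- edge_index_map(K)
  if (length(v) != map$E)
    stop("devectorize: length(v) = ", length(v), " but E = ", map$E, " for K = ", K)
  m <- matrix(diag_value, K, K)
  m[cbind(map$i, map$j)] <- v
  m[cbind(map$j, map$i)] <- v
  m
}

#' Stack a cohort of connectivity matrices into an N x E feature matrix
#'
#' Row `s` of `X` is `vectorize_lower(matrices[[s]])`; entries are absolute
#' correlations in `[0, 1]`.
#'
#' @param matrices List of `fc_matrix` objects sharing K and node names.
#' @param labels Character or factor of group labels, one per subject, with
#'   values in `{"HC","SZ"}`.
#' @param subject_ids Optional character ids; default `"s001"...`.
#' @return Object of class `cohort_stack`: list with `X` (N x E), `labels`
#'   (factor HC/SZ), `subject_ids`, `node_names`, and the `edge_index_map`
#'   as `map`.
#' @export
stack_cohort <- function(matrices, labels, subject_ids = NULL) {
  N <- length(matrices)
  if (N < 1L) stop("stack_cohort: empty cohort")
  if (length(labels) != N)
    stop("stack_cohort: ", length(labels), " labels for ", N, " matrices")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("HC", "SZ"))
  if (length(bad)) stop("stack_cohort: unknown group label(s): ",
                        paste(bad, collapse = ", "))
  K <- nrow(matrices[[1]]$values)
  nn <- matrices[[1]]$node_names
  for (s in seq_len(N)) {
    if (!inherits(matrices[[s]], "fc_matrix"))
      stop("stack_cohort: element ", s, " is not an fc_matrix")
    if (nrow(matrices[[s]]$values) != K)
      stop("stack_cohort: matrix ", s, " has K = ", nrow(matrices[[s]]$values),
           ", expected ", K)
  }
  map <- edge_index_map(K)
  X <- t(vapply(matrices, vectorize_lower, numeric(map$E), map = map))
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(N))
  rownames(X) <- subject_ids
  colnames(X) <- paste(nn[map$i], nn[map$j], sep = "|")
  structure(list(X = X, labels = factor(labels, levels = c("HC", "SZ")),
                 subject_ids = subject_ids, node_names = nn, map = map),
            class = "cohort_stack")
}

#' @export
print.cohort_stack <- function(x, ...) {
  cat("cohort_stack:", nrow(x$X), "subjects (",
      sum(x$labels == "HC"), "HC /", sum(x$labels == "SZ"), "SZ ),",
      x$map$K, "nodes,", x$map$E, "edges\n")
  invisible(x)
}

#' Shapiro-Wilk normality screen of the cohort stack
#'
#' Applies the Shapiro-Wilk test to each subject's vectorized edge values.
#' This is a descriptive report and never blocks the pipeline. Rows with
#' zero variance are flagged untestable. The Shapiro-Wilk implementation is
#' limited to 5000 observations, so for E > 5000 a deterministic
#' evenly-spaced subsample of 5000 edges is used (noted in the result).
#'
#' @param stack A `cohort_stack`.
#' @return A data.frame with one row per subject: `subject_id`, `W`, `p`,
#'   `untestable`; attribute `min_p` holds the minimum p over testable rows.
#' @export
normality_screen <- function(stack) {
  stopifnot(inherits(stack, "cohort_stack"))
  X <- stack$X
  E <- ncol(X)
  idx <- if (E > 5000L) unique(round(seq(1L, E, length.out = 5000L))) else seq_len(E)
  res <- lapply(seq_len(nrow(X)), function(s) {
    v <- X[s, idx]
    if (stats::sd(v) == 0)
      return(data.frame(subject_id = stack$subject_ids[s], W = NA_real_,
                        p = NA_real_, untestable = TRUE))
    sw <- stats::shapiro.test(v)
    data.frame(subject_id = stack$subject_ids[s], W = unname(sw$statistic),
               p = sw$p.value, untestable = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "min_p") <- if (all(out$untestable)) NA_real_ else
    min(out$p, na.rm = TRUE)
  attr(out, "subsampled") <- E > 5000L
  out
}

#' Read a two-column subject label table (subject_id, group)
#' @param path TSV path; group must be HC or SZ.
#' @return data.frame with columns `subject_id`, `group`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("subject_id", "group") %in% names(tab)))
    stop("read_labels: need columns subject_id, group in ", path)
  bad <- setdiff(unique(tab$group), c("HC", "SZ"))
  if (length(bad)) stop("read_labels: unknown group(s): ", paste(bad, collapse = ", "))
  tab
}

#' Read a node-to-RSN assignment table (node_name, rsn)
#'
#' RSN labels follow the seven-network convention: Vis, SM, DA, VA, Limb,
#' FP, DMN, plus "None" for unassigned (subcortical) nodes.
#'
#' @param path TSV path.
#' @return data.frame with columns `node_name`, `rsn`.
#' @export
read_rsn_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("node_name", "rsn") %in% names(tab)))
    stop("read_rsn_map: need columns node_name, rsn in ", path)
  bad <- setdiff(unique(tab$rsn), c(rsn_names(), "None"))
  if (length(bad)) stop("read_rsn_map: unknown RSN label(s): ",
                        paste(bad, collapse = ", "))
  tab
}

#' The seven canonical resting-state network labels
#' @return Character vector of length 7.
#' @export
rsn_names <- function() c("Vis", "SM", "DA", "VA", "Limb", "FP", "DMN")

#' Write a cohort stack as TSV (edges as columns named "node_i|node_j")
#' @param stack A `cohort_stack`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_stack_tsv <- function(stack, path) {
  df <- data.frame(subject_id = stack$subject_ids, group = stack$labels,
                   stack$X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
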