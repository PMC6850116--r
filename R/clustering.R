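# Multi-tissue MAF similarity: square-root transform, Euclidean
# distances, agglomerative clustering, Newick export.

#' Assemble a samples-by-assay MAF matrix
#'
#' Pivots long per-sample MAF records into a numeric matrix whose rows are
#' samples (individual + tissue) and whose columns are assays/variants,
#' applying a missing-value policy first: `drop_feature` (default)
#' removes any column containing a missing value, `drop_sample` removes
#' rows with any missing value, `pairwise` keeps missing cells for a
#' downstream pairwise-complete distance.
#'
#' @param samples data frame with identifier, feature and value columns.
#' @param row,col,value tidy-select column names for the row identifier,
#'   the feature/assay, and the MAF (fraction or percent, used as given).
#' @param na_policy `"drop_feature"`, `"drop_sample"`, or `"pairwise"`.
#' @return numeric matrix with row/column names; attribute `missing_cells`
#'   records which (row, col) cells were missing before the policy.
#' @examples
#' load_cohort_fixture("table3_tissues") |>
#'   dplyr::mutate(sample = paste(family_id, member_role, tissue)) |>
#'   build_maf_matrix(row = sample, col = family_id, value = maf_pct)
#' @export
build_maf_matrix <- function(samples, row, col, value,
                             na_policy = c("drop_feature", "drop_sample",
                                           "pairwise")) {
  na_policy <- match.arg(na_policy)
  stopifnot(is.data.frame(samples))
  if (nrow(samples) < 2) {
    abort("Need at least 2 samples.", class = "ddmosaic_clustering_error")
  }
  long <- dplyr::transmute(samples,
                           .row = as.character({{ row }}),
                           .col = as.character({{ col }}),
                           .val = as.numeric({{ value }}))
  if (any(long$.val < 0, na.rm = TRUE)) {
    abort("MAF values must be non-negative.",
          class = "ddmosaic_clustering_error")
  }
  wide <- tidyr::pivot_wider(long, names_from = ".col",
                             values_from = ".val",
                             values_fn = function(x) x[1])
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$.row
  miss <- which(is.na(m), arr.ind = TRUE)
  missing_cells <- tibble(row = rownames(m)[miss[, 1]],
                          col = colnames(m)[miss[, 2]])
  if (na_policy == "drop_feature") {
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
  } else if (na_policy == "drop_sample") {
    m <- m[rowSums(is.na(m)) == 0, , drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 1) {
    abort("Fewer than 2 complete rows remain after the missing-value policy.",
          class = "ddmosaic_clustering_error")
  }
  attr(m, "missing_cells") <- missing_cells
  attr(m, "na_policy") <- na_policy
  m
}

#' Euclidean distances on square-root-transformed MAFs
#'
#' `d(i, j) = sqrt(sum_f (sqrt(m_if) - sqrt(m_jf))^2)`. The square-root
#' transform is variance-stabilising for binomial fractions and tempers
#' the dominance of high-MAF samples. Applied to values as given
#' (fractions in `[0, 1]` by convention; the transform is monotone on
#' either scale).
#'
#' @param m numeric matrix from [build_maf_matrix()]; no missing values
#'   unless it was built with `na_policy = "pairwise"`, in which case
#'   pairwise-complete features are used per pair.
#' @return a `dist` object (symmetric, zero diagonal).
#' @export
sqrt_euclidean_distances <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m < 0, na.rm = TRUE)) {
    abort("Negative MAF.", class = "ddmosaic_domain_error")
  }
  dist(sqrt(m), method = "euclidean")
}

#' Agglomerative clustering of a MAF distance matrix
#'
#' Standard agglomerative merging on a precomputed distance matrix.
#' Average (UPGMA) linkage is the default; ties are broken
#' deterministically by ordering leaves lexicographically before merging,
#' so permuting input rows cannot change the tree.
#'
#' @param d a `dist` object or symmetric matrix with zero diagonal.
#' @param linkage `"average"`, `"complete"`, or `"single"`.
#' @return an `hclust` tree.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete",
                                                "single")) {
  linkage <- match.arg(linkage)
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      abort("Distance matrix must be symmetric with zero diagonal.",
            class = "ddmosaic_domain_error")
    }
    d <- as.dist(d)
  }
  if (!inherits(d, "dist")) {
    abort("`d` must be a dist object or symmetric matrix.",
          class = "ddmosaic_domain_error")
  }
  if (attr(d, "Size") < 2) {
    abort("Need at least 2 rows to cluster.",
          class = "ddmosaic_domain_error")
  }
  labs <- attr(d, "Labels") %||% as.character(seq_len(attr(d, "Size")))
  # Deterministic tie-break: present rows to hclust in lexicographic
  # label order.
  ord <- order(labs)
  dm <- as.matrix(d)[ord, ord]
  hclust(as.dist(dm), method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths place each leaf at depth `height / 2` of its merge, so
#' average-linkage trees export as ultrametric Newick. Round-trips through
#' standard Newick parsers.
#'
#' @param t an `hclust` tree with at least 2 leaves.
#' @return single Newick string (terminated with `;`).
#' @examples
#' m <- matrix(c(0, 0.16, 0.16, 0), 2, dimnames = list(c("A", "B"), NULL))
#' h <- hierarchical_cluster(as.dist(m))
#' dendrogram_to_newick(h)
#' @export
dendrogram_to_newick <- function(t) {
  if (!inherits(t, "hclust")) {
    abort("`t` must be an hclust tree.", class = "ddmosaic_domain_error")
  }
  if (length(t$labels %||% t$order) < 2) {
    abort("Newick export needs at least 2 leaves.",
          class = "ddmosaic_domain_error")
  }
  phy <- ape::as.phylo(t)
  ape::write.tree(phy)
}
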