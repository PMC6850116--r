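# Multi-tissue MAF clustering and Newick export.

tissue_matrix <- function(na_policy = "drop_feature") {
  load_cohort_fixture("table3_tissues") |>
    dplyr::mutate(sample_id = paste(family_id, member_role, tissue,
                                    sep = ":"),
                  feature = "maf",
                  maf = pct_to_frac(maf_pct)) |>
    build_maf_matrix(row = sample_id, col = feature, value = maf,
                     na_policy = na_policy)
}

test_that("matrix assembly applies the missing-value policies", {
  simple <- tibble::tibble(sample = c("a", "b"), feature = "f",
                           maf = c(0.1, 0.2))
  m <- build_maf_matrix(simple, sample, feature, maf)
  expect_equal(dim(m), c(2L, 1L))
  expect_equal(unname(m[, 1]), c(0.1, 0.2))

  # drop_sample removes the incomplete row, drop_feature the column
  with_na <- tibble::tibble(
    sample = rep(c("a", "b", "c"), each = 2),
    feature = rep(c("f1", "f2"), 3),
    maf = c(0.1, 0.2, 0.3, NA, 0.5, 0.6))
  ms <- build_maf_matrix(with_na, sample, feature, maf,
                         na_policy = "drop_sample")
  expect_equal(rownames(ms), c("a", "c"))
  mf <- build_maf_matrix(with_na, sample, feature, maf,
                         na_policy = "drop_feature")
  expect_equal(colnames(mf), "f1")
  expect_equal(nrow(dplyr::filter(attr(mf, "missing_cells"), row == "b")), 1)

  # tissue fixture: NA rows drop, remaining values equal the printed ones
  m3 <- tissue_matrix(na_policy = "drop_sample")
  expect_false(anyNA(m3))
  expect_equal(unname(m3["A112:father:sperm", 1]), 0.3303)
  expect_false("A052:father:sperm" %in% rownames(m3))

  expect_error(build_maf_matrix(simple[1, ], sample, feature, maf),
               class = "ddmosaic_clustering_error")
})

test_that("sqrt-Euclidean distances obey the metric axioms", {
  # hand-computed single-feature case
  m <- matrix(c(0.25, 0.04), 2, dimnames = list(c("r1", "r2"), "f"))
  expect_equal(as.numeric(sqrt_euclidean_distances(m)), 0.3)
  # identical rows at distance zero
  m2 <- matrix(c(0.1, 0.1, 0.3, 0.3), 2, dimnames = list(c("a", "b"), NULL))
  expect_equal(as.numeric(sqrt_euclidean_distances(m2)), 0)

  m3 <- tissue_matrix(na_policy = "drop_sample")
  d <- as.matrix(sqrt_euclidean_distances(m3))
  # per-pair brute-force recomputation
  for (i in seq_len(nrow(m3))) {
    for (j in seq_len(nrow(m3))) {
      expect_equal(d[i, j],
                   sqrt(sum((sqrt(m3[i, ]) - sqrt(m3[j, ]))^2)),
                   tolerance = 1e-12)
    }
  }
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  # triangle inequality
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      expect_true(all(d[i, j] <= d[i, ] + d[, j] + 1e-12))
    }
  }
  expect_error(sqrt_euclidean_distances(matrix(-0.1)),
               class = "ddmosaic_domain_error")
})

test_that("agglomerative merges follow the distances", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), NULL))
  h <- hierarchical_cluster(as.dist(two))
  expect_equal(h$height, 0.4)

  three <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
                  dimnames = list(c("A", "B", "C"), NULL))
  h3 <- hierarchical_cluster(as.dist(three))
  # first merge joins the close pair {A, B}
  first <- sort(h3$labels[-h3$merge[1, ]])
  expect_equal(first, c("A", "B"))
  expect_equal(h3$height[1], 1)

  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2)),
               class = "ddmosaic_domain_error")
})

test_that("mosaic and control samples separate into pure subtrees", {
  cohort <- simulate_cohort(
    c(replicate(4, family_scenario("parental_somatic_mosaic",
                                   parent_maf = 0.08), simplify = FALSE),
      replicate(4, family_scenario("de_novo"), simplify = FALSE)),
    assay_params = list(n_droplets = 30000L, sd_between = 0, sd_within = 0),
    seed = 51)
  samples <- purrr::map_dfr(cohort, "samples") |>
    dplyr::filter(member_role %in% c("father", "mother"),
                  tissue == "blood") |>
    estimate_maf() |>
    dplyr::mutate(sample_id = paste(family_id, member_role, sep = ":"),
                  feature = "maf",
                  group = ifelse(true_maf >= 0.05, "mosaic", "clean"))
  m <- build_maf_matrix(samples, sample_id, feature, maf)
  h <- hierarchical_cluster(sqrt_euclidean_distances(m))
  k2 <- stats::cutree(h, 2)
  grp <- samples$group[match(names(k2), samples$sample_id)]
  expect_equal(length(unique(k2[grp == "mosaic"])), 1)
  expect_equal(length(unique(k2[grp == "clean"])), 1)
  expect_false(unique(k2[grp == "mosaic"]) == unique(k2[grp == "clean"]))
})

test_that("row order never changes the tree", {
  m <- tissue_matrix(na_policy = "drop_sample")
  d1 <- sqrt_euclidean_distances(m)
  perm <- withr::with_seed(52, sample.int(nrow(m)))
  d2 <- sqrt_euclidean_distances(m[perm, , drop = FALSE])
  h1 <- hierarchical_cluster(d1)
  h2 <- hierarchical_cluster(d2)
  expect_equal(h1$height, h2$height)
  expect_equal(dendrogram_to_newick(h1), dendrogram_to_newick(h2))
})

test_that("merge heights are monotone under average and complete linkage", {
  m <- tissue_matrix(na_policy = "drop_sample")
  d <- sqrt_euclidean_distances(m)
  for (lk in c("average", "complete")) {
    h <- hierarchical_cluster(d, linkage = lk)
    expect_true(all(diff(h$height) >= -1e-12))
  }
})

test_that("Newick export is ultrametric and round-trips", {
  two <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), NULL))
  nwk <- dendrogram_to_newick(hierarchical_cluster(as.dist(two)))
  expect_equal(nwk, "(A:0.2,B:0.2);")

  # random 8-leaf tree: parse back and compare topology + depths
  pts <- withr::with_seed(53, matrix(runif(16), 8,
                                     dimnames = list(paste0("L", 1:8), NULL)))
  h <- hierarchical_cluster(sqrt_euclidean_distances(pts))
  phy <- ape::read.tree(text = dendrogram_to_newick(h))
  expect_setequal(phy$tip.label, paste0("L", 1:8))
  depths <- ape::node.depth.edgelength(phy)[seq_len(8)]
  # ultrametric: every leaf sits at half the root merge height
  expect_equal(unname(depths), rep(max(h$height) / 2, 8), tolerance = 1e-9)
  expect_equal(ape::Ntip(phy), 8)
  # topology preserved: cophenetic distances match the merge structure
  coph_h <- stats::cophenetic(h)
  coph_p <- ape::cophenetic.phylo(phy)
  expect_equal(as.matrix(coph_h)[rownames(coph_p), colnames(coph_p)],
               coph_p, tolerance = 1e-9)

  expect_error(dendrogram_to_newick("not a tree"),
               class = "ddmosaic_domain_error")
})
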