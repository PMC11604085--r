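test_that("neighbourhood features encode composition, shape and spread", {
  # 4 cells on a unit square, fully connected within 3 steps
  sq <- data.frame(cell_id = letters[1:4],
                   x_um = c(0, 1, 1, 0), y_um = c(0, 0, 1, 1))
  g <- build_spatial_graph(sq, prune_percentile = 100)
  ft <- neighbourhood_features(g, labels = c("A", "A", "B", "B"), l = 3)
  expect_equal(unname(ft[, "comp_A"]), rep(0.5, 4))
  expect_equal(unname(ft[, "hull_area_um2"]), rep(1, 4))
  expect_equal(unname(ft[, "dist_mean_um"]), rep(sqrt(2) / 2, 4))
  expect_equal(unname(ft[, "dist_sd_um"]), rep(0, 4))
  # circularity of a square: 4*pi*A/P^2 = pi/4
  expect_equal(unname(ft[, "circularity"]), rep(pi / 4, 4))
  # single-population neighbourhood has composition coordinate 1
  ft2 <- neighbourhood_features(g, labels = rep("A", 4))
  expect_equal(unname(ft2[, "comp_A"]), rep(1, 4))
  # compositions always sum to 1 on a realistic ROI
  sm <- small_cohort()
  roi <- as.data.frame(sm$cells)[sm$cells$roi_id == sm$cells$roi_id[1], ]
  gr <- build_spatial_graph(roi)
  ftr <- neighbourhood_features(gr, roi$population_label)
  comp <- ftr[, startsWith(colnames(ftr), "comp_"), drop = FALSE]
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
  expect_true(all(is.finite(ftr)))
  # tiny neighbourhoods degrade to hull 0, circularity 1
  iso <- build_spatial_graph(data.frame(cell_id = c("u", "v"),
                                        x_um = c(0, 3), y_um = c(0, 0)))
  fti <- neighbourhood_features(iso, c("A", "A"))
  expect_equal(unname(fti[, "hull_area_um2"]), c(0, 0))
  expect_equal(unname(fti[, "circularity"]), c(1, 1))
})

test_that("Fowlkes-Mallows index matches pair enumeration", {
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c("x", "y", "x", "y")), 0)
  # {123|4} vs {12|34}: TP = 1 (pair 12), FP = 2 (13, 23), FN = 1 (34)
  # -> 1 / sqrt((1+2) * (1+1)) = 1/sqrt(6), confirmed by the oracle below
  expect_equal(fowlkes_mallows(c(1, 1, 1, 2), c(1, 1, 2, 2)), 1 / sqrt(6))
  expect_equal(fmi_oracle(c(1, 1, 1, 2), c(1, 1, 2, 2)), 1 / sqrt(6))
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:3, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    expect_equal(fowlkes_mallows(a, b), fmi_oracle(a, b))
    expect_equal(fowlkes_mallows(a, b), fowlkes_mallows(b, a))
  }
  # identical up to relabelling -> 1
  a <- sample(1:3, 12, replace = TRUE)
  expect_equal(fowlkes_mallows(a, c(9, 7, 8)[a]), 1)
  expect_error(fowlkes_mallows(1, 1), "fewer than 2")
  expect_error(fowlkes_mallows(1:3, 1:2), "same items")
})

test_that("stability-selected GMM recovers a planted mosaic", {
  mz <- plant_neighbourhood_mosaic(3, mosaic_compositions(3),
                                   min_centre_sep_um = 400, seed = 3)
  g <- build_spatial_graph(mz$cells)
  ft <- neighbourhood_features(g, mz$cells$population_label)
  m <- cluster_neighbourhoods(ft, K_range = 2:5, n_repeats = 10, seed = 3)
  expect_equal(m$K, 3)
  expect_gte(mclust::adjustedRandIndex(m$nbhd_label, mz$truth$domain), 0.8)
  # determinism
  m2 <- cluster_neighbourhoods(ft, K_range = 2:5, n_repeats = 10, seed = 3)
  expect_identical(m$nbhd_label, m2$nbhd_label)
  expect_identical(m$stability_by_K, m2$stability_by_K)
  # K = 1 is trivially stable
  m1 <- cluster_neighbourhoods(ft[1:50, ], K_range = 1, n_repeats = 3, seed = 1)
  expect_equal(m1$K, 1)
  expect_true(all(m1$nbhd_label == 1))
  expect_warning(cluster_neighbourhoods(ft[1:5, ], K_range = c(2, 10),
                                        n_repeats = 3, seed = 1), "skipped")
})

test_that("cluster annotation computes enrichment fold changes", {
  # 2 clusters, hand-computed FCs
  nbhd <- c(1, 1, 1, 1, 2, 2, 2, 2)
  pop <- c("S", "S", "S", "T", "S", "T", "T", "T")
  hier <- c("neoplastic", "neoplastic", "neoplastic", "myeloid",
            "neoplastic", "myeloid", "myeloid", "myeloid")[match(pop, c("S", "T", "S", "T", "S", "T", "S", "T"))]
  hier <- ifelse(pop == "S", "neoplastic", "myeloid")
  ann <- annotate_neighbourhood_clusters(nbhd, pop, hier)
  # overall: S 4/8, T 4/8; cluster 1: S 3/4 -> FC 1.5, T 1/4 -> FC 0.5
  expect_equal(unname(ann$fc["1", c("S", "T")]), c(1.5, 0.5))
  expect_equal(unname(ann$fc["2", c("S", "T")]), c(0.5, 1.5))
  expect_equal(unname(ann$category), c("tumour_enriched", "immune_enriched"))
  expect_false(any(ann$proliferative))
  # cluster matching the global composition has all FC = 1
  ann2 <- annotate_neighbourhood_clusters(rep(1, 8), pop, hier)
  expect_true(all(ann2$fc == 1))
  # pure Schwann cluster: tumour-enriched, non-proliferative
  ann3 <- annotate_neighbourhood_clusters(c(1, 1, 2, 2),
                                          c("Schwann", "Schwann", "TAM", "Ki67"),
                                          c("neoplastic", "neoplastic",
                                            "myeloid", "proliferative"))
  expect_equal(unname(ann3$category["1"]), "tumour_enriched")
  expect_false(ann3$proliferative[["1"]])
  expect_true(ann3$proliferative[["2"]])
})

test_that("observed/expected proximity is calibrated", {
  set.seed(13)
  pts <- data.frame(cell_id = paste0("c", 1:600),
                    x_um = runif(600, 0, 800), y_um = runif(600, 0, 800))
  g <- build_spatial_graph(pts)
  expect_gte(nrow(g$edges), 500)
  # random balanced labels: O/E ~ 1 everywhere
  lab <- rep(1:2, 300)
  pr <- neighbourhood_proximity(list(g), list(lab), n_perm = 1000, seed = 5)
  expect_true(all(abs(pr$oe - 1) < 0.1))
  expect_equal(pr$oe, t(pr$oe))
  # single label: O/E = 1 exactly (the permutation cannot change anything)
  pr1 <- neighbourhood_proximity(list(g), list(rep(1, 600)), n_perm = 50,
                                 seed = 1)
  expect_equal(unname(pr1$oe[1, 1]), 1)
})

test_that("proximity matches exhaustive permutation on a 6-node graph", {
  # two triangles joined by one bridge edge
  pts <- data.frame(cell_id = paste0("n", 1:6),
                    x_um = c(0, 10, 5, 40, 50, 45),
                    y_um = c(0, 0, 8, 0, 0, 8))
  g <- build_spatial_graph(pts, prune_percentile = 100)
  lab <- c(1, 1, 1, 2, 2, 2)
  pr <- neighbourhood_proximity(list(g), list(lab), n_perm = 4000, seed = 7)
  # exhaustive oracle over all 720 label orderings
  perms <- all_perms(lab)
  acc <- matrix(0, 2, 2)
  for (p in perms) {
    for (e in seq_len(nrow(g$edges))) {
      a <- p[g$edges$i[e]]; b <- p[g$edges$j[e]]
      acc[a, b] <- acc[a, b] + 1
      if (a != b) acc[b, a] <- acc[b, a] + 1
    }
  }
  expected <- acc / length(perms)
  obs <- matrix(0, 2, 2)
  for (e in seq_len(nrow(g$edges))) {
    a <- lab[g$edges$i[e]]; b <- lab[g$edges$j[e]]
    obs[a, b] <- obs[a, b] + 1
    if (a != b) obs[b, a] <- obs[b, a] + 1
  }
  oe_oracle <- obs / expected
  expect_equal(unname(pr$oe), unname(oe_oracle), tolerance = 0.05)
})

test_that("disconnected label blocks yield zero cross-proximity", {
  pts <- data.frame(cell_id = paste0("n", 1:8),
                    x_um = c(1, 2, 1, 2, 100, 101, 100, 101),
                    y_um = c(1, 1, 2, 2, 1, 1, 2, 2))
  g <- build_spatial_graph(pts, prune_percentile = 60)  # prune bridge edges
  lab <- rep(1:2, each = 4)
  # confirm no cross-block edge survives pruning
  cross <- (lab[g$edges$i] != lab[g$edges$j])
  expect_false(any(cross))
  pr <- neighbourhood_proximity(list(g), list(lab), n_perm = 200, seed = 2)
  expect_equal(unname(pr$oe[1, 2]), 0)
})

test_that("group comparison uses per-case proportions that sum to one", {
  sm <- small_cohort()
  set.seed(14)
  nbhd <- sample(1:3, nrow(sm$cells), replace = TRUE)
  cmp <- suppressWarnings(
    neighbourhood_group_comparison(nbhd, sm$cells$case_id, sm$metadata))
  expect_true(all(abs(rowSums(cmp$proportions) - 1) < 1e-9))
  # random labels: nothing significant at 0.01
  expect_true(all(cmp$per_cluster$p > 0.01))
})
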