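test_that("kNN expression graphs are symmetrised unions of neighbour lists", {
  x <- matrix(c(0, 0, 1, 0, 10, 0), ncol = 2, byrow = TRUE)
  g <- build_expression_graph(x, k_neighbours = 1)
  el <- igraph::as_edgelist(g)
  # points 1 and 2 are mutual nearest; 3's nearest is 2 -> union keeps both
  expect_true(igraph::are_adjacent(g, 1, 2))
  expect_true(igraph::are_adjacent(g, 2, 3))
  # duplicate points allowed (zero-distance edges)
  g2 <- build_expression_graph(rbind(x, x[1, ]), k_neighbours = 1)
  expect_equal(igraph::vcount(g2), 4)
  expect_warning(build_expression_graph(x, k_neighbours = 5), "k reduced")
})

test_that("every vertex keeps at least k neighbours after the union", {
  set.seed(6)
  x <- matrix(rnorm(200), ncol = 4)
  k <- 7
  g <- build_expression_graph(x, k_neighbours = k)
  expect_true(all(igraph::degree(g) >= k))
  # brute-force kNN: each point's k nearest are adjacent
  d <- as.matrix(dist(x)); diag(d) <- Inf
  for (i in seq_len(nrow(x))) {
    nn <- order(d[i, ])[seq_len(k)]
    expect_true(all(vapply(nn, function(j) igraph::are_adjacent(g, i, j),
                           logical(1))))
  }
})

test_that("leiden clustering separates well-separated blobs deterministically", {
  set.seed(8)
  x <- rbind(matrix(rnorm(400, 0, 1), ncol = 2),
             matrix(rnorm(400, 30, 1), ncol = 2))
  g <- build_expression_graph(x, k_neighbours = 10)
  cl <- leiden_cluster(g, resolution = 0.05, seed = 4)
  expect_equal(length(unique(cl)), 2)
  truth <- rep(1:2, each = 200)
  expect_equal(mclust::adjustedRandIndex(cl, truth), 1)
  expect_identical(cl, leiden_cluster(g, resolution = 0.05, seed = 4))
  # partition modularity beats the all-singletons partition
  expect_gte(igraph::modularity(g, cl),
             igraph::modularity(g, seq_len(igraph::vcount(g))))
  expect_identical(leiden_cluster(igraph::make_empty_graph(0, directed = FALSE)),
                   integer())
  expect_equal(leiden_cluster(igraph::make_empty_graph(1, directed = FALSE)),
               1L)
})

test_that("rule annotation recognises the alt-act TAM signature", {
  # five clusters with hand-built profiles on the signature markers
  mk <- c("CD16", "CX3CR1", "CD163", "CD11b", "CD56")
  prof <- rbind(altact = c(0.9, 0.9, 0.6, 0.6, 0.01),
                classact = c(0.05, 0.05, 0.02, 0.02, 0.7),
                bg1 = c(0.05, 0.05, 0.02, 0.02, 0.02),
                bg2 = c(0.06, 0.04, 0.03, 0.02, 0.03),
                bg3 = c(0.05, 0.06, 0.02, 0.03, 0.02))
  colnames(prof) <- mk
  cl <- rep(1:5, each = 10)
  norm <- prof[cl, ]
  rules <- list(annotation_rule("AltActTAM", "myeloid",
                                c(CD16 = "high", CX3CR1 = "high", CD163 = "pos",
                                  CD11b = "pos", CD56 = "neg")))
  asg <- annotate_clusters(norm, cl, rules)
  expect_equal(asg$labels$population_label,
               c("AltActTAM", "other", "other", "other", "other"))
  # all-zero profile stays "other"
  expect_equal(asg$labels$population_label[3], "other")
})

test_that("equal labels are merged and annotation ignores cluster ids", {
  mk <- c("A", "B")
  norm <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
                matrix(c(0.97, 0.02), 10, 2, byrow = TRUE),
                matrix(c(0, 1), 10, 2, byrow = TRUE))
  colnames(norm) <- mk
  cl <- rep(1:3, each = 10)
  rules <- list(annotation_rule("Apop", "other", c(A = "high")),
                annotation_rule("Bpop", "other", c(B = "high")))
  asg <- annotate_clusters(norm, cl, rules)
  expect_equal(asg$labels$population_label, c("Apop", "Apop", "Bpop"))
  merged <- asg$merged$merged_from[asg$merged$population == "Apop"]
  expect_equal(merged, "1,2")
  # permuting cluster ids permutes nothing biologically
  perm <- c(3L, 1L, 2L)[cl]
  asg2 <- annotate_clusters(norm, perm, rules)
  expect_equal(asg2$population_label, asg$population_label)
})

test_that("synthetic cohorts are phenotyped back to their true populations", {
  sm <- small_cohort()
  ari <- mclust::adjustedRandIndex(sm$cells$population_label,
                                   sm$truth$true_population)
  expect_gte(ari, 0.9)
  expect_gte(mean(sm$cells$hierarchy_label == sm$truth$true_hierarchy), 0.9)
})

test_that("sub-clustering splits a population into its planted profiles", {
  set.seed(10)
  n <- 240
  sub_truth <- rep(1:3, each = n / 3)
  mk <- c("P1", "P2", "P3", "bulk")
  norm <- matrix(0.05, n, 4, dimnames = list(NULL, mk))
  for (k in 1:3) norm[sub_truth == k, k] <- rnorm(n / 3, 0.8, 0.05)
  d <- data.frame(cell_id = paste0("c", 1:n), case_id = "k", roi_id = "r",
                  x_um = 1:n * 0.1, y_um = 1, population_label = "target")
  for (m in mk) { d[[m]] <- norm[, m]; d[[paste0("norm_", m)]] <- norm[, m] }
  ct <- cell_table(d, panel_def(mk), roi_geometry("r", "k", 100, 100))
  ct$population_label <- "target"
  out <- subcluster_population(ct, "target", rules = NULL, k_neighbours = 10,
                               resolution = 0.05, seed = 2)
  expect_equal(length(unique(out$subpopulation_label)), 3)
  expect_equal(mclust::adjustedRandIndex(out$subpopulation_label, sub_truth), 1)
  # tiny subset collapses to one subcluster with a warning
  ct2 <- ct[1:5, ]
  attr(ct2, "markers") <- mk
  class(ct2) <- c("cell_table", "data.frame")
  expect_warning(out2 <- subcluster_population(ct2, "target", k_neighbours = 10),
                 "single subcluster")
  expect_equal(unique(out2$subpopulation_label), "target_sub1")
  expect_error(subcluster_population(ct, "absent"), "no cells")
})
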