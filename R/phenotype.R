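#' Annotation rules
#'
#' Phenotype annotation is mechanised as a declarative rule table: each
#' rule names a population, its hierarchy, and marker expectations.
#' Expectations are evaluated on cluster mean profiles of normalised
#' expression, z-scored per marker across clusters:
#' \describe{
#'   \item{high / low}{z-score at or above `+0.5` / at or below `-0.5`
#'     (thresholds configurable in [annotate_clusters()]).}
#'   \item{pos / neg}{cluster mean strictly above / at or below the
#'     across-cluster median for that marker (neg is inclusive so that
#'     background-level clusters, which tie at the median, count as
#'     negative).}
#'   \item{any}{no constraint (ignored).}
#' }
#'
#' @param population population label the rule assigns.
#' @param hierarchy hierarchical cell type (`"myeloid"`, `"neoplastic"`,
#'   `"lymphoid"`, `"vascular"`, `"proliferative"`, `"other"`).
#' @param expectations named character vector of expectations, values in
#'   `c("high", "low", "pos", "neg", "any")`.
#' @return An `annotation_rule` list.
#' @export
annotation_rule <- function(population, hierarchy, expectations) {
  stopifnot(length(expectations) >= 1, !is.null(names(expectations)))
  bad <- setdiff(expectations, c("high", "low", "pos", "neg", "any"))
  if (length(bad)) stopf("unknown expectation(s): %s", paste(bad, collapse = ", "))
  if (all(expectations == "any")) stopf("rule needs at least one non-'any' expectation")
  hierarchy <- match.arg(hierarchy, c("myeloid", "neoplastic", "lymphoid",
                                      "vascular", "proliferative", "other"))
  structure(list(population = population, hierarchy = hierarchy,
                 expectations = expectations),
            class = "annotation_rule")
}

#' Read or write annotation rule tables as YAML
#'
#' @param path YAML file: a list of entries with fields `population`,
#'   `hierarchy` and `expectations` (a marker -> expectation map).
#' @return [read_annotation_rules()] returns a list of
#'   [annotation_rule()] objects.
#' @export
read_annotation_rules <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(e)
    annotation_rule(e$population, e$hierarchy, unlist(e$expectations)))
}

#' @rdname read_annotation_rules
#' @param rules list of `annotation_rule` objects.
#' @export
write_annotation_rules <- function(rules, path) {
  y <- lapply(rules, function(r)
    list(population = r$population, hierarchy = r$hierarchy,
         expectations = as.list(r$expectations)))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Default annotation rule tables
#'
#' `default_population_rules()` transcribes the marker signatures of the
#' granular populations the package's simulator emulates, including the
#' alternatively activated TAM signature (CD16-high, CX3CR1-high,
#' CD163+, CD11b+, CD56-) and its classically activated counterpart
#' (CD16-low, CX3CR1-low, CD163-, CD11b-, CD56+).
#' `default_hierarchy_rules()` maps clusters to the six hierarchical
#' types (myeloid, neoplastic, lymphoid, vascular, proliferative, other).
#'
#' @return A list of [annotation_rule()] objects.
#' @export
default_population_rules <- function() {
  list(
    annotation_rule("AltActTAM", "myeloid",
                    c(CD16 = "high", CX3CR1 = "high", CD163 = "pos",
                      CD11b = "pos", CD56 = "neg")),
    annotation_rule("ClassActTAM", "myeloid",
                    c(CD16 = "low", CX3CR1 = "low", CD163 = "neg",
                      CD11b = "neg", CD56 = "pos", CD68 = "pos")),
    annotation_rule("Schwann", "neoplastic",
                    c(S100B = "high", PanCytokeratin = "high",
                      Vimentin = "high", CD68 = "low")),
    annotation_rule("TEM", "lymphoid",
                    c(CD3 = "high", CD8a = "high", CD45RO = "pos")),
    annotation_rule("Vascular", "vascular",
                    c(SMA = "high", CD31 = "high")),
    annotation_rule("Proliferative", "proliferative",
                    c(`Ki-67` = "high"))
  )
}

#' @rdname default_population_rules
#' @export
default_hierarchy_rules <- function() {
  list(
    annotation_rule("proliferative", "proliferative", c(`Ki-67` = "high")),
    annotation_rule("neoplastic", "neoplastic",
                    c(S100B = "high", PanCytokeratin = "high")),
    annotation_rule("lymphoid", "lymphoid", c(CD3 = "high", CD8a = "high")),
    annotation_rule("vascular", "vascular", c(SMA = "high", CD31 = "high")),
    annotation_rule("myeloid", "myeloid", c(Iba1 = "pos", CD68 = "pos"))
  )
}

#' Build a k-nearest-neighbour expression graph
#'
#' Euclidean kNN on a numeric matrix (cells x features), symmetrised by
#' union: an edge joins two cells when either is among the other's `k`
#' nearest neighbours.
#'
#' @param x numeric matrix (rows = cells).
#' @param k_neighbours neighbours per cell (default 15); reduced with a
#'   warning when fewer than `k + 1` cells are supplied.
#' @return An undirected `igraph` graph with one vertex per row of `x`.
#' @export
build_expression_graph <- function(x, k_neighbours = 15) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2) stopf("need at least 2 cells to build a graph")
  if (n <= k_neighbours) {
    warnf("build_expression_graph: k reduced from %d to %d (n = %d)",
          k_neighbours, n - 1L, n)
    k_neighbours <- n - 1L
  }
  nn <- FNN::get.knn(x, k = k_neighbours)$nn.index
  i <- rep(seq_len(n), ncol(nn)); j <- as.vector(nn)
  a <- pmin(i, j); b <- pmax(i, j)
  keep <- !duplicated(a * (n + 1) + b)
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

#' Leiden clustering of a graph
#'
#' Community detection with the Leiden algorithm (modularity objective).
#' Deterministic given `seed`; every vertex is assigned a cluster.
#'
#' @param graph an `igraph` graph.
#' @param resolution resolution parameter (default 1).
#' @param seed integer seed.
#' @return Integer vector of 1-based cluster ids, one per vertex.
#' @export
leiden_cluster <- function(graph, resolution = 1, seed = 1L) {
  if (igraph::vcount(graph) == 0) return(integer())
  cl <- with_seed(seed,
    igraph::cluster_leiden(graph, objective_function = "modularity",
                           resolution = resolution, n_iterations = 5))
  as.integer(igraph::membership(cl))
}

# Cluster mean profiles: clusters x markers matrix of mean normalised values.
cluster_profiles <- function(norm, cluster_id) {
  ids <- sort(unique(cluster_id))
  prof <- t(vapply(ids, function(k) colMeans(norm[cluster_id == k, , drop = FALSE]),
                   numeric(ncol(norm))))
  rownames(prof) <- ids
  prof
}

#' Annotate expression clusters with a rule table
#'
#' Cluster mean profiles are z-scored per marker across clusters; a rule
#' matches a cluster when all its non-`any` expectations hold (see
#' [annotation_rule()]). Each cluster receives the matching rule with the
#' most satisfied expectations (ties broken by rule order); clusters no
#' rule matches are labelled `"other"`. Clusters with equal labels are
#' merged, with the constituent ids recorded.
#'
#' Annotation depends only on the cluster profiles, so it is invariant
#' to permutation of cluster ids.
#'
#' @param norm numeric matrix of normalised expression (cells x markers).
#' @param cluster_id integer cluster id per cell.
#' @param rules list of [annotation_rule()] objects.
#' @param high_z,low_z z-score thresholds for `high` / `low` (defaults
#'   +0.5 / -0.3). The `low` default is less extreme than the `high`
#'   one because across-cluster z-scores are right-skewed: a single
#'   strongly positive cluster caps every other cluster's z near
#'   `-1/sqrt(k - 1)` for k clusters, so a -0.5 cut would make `low`
#'   unreachable once k exceeds ~5.
#' @param pos_margin minimal contrast (on the normalised \[0, 1\]
#'   expression scale) a cluster mean must exceed the across-cluster
#'   median by to count as `pos` (default 0.02); without it, clusters
#'   tied at background level satisfy `pos` through sampling noise of
#'   order 1e-3.
#' @return A `cluster_assignment` list: per-cell `population_label` and
#'   `hierarchy_label`, per-cluster `labels` data frame (with
#'   `merged_from`), and the `profiles` matrix.
#' @export
annotate_clusters <- function(norm, cluster_id, rules, high_z = 0.5,
                              low_z = -0.3, pos_margin = 0.02) {
  stopifnot(nrow(norm) == length(cluster_id))
  prof <- cluster_profiles(norm, cluster_id)
  nk <- nrow(prof)
  mu <- colMeans(prof)
  sdv <- apply(prof, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf     # constant marker or single cluster: z = 0
  z <- sweep(sweep(prof, 2, mu), 2, sdv, "/")
  med <- apply(prof, 2, stats::median)
  pop <- character(nk); hier <- character(nk)
  for (i in seq_len(nk)) {
    best <- 0L; best_score <- -1L
    for (j in seq_along(rules)) {
      r <- rules[[j]]
      ex <- r$expectations[r$expectations != "any"]
      mk <- names(ex)
      miss <- setdiff(mk, colnames(prof))
      if (length(miss)) next                 # rule references absent markers
      ok <- vapply(mk, function(m) switch(ex[[m]],
        high = z[i, m] >= high_z,
        low  = z[i, m] <= low_z,
        pos  = prof[i, m] > med[[m]] + pos_margin,
        neg  = prof[i, m] <= med[[m]] + pos_margin), logical(1))
      if (all(ok) && length(ok) > best_score) {
        best <- j; best_score <- length(ok)
      }
    }
    if (best == 0L) { pop[i] <- "other"; hier[i] <- "other" }
    else { pop[i] <- rules[[best]]$population; hier[i] <- rules[[best]]$hierarchy }
  }
  ids <- as.integer(rownames(prof))
  merged <- stats::aggregate(list(merged_from = ids), by = list(population = pop),
                             FUN = function(v) paste(v, collapse = ","))
  labels <- data.frame(cluster_id = ids, population_label = pop,
                       hierarchy_label = hier, stringsAsFactors = FALSE)
  idx <- match(cluster_id, ids)
  structure(list(cluster_id = cluster_id,
                 population_label = pop[idx],
                 hierarchy_label = hier[idx],
                 labels = labels, merged = merged, profiles = prof),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d cells, %d clusters -> %d populations\n",
              length(x$cluster_id), nrow(x$labels),
              length(unique(x$labels$population_label))))
  print(table(x$population_label))
  invisible(x)
}

#' Phenotype the cells of a cohort
#'
#' Convenience wrapper: builds the kNN expression graph on normalised
#' values, clusters it with Leiden, annotates clusters with the
#' hierarchy and population rule tables, and appends `hierarchy_label`
#' and `population_label` columns to the table.
#'
#' @param table a normalised `cell_table`.
#' @param k_neighbours,resolution,seed clustering parameters.
#' @param hierarchy_rules,population_rules rule tables (defaults:
#'   [default_hierarchy_rules()], [default_population_rules()]).
#' @return The labelled `cell_table`, with the `cluster_assignment` in
#'   the `"phenotype"` attribute.
#' @export
phenotype_cells <- function(table, k_neighbours = 15, resolution = 0.5,
                            seed = 1L,
                            hierarchy_rules = default_hierarchy_rules(),
                            population_rules = default_population_rules()) {
  norm <- norm_matrix(table)
  g <- build_expression_graph(norm, k_neighbours)
  cl <- leiden_cluster(g, resolution, seed = derive_seed(seed, "leiden"))
  asg_h <- annotate_clusters(norm, cl, hierarchy_rules)
  asg_p <- annotate_clusters(norm, cl, population_rules)
  table$cluster_id <- cl
  table$hierarchy_label <- asg_h$hierarchy_label
  table$population_label <- asg_p$population_label
  attr(table, "phenotype") <- asg_p
  table
}

#' Sub-cluster one population
#'
#' Re-runs Leiden clustering on the cells of a single population only
#' (e.g. the proliferative cells) and annotates the sub-clusters with a
#' second rule table.
#'
#' @param table a labelled, normalised `cell_table`.
#' @param population the `population_label` to sub-cluster.
#' @param rules rule table for sub-population annotation; `NULL` keeps
#'   raw sub-cluster ids as labels.
#' @param k_neighbours,resolution,seed clustering parameters.
#' @return The table with a `subpopulation_label` column filled for the
#'   target population (`NA` elsewhere).
#' @export
subcluster_population <- function(table, population, rules = NULL,
                                  k_neighbours = 15, resolution = 0.5,
                                  seed = 1L) {
  if (!"population_label" %in% names(table))
    stopf("table has no population labels; run phenotype_cells()")
  idx <- which(table$population_label == population)
  if (!length(idx)) stopf("population '%s' has no cells", population)
  norm <- norm_matrix(table)[idx, , drop = FALSE]
  if (length(idx) == 1L) {
    sub <- 1L
  } else if (length(idx) <= k_neighbours) {
    warnf("subcluster_population: subset (n = %d) smaller than k; single subcluster",
          length(idx))
    sub <- rep(1L, length(idx))
  } else {
    g <- build_expression_graph(norm, k_neighbours)
    sub <- leiden_cluster(g, resolution, seed = derive_seed(seed, "subleiden"))
  }
  lab <- if (is.null(rules)) {
    sprintf("%s_sub%d", population, sub)
  } else {
    annotate_clusters(norm, sub, rules)$population_label
  }
  if (!"subpopulation_label" %in% names(table))
    table$subpopulation_label <- NA_character_
  table$subpopulation_label[idx] <- lab
  table
}
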