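#' Per-cell neighbourhood feature vectors
#'
#' For every cell, the `l`-step neighbourhood on the pruned spatial
#' graph is summarised by four feature groups:
#' \describe{
#'   \item{composition}{fraction of member cells per population (sums
#'     to 1).}
#'   \item{shape}{convex-hull area of the member coordinates (um^2) and
#'     circularity `4 * pi * area / perimeter^2` (1 for a disc).
#'     Neighbourhoods with fewer than 3 members, or degenerate
#'     (collinear) hulls, get area 0 and circularity 1.}
#'   \item{distribution}{mean and standard deviation of member distances
#'     to the neighbourhood centroid (um; sd 0 for single members).}
#'   \item{proximity}{mean length of graph edges joining two members
#'     (um; 0 when no internal edge exists).}
#' }
#'
#' @param graph a `spatial_graph`.
#' @param labels population label per graph cell (same order as
#'   `graph$cell_id`).
#' @param l neighbourhood steps (default 3).
#' @param pop_levels population levels defining the composition columns
#'   (default: sorted unique labels). Pass the cohort-wide levels when
#'   pooling features across ROIs.
#' @return A numeric matrix (cells x features) with columns
#'   `comp_<population>`, `hull_area_um2`, `circularity`, `dist_mean_um`,
#'   `dist_sd_um`, `proximity_um`, and the member count in attribute
#'   `"size"`.
#' @export
neighbourhood_features <- function(graph, labels, l = 3, pop_levels = NULL) {
  n <- length(graph$cell_id)
  stopifnot(length(labels) == n)
  pop_levels <- pop_levels %||% sort(unique(labels))
  lab_i <- match(labels, pop_levels)
  if (anyNA(lab_i)) stopf("labels outside pop_levels")
  P <- length(pop_levels)
  # index internal edges once: for each cell the incident edge ids
  feat <- matrix(0, n, P + 5)
  colnames(feat) <- c(paste0("comp_", pop_levels), "hull_area_um2",
                      "circularity", "dist_mean_um", "dist_sd_um",
                      "proximity_um")
  sizes <- integer(n)
  ei <- graph$edges$i; ej <- graph$edges$j; el <- graph$edges$length_um
  for (v in seq_len(n)) {
    mem <- l_step_indices(graph$adj, v, l)
    sizes[v] <- length(mem)
    comp <- tabulate(lab_i[mem], nbins = P)
    feat[v, seq_len(P)] <- comp / length(mem)
    xs <- graph$x[mem]; ys <- graph$y[mem]
    if (length(mem) >= 3) {
      h <- grDevices::chull(xs, ys)
      hx <- xs[h]; hy <- ys[h]
      area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
      per <- sum(sqrt(diff(c(hx, hx[1]))^2 + diff(c(hy, hy[1]))^2))
      if (area > 0 && per > 0) {
        feat[v, P + 1] <- area
        feat[v, P + 2] <- min(1, 4 * pi * area / per^2)
      } else {
        feat[v, P + 2] <- 1
      }
    } else {
      feat[v, P + 2] <- 1
    }
    cx <- mean(xs); cy <- mean(ys)
    dd <- sqrt((xs - cx)^2 + (ys - cy)^2)
    feat[v, P + 3] <- mean(dd)
    feat[v, P + 4] <- if (length(mem) > 1) stats::sd(dd) else 0
    if (nrow(graph$edges)) {
      inmem <- logical(n); inmem[mem] <- TRUE
      internal <- inmem[ei] & inmem[ej]
      if (any(internal)) feat[v, P + 5] <- mean(el[internal])
    }
  }
  attr(feat, "size") <- sizes
  attr(feat, "cell_id") <- graph$cell_id
  feat
}

#' Fowlkes-Mallows index between two partitions
#'
#' Pair-counting similarity: `FMI = TP / sqrt((TP+FP) * (TP+FN))`, where
#' TP is the number of item pairs co-clustered in both partitions, TP+FP
#' the pairs co-clustered in the first, TP+FN in the second. 1 iff the
#' partitions are identical up to relabelling. When one partition has no
#' co-clustered pair at all (all singletons), the index is 1 if the
#' other has none either, otherwise 0.
#'
#' @param labels_a,labels_b cluster labels over the same items.
#' @return A number in \[0, 1\].
#' @export
fowlkes_mallows <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stopf("partitions must cover the same items")
  n <- length(labels_a)
  if (n < 2) stopf("Fowlkes-Mallows index undefined for fewer than 2 items")
  ct <- table(labels_a, labels_b)
  tp <- sum(choose(ct, 2))
  pa <- sum(choose(rowSums(ct), 2))          # TP + FP
  pb <- sum(choose(colSums(ct), 2))          # TP + FN
  if (pa == 0 && pb == 0) return(1)
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

# Standardise features, dropping zero-variance columns.
standardize_features <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  keep <- is.finite(sdv) & sdv > 0
  scale(x[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
}

# One GMM fit (full covariance, k-means initialisation); returns labels
# with the attained log-likelihood in attribute "loglik".
gmm_fit_once <- function(x, K, seed) {
  with_seed(seed, {
    if (K == 1)
      return(structure(rep(1L, nrow(x)), loglik = 0, wss = 0))
    # single random start per fit: stability selection relies on fits
    # varying when K does not match real structure
    km <- stats::kmeans(x, centers = K, nstart = 1, iter.max = 50)
    fit <- tryCatch(
      mclust::me(data = x, modelName = "VVV",
                 z = mclust::unmap(km$cluster, groups = seq_len(K)),
                 prior = mclust::priorControl()),
      error = function(e) NULL)
    # EM can fail on (near-)degenerate clusters; keep the k-means
    # solution then, scored by its total within-cluster SS
    if (is.null(fit) || anyNA(fit$z) || !is.finite(fit$loglik))
      return(structure(as.integer(km$cluster), loglik = -Inf,
                       wss = km$tot.withinss))
    structure(max.col(fit$z), loglik = fit$loglik,
              wss = km$tot.withinss)
  })
}

# Best-of-n_init GMM fit (used for the final refit; stability repeats
# deliberately use one start each). Candidates with a finite EM
# log-likelihood are preferred by log-likelihood; when EM failed for
# all starts, the k-means fallback with the lowest within-SS wins.
gmm_fit <- function(x, K, seed, n_init = 1) {
  best <- NULL
  for (i in seq_len(n_init)) {
    cand <- gmm_fit_once(x, K, derive_seed(seed, "init", i))
    if (is.null(best) ||
        attr(cand, "loglik") > attr(best, "loglik") ||
        (!is.finite(attr(best, "loglik")) && !is.finite(attr(cand, "loglik")) &&
         attr(cand, "wss") < attr(best, "wss")))
      best <- cand
  }
  best
}

#' Cluster neighbourhood features with a stability-selected GMM
#'
#' Features are z-scored internally and fitted with Gaussian mixture
#' models (full covariance, k-means initialisation) over a range of
#' component counts. For each K, `n_repeats` fits on random
#' `subsample`-fraction subsamples are compared by the mean pairwise
#' Fowlkes-Mallows index of their labels on shared cells; the most
#' stable K (ties broken toward smaller K) is refit on all cells.
#'
#' Note K = 1 is trivially perfectly stable; include it in `K_range`
#' only deliberately.
#'
#' @param features numeric matrix from [neighbourhood_features()] (rows
#'   pooled over ROIs for a cohort-level model).
#' @param K_range integer vector of candidate cluster counts.
#' @param n_repeats subsample fits per K (default 10).
#' @param subsample subsample fraction (default 0.8).
#' @param seed integer seed.
#' @param feature_weights named weights of the four feature groups
#'   (`composition`, `shape`, `distribution`, `proximity`). After
#'   z-scoring, each column is scaled by its group weight divided by the
#'   square root of the group's column count, so a group's total
#'   variance is `weight^2` regardless of how many columns encode it;
#'   composition columns keep weight 1 each. The default keeps cell-type
#'   composition the primary signal, with the geometric groups refining
#'   rather than dominating the mixture.
#' @return An `nbhd_model`: `K`, `nbhd_label` (integer per cell),
#'   `stability_by_K`, plus the standardised feature matrix attributes
#'   needed by downstream annotation.
#' @export
cluster_neighbourhoods <- function(features, K_range, n_repeats = 10,
                                   subsample = 0.8, seed = 1L,
                                   feature_weights = c(composition = 1,
                                                       shape = 0.5,
                                                       distribution = 0.5,
                                                       proximity = 0.5)) {
  x <- standardize_features(features)
  grp_of <- function(nm) {
    if (startsWith(nm, "comp_")) "composition"
    else if (nm %in% c("hull_area_um2", "circularity")) "shape"
    else if (nm %in% c("dist_mean_um", "dist_sd_um")) "distribution"
    else if (nm == "proximity_um") "proximity"
    else "composition"
  }
  grps <- vapply(colnames(x), grp_of, "")
  for (g in setdiff(unique(grps), "composition")) {
    cols <- grps == g
    w <- if (g %in% names(feature_weights)) feature_weights[[g]] else 1
    x[, cols] <- x[, cols] * (w / sqrt(sum(cols)))
  }
  n <- nrow(x)
  K_range <- sort(unique(as.integer(K_range)))
  drop_k <- K_range >= n
  if (any(drop_k)) {
    warnf("cluster_neighbourhoods: K >= n skipped: %s",
          paste(K_range[drop_k], collapse = ", "))
    K_range <- K_range[!drop_k]
  }
  if (!length(K_range)) stopf("no feasible K in K_range")
  m <- max(2L, floor(subsample * n))
  stability <- setNames(numeric(length(K_range)), K_range)
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    subs <- vector("list", n_repeats)
    labs <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      idx <- with_seed(derive_seed(seed, "subsample", K, r),
                       sort(sample.int(n, m)))
      subs[[r]] <- idx
      labs[[r]] <- gmm_fit(x[idx, , drop = FALSE], K,
                           seed = derive_seed(seed, "gmm", K, r))
    }
    fmis <- c()
    for (a in seq_len(n_repeats - 1)) {
      for (b in seq((a + 1), n_repeats)) {
        shared <- intersect(subs[[a]], subs[[b]])
        if (length(shared) < 2) next
        fmis <- c(fmis, fowlkes_mallows(labs[[a]][match(shared, subs[[a]])],
                                        labs[[b]][match(shared, subs[[b]])]))
      }
    }
    stability[ki] <- if (length(fmis)) mean(fmis) else NA_real_
  }
  K_best <- K_range[which.max(stability)]   # which.max takes first (smallest K) on ties
  final <- gmm_fit(x, K_best, seed = derive_seed(seed, "final", K_best),
                   n_init = 5)
  structure(list(K = K_best, nbhd_label = as.integer(final),
                 stability_by_K = stability, n = n,
                 features_used = colnames(x)),
            class = "nbhd_model")
}

#' @export
print.nbhd_model <- function(x, ...) {
  cat(sprintf("<nbhd_model> K = %d over %d cells\n", x$K, x$n))
  cat("stability by K:\n")
  print(round(x$stability_by_K, 3))
  invisible(x)
}

#' Annotate neighbourhood clusters by cell-type enrichment
#'
#' For each neighbourhood cluster and population, the fold change
#' `FC = frequency in cluster / overall frequency` is computed;
#' populations with `FC >= 1` are the cluster's enriched set. The
#' cluster category is the compartment (tumour from neoplastic cells,
#' vasculature from vascular cells, immune from myeloid plus lymphoid
#' cells) with the largest summed enriched FC, and a cluster is marked
#' proliferative when any proliferative-hierarchy population reaches
#' `FC >= 1`.
#'
#' @param nbhd_label neighbourhood cluster id per cell.
#' @param population_label population per cell.
#' @param hierarchy_label hierarchy per cell (`"myeloid"`,
#'   `"neoplastic"`, `"lymphoid"`, `"vascular"`, `"proliferative"`,
#'   `"other"`).
#' @return A list with `fc` (clusters x populations matrix),
#'   `category` (per cluster: `"tumour_enriched"`,
#'   `"vasculature_enriched"` or `"immune_enriched"`) and
#'   `proliferative` (logical per cluster).
#' @export
annotate_neighbourhood_clusters <- function(nbhd_label, population_label,
                                            hierarchy_label) {
  stopifnot(length(nbhd_label) == length(population_label),
            length(nbhd_label) == length(hierarchy_label))
  pops <- sort(unique(population_label))
  ks <- sort(unique(nbhd_label))
  overall <- prop.table(table(factor(population_label, levels = pops)))
  fc <- matrix(NA_real_, length(ks), length(pops),
               dimnames = list(as.character(ks), pops))
  for (i in seq_along(ks)) {
    ink <- nbhd_label == ks[i]
    freq <- prop.table(table(factor(population_label[ink], levels = pops)))
    fc[i, ] <- as.numeric(freq) / as.numeric(overall)
  }
  hier_of <- tapply(hierarchy_label, population_label, function(h)
    names(sort(table(h), decreasing = TRUE))[1])[pops]
  cat_of <- c(neoplastic = "tumour_enriched", vascular = "vasculature_enriched",
              myeloid = "immune_enriched", lymphoid = "immune_enriched")
  category <- character(length(ks)); prolif <- logical(length(ks))
  for (i in seq_along(ks)) {
    enriched <- fc[i, ] >= 1
    sums <- c(tumour_enriched = 0, vasculature_enriched = 0, immune_enriched = 0)
    for (p in pops) {
      cl <- cat_of[hier_of[[p]]]
      if (!is.na(cl) && enriched[[p]]) sums[[cl]] <- sums[[cl]] + fc[i, p]
    }
    category[i] <- names(sums)[which.max(sums)]
    prolif[i] <- any(enriched[hier_of == "proliferative"], na.rm = TRUE)
  }
  list(fc = fc, category = setNames(category, ks),
       proliferative = setNames(prolif, ks))
}

#' Observed/expected neighbourhood proximity
#'
#' How likely cells of one neighbourhood cluster are to be connected (by
#' retained spatial-graph edges) to cells of another, against random
#' chance: observed inter-label edge counts pooled over ROIs, divided by
#' their expectation under random permutation of the labels within each
#' ROI (preserving each ROI's graph and label counts).
#'
#' @param graphs list of `spatial_graph` objects.
#' @param labels_by_graph list (parallel to `graphs`) of per-cell
#'   neighbourhood labels in graph vertex order.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @param levels label levels defining the matrix (default: union).
#' @return A `proximity_matrix` list: `oe` (K x K symmetric matrix),
#'   `observed`, `expected`, `n_perm`.
#' @export
neighbourhood_proximity <- function(graphs, labels_by_graph, n_perm = 1000,
                                    seed = 1L, levels = NULL) {
  stopifnot(length(graphs) == length(labels_by_graph))
  levels <- levels %||% sort(unique(unlist(labels_by_graph)))
  K <- length(levels)
  count_edges <- function(li, lj) {
    a <- pmin(li, lj); b <- pmax(li, lj)
    m <- matrix(0, K, K)
    tab <- tabulate((a - 1L) * K + b, nbins = K * K)
    m[] <- tab
    m <- t(m)                                 # tab indexed by (a-1)*K+b -> row a, col b
    m + t(m) - diag(diag(m), nrow = K)
  }
  obs <- matrix(0, K, K)
  exp_sum <- matrix(0, K, K)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    lab <- match(labels_by_graph[[gi]], levels)
    if (anyNA(lab)) stopf("labels outside levels in graph %d", gi)
    if (!nrow(g$edges)) next
    ei <- g$edges$i; ej <- g$edges$j
    obs <- obs + count_edges(lab[ei], lab[ej])
    perm_acc <- matrix(0, K, K)
    with_seed(derive_seed(seed, "proximity", gi), {
      for (p in seq_len(n_perm)) {
        pl <- lab[sample.int(length(lab))]
        perm_acc <- perm_acc + count_edges(pl[ei], pl[ej])
      }
    })
    exp_sum <- exp_sum + perm_acc / n_perm
  }
  oe <- obs / exp_sum
  oe[!is.finite(oe)] <- 0                     # labels with no expected contact
  dimnames(oe) <- dimnames(obs) <- dimnames(exp_sum) <-
    list(levels, levels)
  structure(list(oe = oe, observed = obs, expected = exp_sum,
                 n_perm = n_perm), class = "proximity_matrix")
}

#' @export
print.proximity_matrix <- function(x, ...) {
  cat(sprintf("<proximity_matrix> %d labels, %d permutations\n",
              nrow(x$oe), x$n_perm))
  print(round(x$oe, 2))
  invisible(x)
}

#' Compare neighbourhood composition between case groups
#'
#' Computes per-case proportions of cells in each neighbourhood cluster
#' (each case's proportions sum to 1), then: (i) per-cluster
#' static-vs-growing Mann-Whitney tests; (ii) a two-way ANOVA
#' (group x category) on per-case proportions summed within annotation
#' categories; (iii) a two-way ANOVA (group x proliferative status) on
#' proliferative vs non-proliferative proportions.
#'
#' @param nbhd_label neighbourhood cluster per cell.
#' @param case_id case per cell.
#' @param metadata a `case_metadata` data frame.
#' @param annotation result of [annotate_neighbourhood_clusters()]
#'   (optional; required for the category/proliferative ANOVAs).
#' @return A list with `proportions` (case x cluster matrix),
#'   `per_cluster` (data frame of Mann-Whitney results), and, when
#'   `annotation` is given, `category_anova` and `proliferative_anova`.
#' @export
neighbourhood_group_comparison <- function(nbhd_label, case_id, metadata,
                                           annotation = NULL) {
  ks <- sort(unique(nbhd_label))
  cases <- intersect(metadata$case_id, unique(case_id))
  dropped <- setdiff(metadata$case_id, cases)
  if (length(dropped))
    warnf("cases with zero cells excluded: %s", paste(dropped, collapse = ", "))
  tab <- table(factor(case_id, levels = cases), factor(nbhd_label, levels = ks))
  prop <- prop.table(tab, margin = 1)
  grp <- metadata$classification[match(cases, metadata$case_id)]
  per_cluster <- data.frame(nbhd = ks, statistic = NA_real_, p = NA_real_)
  for (i in seq_along(ks)) {
    wt <- suppressWarnings(stats::wilcox.test(prop[grp == "static", i],
                                              prop[grp == "growing", i],
                                              exact = TRUE))
    per_cluster$statistic[i] <- unname(wt$statistic)
    per_cluster$p[i] <- wt$p.value
  }
  out <- list(proportions = prop, group = setNames(grp, cases),
              per_cluster = per_cluster)
  if (!is.null(annotation)) {
    cat_of <- annotation$category[as.character(ks)]
    cat_prop <- do.call(rbind, lapply(unique(cat_of), function(cc) {
      data.frame(case = cases,
                 value = rowSums(prop[, cat_of == cc, drop = FALSE]),
                 factorA = grp, factorB = cc, stringsAsFactors = FALSE)
    }))
    out$category_anova <- if (length(unique(cat_prop$factorB)) > 1 &&
                              length(unique(cat_prop$factorA)) > 1)
      compare_groups(cat_prop[c("value", "factorA", "factorB")],
                     design = "two_way") else NULL
    pr_of <- ifelse(annotation$proliferative[as.character(ks)],
                    "proliferative", "non_proliferative")
    pr_prop <- do.call(rbind, lapply(unique(pr_of), function(cc) {
      data.frame(case = cases,
                 value = rowSums(prop[, pr_of == cc, drop = FALSE]),
                 factorA = grp, factorB = cc, stringsAsFactors = FALSE)
    }))
    out$proliferative_anova <- if (length(unique(pr_of)) > 1 &&
                                   length(unique(grp)) > 1)
      compare_groups(pr_prop[c("value", "factorA", "factorB")],
                     design = "two_way") else NULL
    out$category_proportions <- cat_prop
    out$proliferative_proportions <- pr_prop
  }
  out
}
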