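#' Pipeline configuration
#'
#' A pipeline run is driven by a single configuration (R list or YAML
#' file) holding the input source, stage list, stage parameters, the
#' mandatory global seed, and the output directory. All randomised
#' procedures consume seeds derived deterministically from the global
#' seed and a stage tag, so stages are independently reproducible.
#'
#' @param path YAML file path.
#' @return A validated config list.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

pipeline_stages <- c("simulate", "quantify", "phenotype", "neighbourhoods",
                     "spatial")

default_pipeline_params <- function() {
  list(q = 99.9, k_neighbours = 15, resolution = 0.5, l = 3,
       prune_percentile = 99, K_range = 2:6, n_repeats = 10,
       subsample = 0.8, side_um = 100, r_max = 300, dr = 10,
       n_boot = 200, n_perm = 1000, alpha = 0.05, qcm_prop = 0.5,
       max_pairs = 6)
}

#' @rdname read_pipeline_config
#' @param config a config list with elements `seed` (mandatory),
#'   `output_dir`, `stages` (subset of simulate, quantify, phenotype,
#'   neighbourhoods, spatial), either `simulate` (list of
#'   [default_scenario()] overrides: `n_static`, `n_growing`,
#'   `rois_per_case`, `roi_width_um`, `roi_height_um`,
#'   `intensity_scale`) or `input` (paths `cells`, `panel`, `metadata`,
#'   `geometry`), and `params` overriding the stage defaults.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) stopf("pipeline config requires a seed")
  config$seed <- as.integer(config$seed)
  config$output_dir <- config$output_dir %||% "spatialTME_out"
  config$stages <- config$stages %||% pipeline_stages
  bad <- setdiff(config$stages, pipeline_stages)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  if (is.null(config$simulate) && is.null(config$input))
    config$simulate <- list()
  p <- default_pipeline_params()
  for (nm in names(config$params)) {
    if (!nm %in% names(p)) stopf("unknown parameter '%s'", nm)
    p[[nm]] <- config$params[[nm]]
  }
  p$K_range <- as.integer(unlist(p$K_range))
  config$params <- p
  config
}

config_hash <- function(config) {
  derive_seed(1L, yaml::as.yaml(config[sort(names(config))]))
}

stage_done <- function(manifest, stage, files) {
  !is.null(manifest$stages[[stage]]) && all(file.exists(files))
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (simulate/load -> quantify ->
#' phenotype -> neighbourhoods -> spatial), writing tabular outputs to
#' the configured directory and a manifest (`manifest.yaml`) recording
#' the config hash, seed, package version and per-stage output paths.
#' Re-running an identical config is a no-op for completed stages;
#' identical config and seed reproduce identical outputs.
#'
#' @param config a config list (see [validate_pipeline_config()]) or a
#'   YAML file path.
#' @return The manifest list, invisibly; its `results` element carries
#'   the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.yaml")
  hash <- config_hash(config)
  manifest <- list(config_hash = hash, seed = config$seed,
                   version = as.character(utils::packageVersion("spatialTME")),
                   stages = list())
  if (file.exists(manifest_path)) {
    old <- yaml::read_yaml(manifest_path)
    if (identical(old$config_hash, hash)) manifest$stages <- old$stages
    else manifest$stages <- list()
  }
  res <- list()
  p <- config$params
  seed <- config$seed
  stages <- config$stages

  # ---- stage: simulate / load -------------------------------------------
  paths <- list(cells = file.path(out, "cells.csv"),
                metadata = file.path(out, "metadata.csv"),
                geometry = file.path(out, "geometry.csv"),
                truth = file.path(out, "truth.csv"))
  if ("simulate" %in% stages && !is.null(config$simulate)) {
    sim_files <- unlist(paths[c("cells", "metadata", "geometry")])
    if (!stage_done(manifest, "simulate", sim_files)) {
      s <- config$simulate
      scenario <- default_scenario(
        seed = derive_seed(seed, "simulate"),
        rois_per_case = s$rois_per_case %||% 6,
        roi_width_um = s$roi_width_um %||% 1000,
        roi_height_um = s$roi_height_um %||% 1000,
        intensity_scale = s$intensity_scale %||% 1)
      if (!is.null(s$n_static) || !is.null(s$n_growing)) {
        scenario$n_static <- s$n_static %||% scenario$n_static
        scenario$n_growing <- s$n_growing %||% scenario$n_growing
      }
      sim <- simulate_cohort(scenario)
      write_cell_table(sim$cells, paths$cells)
      write_case_metadata(sim$metadata, paths$metadata)
      write_roi_geometry(sim$geometry, paths$geometry)
      utils::write.csv(sim$truth, paths$truth, row.names = FALSE)
      manifest$stages$simulate <- unname(unlist(paths))
    }
    panel <- panel_def(setdiff(names(utils::read.csv(paths$cells, nrows = 1,
                                                     check.names = FALSE)),
                               c("cell_id", "case_id", "roi_id", "x_um", "y_um")))
    geometry <- read_roi_geometry(paths$geometry)
    cells <- read_cell_table(paths$cells, panel, geometry)
    metadata <- read_case_metadata(paths$metadata)
  } else if (!is.null(config$input)) {
    inp <- config$input
    panel <- read_panel(inp$panel)
    geometry <- read_roi_geometry(inp$geometry)
    cells <- read_cell_table(inp$cells, panel, geometry)
    metadata <- read_case_metadata(inp$metadata)
  } else {
    stopf("no input: configure 'simulate' or 'input'")
  }
  res$cells <- cells; res$metadata <- metadata; res$geometry <- geometry

  # ---- stage: quantify ---------------------------------------------------
  if ("quantify" %in% stages) {
    cells <- normalize_expression(cells, q = p$q)
    dens <- cell_density(cells, geometry, "case")
    f <- file.path(out, "density_case.csv")
    utils::write.csv(dens, f, row.names = FALSE)
    manifest$stages$quantify <- f
    res$cells <- cells
    res$density_case <- dens
  }

  # ---- stage: phenotype --------------------------------------------------
  if ("phenotype" %in% stages) {
    if (!"quantify" %in% stages)
      stopf("stage 'phenotype' requires stage 'quantify'")
    cells <- phenotype_cells(cells, k_neighbours = p$k_neighbours,
                             resolution = p$resolution,
                             seed = derive_seed(seed, "phenotype"))
    dens_pop <- cell_density(cells, geometry, "case_population")
    corr <- list()
    for (pop in unique(dens_pop$label)) {
      v <- dens_pop$density_per_mm2[dens_pop$label == pop]
      names(v) <- dens_pop$case_id[dens_pop$label == pop]
      corr[[pop]] <- tryCatch(correlate_with_growth(v, metadata, alpha = p$alpha),
                              error = function(e) NULL)
    }
    corr_df <- do.call(rbind, lapply(names(corr), function(pop) {
      cr <- corr[[pop]]
      if (is.null(cr)) return(NULL)
      data.frame(population = pop, method = cr$method, r = cr$r,
                 p = cr$p_two_tailed, slope = cr$slope, stringsAsFactors = FALSE)
    }))
    f1 <- file.path(out, "cells_labelled.csv")
    f2 <- file.path(out, "density_population.csv")
    f3 <- file.path(out, "growth_correlations.csv")
    write_cell_table(cells, f1)
    utils::write.csv(dens_pop, f2, row.names = FALSE)
    utils::write.csv(corr_df, f3, row.names = FALSE)
    manifest$stages$phenotype <- c(f1, f2, f3)
    res$cells <- cells
    res$density_population <- dens_pop
    res$growth_correlations <- corr_df
  }

  # ---- stage: neighbourhoods --------------------------------------------
  if ("neighbourhoods" %in% stages) {
    if (!"phenotype" %in% stages)
      stopf("stage 'neighbourhoods' requires stage 'phenotype'")
    rois <- unique(cells$roi_id)
    pop_levels <- sort(unique(cells$population_label))
    graphs <- list(); labels <- list(); feats <- list()
    for (r in rois) {
      sub <- as.data.frame(cells)[cells$roi_id == r, ]
      g <- build_spatial_graph(sub, prune_percentile = p$prune_percentile,
                               roi_id = r)
      graphs[[r]] <- g
      labels[[r]] <- sub$population_label
      feats[[r]] <- neighbourhood_features(g, sub$population_label, l = p$l,
                                           pop_levels = pop_levels)
    }
    features <- do.call(rbind, feats)
    model <- cluster_neighbourhoods(features, K_range = p$K_range,
                                    n_repeats = p$n_repeats,
                                    subsample = p$subsample,
                                    seed = derive_seed(seed, "neighbourhoods"))
    cells$nbhd_label <- NA_integer_
    ofs <- 0
    nbhd_by_graph <- list()
    for (r in rois) {
      nr <- length(graphs[[r]]$cell_id)
      nbhd_by_graph[[r]] <- model$nbhd_label[ofs + seq_len(nr)]
      cells$nbhd_label[cells$roi_id == r] <- nbhd_by_graph[[r]]
      ofs <- ofs + nr
    }
    ann <- annotate_neighbourhood_clusters(cells$nbhd_label,
                                           cells$population_label,
                                           cells$hierarchy_label)
    prox <- neighbourhood_proximity(graphs, nbhd_by_graph,
                                    n_perm = min(p$n_perm, 200),
                                    seed = derive_seed(seed, "proximity"))
    cmp <- neighbourhood_group_comparison(cells$nbhd_label, cells$case_id,
                                          metadata, ann)
    f1 <- file.path(out, "nbhd_stability.csv")
    f2 <- file.path(out, "nbhd_fc.csv")
    f3 <- file.path(out, "nbhd_proximity_oe.csv")
    f4 <- file.path(out, "nbhd_group_comparison.csv")
    utils::write.csv(data.frame(K = as.integer(names(model$stability_by_K)),
                                stability = as.numeric(model$stability_by_K)),
                     f1, row.names = FALSE)
    utils::write.csv(as.data.frame(ann$fc), f2, row.names = TRUE)
    utils::write.csv(as.data.frame(prox$oe), f3, row.names = TRUE)
    utils::write.csv(cmp$per_cluster, f4, row.names = FALSE)
    manifest$stages$neighbourhoods <- c(f1, f2, f3, f4)
    res$cells <- cells
    res$nbhd_model <- model
    res$nbhd_annotation <- ann
    res$nbhd_proximity <- prox
    res$nbhd_comparison <- cmp
    res$graphs <- graphs
    res$labels_by_graph <- labels
  }

  # ---- stage: spatial ----------------------------------------------------
  if ("spatial" %in% stages) {
    if (!"neighbourhoods" %in% stages)
      stopf("stage 'spatial' requires stage 'neighbourhoods'")
    networks <- list()
    pair_rows <- list()
    for (grp in c("static", "growing")) {
      grp_cases <- metadata$case_id[metadata$classification == grp]
      grp_rois <- geometry$roi_id[geometry$case_id %in% grp_cases]
      grp_rois <- intersect(grp_rois, unique(cells$roi_id))
      if (!length(grp_rois)) next
      pop_levels <- sort(unique(cells$population_label))
      sig_count <- matrix(0, length(pop_levels), length(pop_levels),
                          dimnames = list(pop_levels, pop_levels))
      r_sum <- sig_count
      n_qcm <- 0
      for (r in grp_rois) {
        sub <- as.data.frame(cells)[cells$roi_id == r, ]
        gr <- geometry[geometry$roi_id == r, ]
        qc <- quadrat_counts(sub, gr$width_um, gr$height_um,
                             side_um = p$side_um, pop_levels = pop_levels)
        if (nrow(qc$counts) < 10) next
        qr <- quadrat_correlation_matrix(qc, alpha = p$alpha)
        sig_count <- sig_count + (qr$gated != 0)
        r_sum <- r_sum + qr$r
        n_qcm <- n_qcm + 1
      }
      if (n_qcm == 0) next
      qcm_grp <- list(gated = (sig_count / n_qcm >= p$qcm_prop) * (r_sum / n_qcm),
                      alpha = p$alpha)
      class(qcm_grp) <- "qcm"
      diag(qcm_grp$gated) <- 0          # self-correlation is trivially 1
      sig_pairs <- which(qcm_grp$gated != 0, arr.ind = TRUE)
      sig_pairs <- sig_pairs[order(-abs(qcm_grp$gated[sig_pairs])), ,
                             drop = FALSE]
      if (nrow(sig_pairs) > p$max_pairs)
        sig_pairs <- sig_pairs[seq_len(p$max_pairs), , drop = FALSE]
      pcfs <- list()
      for (k in seq_len(nrow(sig_pairs))) {
        s <- pop_levels[sig_pairs[k, 1]]; rcv <- pop_levels[sig_pairs[k, 2]]
        # per-ROI PCF, group-level summary: mean gr20, majority call
        calls <- character(); gr20s <- numeric()
        curves <- NULL
        for (r in grp_rois) {
          sub <- as.data.frame(cells)[cells$roi_id == r, ]
          gr <- geometry[geometry$roi_id == r, ]
          A <- sub[sub$population_label == s, ]
          B <- sub[sub$population_label == rcv, ]
          if (nrow(A) < 10 || nrow(B) < 10) next
          pf <- bootstrap_pcf(A, B, window = c(gr$width_um, gr$height_um),
                              r_max = p$r_max, dr = p$dr, n_boot = p$n_boot,
                              seed = derive_seed(seed, "pcf", grp, s, rcv, r),
                              sender_name = s, receiver_name = rcv)
          calls <- c(calls, pf$call); gr20s <- c(gr20s, pf$gr20)
          curves <- pf
        }
        if (!length(calls)) next
        maj <- names(sort(table(calls), decreasing = TRUE))[1]
        if (maj == "none" || is.null(curves)) next
        curves$call <- maj
        curves$gr20 <- mean(gr20s)
        pcfs[[paste(s, rcv, sep = "->")]] <- curves
        pair_rows[[length(pair_rows) + 1]] <-
          data.frame(group = grp, sender = s, receiver = rcv,
                     gr20 = mean(gr20s), call = maj,
                     n_rois = length(calls), stringsAsFactors = FALSE)
      }
      networks[[grp]] <- adjacency_network(qcm_grp, pcfs,
                                           res$graphs[grp_rois],
                                           res$labels_by_graph[grp_rois])
    }
    pair_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else
      data.frame(group = character(), sender = character(),
                 receiver = character(), gr20 = numeric(), call = character(),
                 n_rois = integer(), stringsAsFactors = FALSE)
    f1 <- file.path(out, "spatial_pairs.csv")
    utils::write.csv(pair_df, f1, row.names = FALSE)
    sp_files <- f1
    for (grp in names(networks)) {
      fe <- file.path(out, sprintf("network_%s_edges.csv", grp))
      utils::write.csv(networks[[grp]]$edges, fe, row.names = FALSE)
      sp_files <- c(sp_files, fe)
    }
    manifest$stages$spatial <- sp_files
    res$spatial_pairs <- pair_df
    res$networks <- networks
  }

  manifest$results <- res
  yaml::write_yaml(manifest[c("config_hash", "seed", "version", "stages")],
                   manifest_path)
  invisible(manifest)
}

#' Summarise a pipeline run
#'
#' Collects the run's main readouts into tidy tables: per-case densities
#' against growth rate, growth-rate correlations per population,
#' neighbourhood proportions by group, and the significant spatial pair
#' list.
#'
#' @param manifest the list returned by [run_pipeline()].
#' @return A `pipeline_report` list of data frames.
#' @export
report <- function(manifest) {
  res <- manifest$results
  out <- list()
  if (!is.null(res$density_case) && !is.null(res$metadata)) {
    d <- res$density_case
    d$growth_rate_pct_per_year <-
      res$metadata$growth_rate_pct_per_year[match(d$case_id,
                                                  res$metadata$case_id)]
    d$classification <- res$metadata$classification[match(d$case_id,
                                                          res$metadata$case_id)]
    out$density_vs_growth <- d
  }
  if (!is.null(res$density_population)) out$density_population <- res$density_population
  if (!is.null(res$growth_correlations)) out$growth_correlations <- res$growth_correlations
  if (!is.null(res$nbhd_comparison)) {
    pr <- as.data.frame.matrix(res$nbhd_comparison$proportions)
    pr <- cbind(case_id = rownames(pr),
                group = unname(res$nbhd_comparison$group[rownames(pr)]), pr)
    rownames(pr) <- NULL
    out$nbhd_proportions <- pr
    out$nbhd_tests <- res$nbhd_comparison$per_cluster
  }
  if (!is.null(res$spatial_pairs)) out$significant_pairs <- res$spatial_pairs
  structure(out, class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in names(x)) {
    cat(sprintf("$%s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
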