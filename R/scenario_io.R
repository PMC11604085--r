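#' Read or write a simulation scenario as YAML
#'
#' A scenario file holds the cohort design (`n_static`, `n_growing`,
#' `rois_per_case`, `roi_width_um`, `roi_height_um`, `seed`), a
#' `growth_effect` map, and a list of `populations`, each with the
#' fields of [population_spec()] (`mean_expr` as a marker -> value map).
#'
#' @param path YAML file path.
#' @return [read_scenario_config()] returns a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- lapply(y$populations, function(p) {
    population_spec(name = p$name, hierarchy = p$hierarchy,
                    mean_expr = unlist(p$mean_expr),
                    noise_cv = p$noise_cv %||% 0.5,
                    process = p$process %||% "poisson",
                    intensity_per_mm2 = p$intensity_per_mm2 %||% 100,
                    thomas_parent_per_mm2 = p$thomas_parent_per_mm2,
                    thomas_mean_offspring = p$thomas_mean_offspring,
                    thomas_sigma_um = p$thomas_sigma_um,
                    link_partner = p$link_partner,
                    link_sigma_um = p$link_sigma_um)
  })
  scenario_config(pops,
                  n_static = y$n_static %||% 4,
                  n_growing = y$n_growing %||% 5,
                  rois_per_case = y$rois_per_case %||% 6,
                  roi_width_um = y$roi_width_um %||% 1000,
                  roi_height_um = y$roi_height_um %||% 1000,
                  growth_effect = unlist(y$growth_effect),
                  seed = y$seed %||% 1L)
}

#' @rdname read_scenario_config
#' @param scenario a `scenario_config`.
#' @export
write_scenario_config <- function(scenario, path) {
  pops <- lapply(unname(scenario$populations), function(p) {
    out <- list(name = p$name, hierarchy = p$hierarchy,
                mean_expr = as.list(p$mean_expr[p$mean_expr > 0]),
                noise_cv = p$noise_cv, process = p$process,
                intensity_per_mm2 = p$intensity_per_mm2)
    for (f in c("thomas_parent_per_mm2", "thomas_mean_offspring",
                "thomas_sigma_um", "link_partner", "link_sigma_um"))
      if (!is.null(p[[f]])) out[[f]] <- p[[f]]
    out
  })
  ge <- scenario$growth_effect[scenario$growth_effect != 0]
  yaml::write_yaml(list(n_static = scenario$n_static,
                        n_growing = scenario$n_growing,
                        rois_per_case = scenario$rois_per_case,
                        roi_width_um = scenario$roi_width_um,
                        roi_height_um = scenario$roi_height_um,
                        seed = scenario$seed,
                        growth_effect = as.list(ge),
                        populations = pops),
                   path)
  invisible(path)
}

#' Export a spatial graph
#'
#' Writes the retained (pruned) cell-cell links as an edge list CSV
#' (`cell_a`, `cell_b`, `length_um`) or as GraphML via igraph.
#'
#' @param graph a `spatial_graph`.
#' @param path output file path.
#' @param format `"csv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(graph, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(data.frame(cell_a = graph$cell_id[graph$edges$i],
                                cell_b = graph$cell_id[graph$edges$j],
                                length_um = graph$edges$length_um),
                     path, row.names = FALSE)
  } else {
    ig <- igraph::make_empty_graph(length(graph$cell_id), directed = FALSE)
    ig <- igraph::set_vertex_attr(ig, "name", value = graph$cell_id)
    if (nrow(graph$edges)) {
      ig <- igraph::add_edges(ig, rbind(graph$edges$i, graph$edges$j))
      ig <- igraph::set_edge_attr(ig, "length_um",
                                  value = graph$edges$length_um)
    }
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
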