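#' Significance-gated adjacency cell network
#'
#' Builds the directed population-interaction network: an edge
#' sender -> receiver exists iff the pair is significant in the quadrat
#' correlation matrix (gated entry non-zero) AND the cross-PCF call for
#' that ordered pair is not `"none"`. Edge weight is g(r = 20 um); the
#' `%` connections of an edge is the share of retained spatial-graph
#' edges incident to sender-type cells that join them to receiver-type
#' cells. Node size is the population's relative abundance.
#'
#' @param qcm a [quadrat_correlation_matrix()] result (or any `qcm`
#'   whose `gated` matrix covers the populations).
#' @param pcfs list of `crosspcf` objects (from [bootstrap_pcf()]) for
#'   the ordered pairs to consider.
#' @param graphs list of `spatial_graph` objects (pooled for counting
#'   connections).
#' @param labels_by_graph list of per-cell population labels parallel to
#'   `graphs` (graph vertex order).
#' @return An `adjacency_network`: `nodes` (population, abundance),
#'   `edges` (sender, receiver, gr20, call, pct_connections).
#' @export
adjacency_network <- function(qcm, pcfs, graphs, labels_by_graph) {
  pops <- rownames(qcm$gated)
  all_labs <- unlist(labels_by_graph)
  abundance <- as.numeric(prop.table(table(factor(all_labs, levels = pops))))
  # pooled edge endpoint labels
  e_a <- character(); e_b <- character()
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]; lab <- labels_by_graph[[gi]]
    if (!nrow(g$edges)) next
    e_a <- c(e_a, lab[g$edges$i]); e_b <- c(e_b, lab[g$edges$j])
  }
  pct_connections <- function(s, r) {
    incident <- e_a == s | e_b == s
    if (!any(incident)) return(0)
    to_r <- (e_a == s & e_b == r) | (e_b == s & e_a == r)
    100 * sum(to_r) / sum(incident)
  }
  key <- vapply(pcfs, function(p) paste(p$sender, p$receiver, sep = "->"), "")
  names(pcfs) <- key
  edges <- data.frame(sender = character(), receiver = character(),
                      gr20 = numeric(), call = character(),
                      pct_connections = numeric(), stringsAsFactors = FALSE)
  for (s in pops) for (r in pops) {
    if (!s %in% rownames(qcm$gated) || qcm$gated[s, r] == 0) next
    p <- pcfs[[paste(s, r, sep = "->")]]
    if (is.null(p)) {
      warnf("adjacency_network: no cross-PCF for QCM-significant pair %s->%s; skipped",
            s, r)
      next
    }
    if (p$call == "none") next
    edges <- rbind(edges, data.frame(
      sender = s, receiver = r, gr20 = p$gr20, call = p$call,
      pct_connections = pct_connections(s, r), stringsAsFactors = FALSE))
  }
  structure(list(nodes = data.frame(population = pops, abundance = abundance,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "adjacency_network")
}

#' @export
print.adjacency_network <- function(x, ...) {
  cat(sprintf("<adjacency_network> %d populations, %d significant directed edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges)
  invisible(x)
}

#' Convert an adjacency network to igraph / GraphML
#'
#' @param network an `adjacency_network`.
#' @return [as_igraph()] returns an `igraph` directed graph with node
#'   `abundance` and edge `gr20`, `call`, `pct_connections` attributes.
#' @export
as_igraph <- function(network) {
  g <- igraph::make_empty_graph(n = nrow(network$nodes), directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = network$nodes$population)
  g <- igraph::set_vertex_attr(g, "abundance", value = network$nodes$abundance)
  if (nrow(network$edges)) {
    g <- igraph::add_edges(g, rbind(match(network$edges$sender,
                                          network$nodes$population),
                                    match(network$edges$receiver,
                                          network$nodes$population)))
    g <- igraph::set_edge_attr(g, "gr20", value = network$edges$gr20)
    g <- igraph::set_edge_attr(g, "call", value = network$edges$call)
    g <- igraph::set_edge_attr(g, "pct_connections",
                               value = network$edges$pct_connections)
  }
  g
}

#' @rdname as_igraph
#' @param path output file path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}
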