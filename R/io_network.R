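#' Write an interaction network to GraphML, SIF or edge TSV
#'
#' GraphML (Cytoscape-importable) carries the edge attributes r, sign and
#' weight plus any node attributes previously attached with
#' [annotate_network()]. SIF uses the interaction labels "pos"/"neg".
#' `edge_tsv` writes the columns taxonA, taxonB, r, weight, sign.
#'
#' @param net an `interaction_network`.
#' @param path output file path.
#' @param format `"graphml"`, `"sif"` or `"edge_tsv"`.
#' @export
write_network <- function(net, path, format = c("graphml", "sif",
                                                "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "interaction_network"))
  ed <- network_edges(net)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else if (format == "sif") {
    lines <- if (nrow(ed) > 0)
      sprintf("%s\t%s\t%s", ed$taxon_a,
              ifelse(ed$sign == "positive", "pos", "neg"), ed$taxon_b)
    else character(0)
    # isolated nodes appear as bare node lines, SIF convention
    iso <- igraph::V(net$graph)$name[igraph::degree(net$graph) == 0]
    writeLines(c(lines, iso), path)
  } else {
    d <- data.frame(taxonA = ed$taxon_a, taxonB = ed$taxon_b, r = ed$r,
                    weight = ed$weight, sign = ed$sign,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#'
#' @param path GraphML file.
#' @param n_samples,alpha optional metadata to restore (not stored in
#'   GraphML).
#' @return An `interaction_network` (with `r_critical` recomputed when
#'   `n_samples` is given, NA otherwise).
#' @export
read_network_graphml <- function(path, n_samples = NA, alpha = 0.05) {
  g <- igraph::read_graph(path, format = "graphml")
  structure(list(graph = g, n_samples = n_samples, alpha = alpha,
                 r_critical = if (is.na(n_samples)) NA_real_
                              else critical_r(n_samples, alpha),
                 method = "unknown"),
            class = "interaction_network")
}

#' Attach node centrality attributes to the graph
#'
#' Writes NDC, NCC, NBC and CCF as igraph vertex attributes so they are
#' exported into GraphML node annotations.
#'
#' @param net an `interaction_network`.
#' @param mode path-length mode for NCC/NBC.
#' @return The network with annotated graph.
#' @export
annotate_network <- function(net, mode = c("topological", "weighted")) {
  mode <- match.arg(mode)
  nt <- node_table(net, mode = mode)
  g <- net$graph
  ord <- match(igraph::V(g)$name, nt$taxon)
  g <- igraph::set_vertex_attr(g, "NDC", value = nt$NDC[ord])
  g <- igraph::set_vertex_attr(g, "NCC", value = nt$NCC[ord])
  g <- igraph::set_vertex_attr(g, "NBC", value = nt$NBC[ord])
  g <- igraph::set_vertex_attr(g, "CCF", value = nt$CCF[ord])
  net$graph <- g
  net
}
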