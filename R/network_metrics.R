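# Global and node-level attributes of a signed interaction network.
#
# Conventions follow Cytoscape's NetworkAnalyzer: path metrics default to
# unweighted hop counts; local clustering is 0 for degree < 2 and enters the
# network mean; closeness is the reciprocal of the mean distance to reachable
# nodes; betweenness is normalized by the pair count of the node's connected
# component, (nc-1)(nc-2)/2. Edge signs never enter topology: weight = |r|.

net_graph <- function(net) {
  if (inherits(net, "interaction_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected an interaction_network or igraph object")
}

path_weights <- function(g, mode) {
  if (mode == "weighted") igraph::E(g)$weight else NA
}

check_taxon <- function(g, taxon) {
  if (!taxon %in% igraph::V(g)$name) stop("unknown taxon: ", taxon)
}

#' Node degree centrality (NDC)
#'
#' Number of direct links incident to a taxon, signs ignored.
#'
#' @param net an `interaction_network` (or igraph graph).
#' @param taxon taxon name; omit for all nodes.
#' @return Integer degree(s), named when vectorized.
#' @export
node_degree <- function(net, taxon = NULL) {
  g <- net_graph(net)
  if (!is.null(taxon)) check_taxon(g, taxon)
  d <- igraph::degree(g, v = if (is.null(taxon)) igraph::V(g) else taxon)
  if (is.null(taxon)) d else unname(d)
}

#' Local clustering coefficient (CCF)
#'
#' Ratio of realized to possible edges among a taxon's neighbours:
#' 2 e_N / (k (k - 1)). Defined as 0 for degree < 2.
#'
#' @inheritParams node_degree
#' @return CCF value(s) in `[0, 1]`.
#' @export
local_clustering <- function(net, taxon = NULL) {
  g <- net_graph(net)
  if (!is.null(taxon)) check_taxon(g, taxon)
  cc <- igraph::transitivity(g, type = "localundirected",
                             vids = if (is.null(taxon)) igraph::V(g)
                                    else taxon,
                             isolates = "zero")
  cc[is.nan(cc)] <- 0
  if (is.null(taxon)) stats::setNames(cc, igraph::V(g)$name) else unname(cc)
}

#' Node closeness centrality (NCC)
#'
#' Reciprocal of the mean shortest-path distance from a taxon to every node it
#' can reach; 0 for isolated nodes. Distances are hop counts by default, or
#' sums of |r| edge weights in `"weighted"` mode.
#'
#' @inheritParams node_degree
#' @param mode `"topological"` (default) or `"weighted"` path lengths.
#' @return NCC value(s); in topological mode these lie in `[0, 1]`.
#' @export
closeness_centrality <- function(net, taxon = NULL,
                                 mode = c("topological", "weighted")) {
  mode <- match.arg(mode)
  g <- net_graph(net)
  if (!is.null(taxon)) check_taxon(g, taxon)
  d <- igraph::distances(g, weights = path_weights(g, mode))
  ncc <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (length(reach) == 0) 0 else 1 / mean(reach)
  })
  ncc <- stats::setNames(ncc, igraph::V(g)$name)
  if (is.null(taxon)) ncc else unname(ncc[taxon])
}

#' Node betweenness centrality (NBC)
#'
#' Fraction of shortest paths between other taxon pairs that pass through a
#' taxon, normalized by the number of such pairs in the taxon's connected
#' component, (nc - 1)(nc - 2)/2. For a connected network this equals
#' whole-graph normalization.
#'
#' @inheritParams closeness_centrality
#' @return NBC value(s) in `[0, 1]`.
#' @export
betweenness_centrality <- function(net, taxon = NULL,
                                   mode = c("topological", "weighted")) {
  mode <- match.arg(mode)
  g <- net_graph(net)
  if (!is.null(taxon)) check_taxon(g, taxon)
  raw <- igraph::betweenness(g, weights = path_weights(g, mode))
  comp <- igraph::components(g)
  nc <- comp$csize[comp$membership]
  norm <- (nc - 1) * (nc - 2) / 2
  nbc <- ifelse(norm > 0, raw / norm, 0)
  nbc <- stats::setNames(nbc, igraph::V(g)$name)
  if (is.null(taxon)) nbc else unname(nbc[taxon])
}

#' Global network attributes
#'
#' The seven whole-network descriptors used to compare class networks:
#' mean local clustering, degree centralization, count and coverage of
#' shortest paths (ordered reachable pairs), characteristic path length,
#' average number of neighbours, density, and degree heterogeneity
#' (coefficient of variation of the degree distribution, population variance).
#'
#' Isolated nodes are excluded from the computation by default (they carry no
#' interaction information and would deflate density-type metrics); set
#' `include_isolated = TRUE` to keep them.
#'
#' @param net an `interaction_network` (or igraph graph).
#' @param mode path-length mode, `"topological"` (default) or `"weighted"`.
#' @param include_isolated keep degree-0 nodes in the node set?
#' @return Object of class `global_network_attributes` (a list): `n_nodes`,
#'   `n_edges`, `clustering_coefficient`, `network_centralization`,
#'   `shortest_paths_count`, `shortest_paths_pct`,
#'   `characteristic_path_length`, `avg_neighbors`, `density`,
#'   `heterogeneity`, `n_isolated_excluded`. Path metrics are `NA` for an
#'   edgeless network.
#' @export
global_attributes <- function(net, mode = c("topological", "weighted"),
                              include_isolated = FALSE) {
  mode <- match.arg(mode)
  g <- net_graph(net)
  n_isolated <- sum(igraph::degree(g) == 0)
  if (!include_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  k <- igraph::degree(g)
  out <- list(n_nodes = n, n_edges = m,
              n_isolated_excluded = if (include_isolated) 0L else n_isolated)
  if (n == 0) {
    out[c("clustering_coefficient", "network_centralization",
          "shortest_paths_count", "shortest_paths_pct",
          "characteristic_path_length", "avg_neighbors", "density",
          "heterogeneity")] <- NA_real_
    return(structure(out, class = "global_network_attributes"))
  }
  kmax <- max(k)
  kbar <- mean(k)
  density <- if (n > 1) 2 * m / (n * (n - 1)) else NA_real_
  cc <- local_clustering(g)
  out$clustering_coefficient <- mean(cc)
  out$network_centralization <-
    if (n > 2) (n / (n - 2)) * (kmax / (n - 1) - density) else NA_real_
  out$avg_neighbors <- kbar
  out$density <- density
  out$heterogeneity <-
    if (kbar > 0) sqrt(mean((k - kbar)^2)) / kbar else NA_real_
  if (m == 0) {
    out$shortest_paths_count <- 0L
    out$shortest_paths_pct <- 0
    out$characteristic_path_length <- NA_real_
  } else {
    d <- igraph::distances(g, weights = path_weights(g, mode))
    finite <- is.finite(d) & d > 0
    out$shortest_paths_count <- as.integer(sum(finite))
    out$shortest_paths_pct <-
      if (n > 1) 100 * sum(finite) / (n * (n - 1)) else NA_real_
    out$characteristic_path_length <- mean(d[finite])
  }
  structure(out, class = "global_network_attributes")
}

#' @export
print.global_network_attributes <- function(x, ...) {
  cat(sprintf("nodes %d (isolated excluded: %d), edges %d\n",
              x$n_nodes, x$n_isolated_excluded, x$n_edges))
  rows <- c("Clustering coefficient"    = x$clustering_coefficient,
            "Network centralization"    = x$network_centralization,
            "Shortest paths"            = x$shortest_paths_count,
            "Shortest paths (%)"        = x$shortest_paths_pct,
            "Characteristic path length" = x$characteristic_path_length,
            "Average number of neighbors" = x$avg_neighbors,
            "Network density"           = x$density,
            "Network heterogeneity"     = x$heterogeneity)
  for (i in seq_along(rows))
    cat(sprintf("  %-28s %s\n", names(rows)[i], format(rows[i], digits = 4)))
  invisible(x)
}

#' Per-taxon node attribute table
#'
#' One record per node with the four nodal centrality attributes: NDC
#' (degree), NCC (closeness), NBC (betweenness) and CCF (local clustering).
#'
#' @inheritParams global_attributes
#' @param sort_by optional attribute name (`"NDC"`, `"NCC"`, `"NBC"`,
#'   `"CCF"`) to sort by, decreasing, ties broken by taxon name.
#' @return data.frame with columns taxon, NDC, NCC, NBC, CCF.
#' @export
node_table <- function(net, mode = c("topological", "weighted"),
                       sort_by = NULL) {
  mode <- match.arg(mode)
  g <- net_graph(net)
  if (igraph::vcount(g) == 0)
    return(data.frame(taxon = character(), NDC = integer(), NCC = numeric(),
                      NBC = numeric(), CCF = numeric(),
                      stringsAsFactors = FALSE))
  d <- data.frame(taxon = igraph::V(g)$name,
                  NDC = as.integer(igraph::degree(g)),
                  NCC = unname(closeness_centrality(g, mode = mode)),
                  NBC = unname(betweenness_centrality(g, mode = mode)),
                  CCF = unname(local_clustering(g)),
                  stringsAsFactors = FALSE)
  d <- if (is.null(sort_by)) d[order(d$taxon), ]
       else {
         stopifnot(sort_by %in% c("NDC", "NCC", "NBC", "CCF"))
         d[order(-d[[sort_by]], d$taxon), ]
       }
  rownames(d) <- NULL
  d
}

#' Compare class networks
#'
#' Aligns the global attributes of several class networks into one table and
#' lists, per class, the taxa exceeding centrality thresholds (the
#' "taxa with the highest net attribute" view).
#'
#' @param nets named list of `interaction_network` objects (>= 2).
#' @param mode path-length mode.
#' @param ndc_cut degree threshold for the top-taxa listing (default > 10).
#' @param nbc_cut betweenness threshold (default > 0.2).
#' @param ncc_cut closeness threshold; a single value or a named vector with
#'   one entry per class (default 0.4).
#' @return List with `attributes` (data.frame, one row per attribute, one
#'   column per class) and `top_taxa` (named list of node-attribute tables
#'   restricted to taxa passing any threshold).
#' @export
compare_classes <- function(nets, mode = c("topological", "weighted"),
                            ndc_cut = 10, nbc_cut = 0.2, ncc_cut = 0.4) {
  mode <- match.arg(mode)
  stopifnot(is.list(nets), length(nets) >= 2, !is.null(names(nets)))
  attrs <- lapply(nets, global_attributes, mode = mode)
  fields <- c("clustering_coefficient", "network_centralization",
              "shortest_paths_count", "shortest_paths_pct",
              "characteristic_path_length", "avg_neighbors", "density",
              "heterogeneity", "n_nodes", "n_edges")
  tab <- data.frame(attribute = fields,
                    sapply(attrs, function(a) unlist(a[fields])),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  cuts <- if (length(ncc_cut) == 1)
            stats::setNames(rep(ncc_cut, length(nets)), names(nets))
          else ncc_cut[names(nets)]
  top <- Map(function(net, cut) {
    nt <- node_table(net, mode = mode)
    nt[nt$NDC > ndc_cut | nt$NBC > nbc_cut | nt$NCC > cut, , drop = FALSE]
  }, nets, cuts)
  list(attributes = tab, top_taxa = top)
}
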