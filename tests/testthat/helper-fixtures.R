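# Build an interaction_network directly from an edge list, for metric tests.
# nodes: character vector; edges: data.frame(a, b) or a k x 2 matrix;
# r: correlation per edge (recycled), default 0.5.
make_net <- function(nodes, edges = NULL, r = 0.5) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    edges <- as.matrix(edges)
    r <- rep_len(r, nrow(edges))
    g <- igraph::add_edges(g, as.vector(t(edges)))
    g <- igraph::set_edge_attr(g, "r", value = r)
    g <- igraph::set_edge_attr(g, "sign",
                               value = ifelse(r > 0, "positive", "negative"))
    g <- igraph::set_edge_attr(g, "weight", value = abs(r))
  }
  structure(list(graph = g, n_samples = 84L, alpha = 0.05,
                 r_critical = critical_r(84, 0.05), method = "pearson"),
            class = "interaction_network")
}

star5 <- function() make_net(c("hub", "l1", "l2", "l3", "l4"),
                             cbind("hub", c("l1", "l2", "l3", "l4")))

path4 <- function() make_net(c("a", "b", "c", "d"),
                             cbind(c("a", "b", "c"), c("b", "c", "d")))

complete_net <- function(n) {
  nodes <- paste0("v", seq_len(n))
  idx <- t(utils::combn(n, 2))
  make_net(nodes, cbind(nodes[idx[, 1]], nodes[idx[, 2]]))
}

# Random connected graph as a 0/1 adjacency matrix (rejection sampling).
random_connected_adjacency <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    A <- A + t(A)
    # BFS connectivity check
    seen <- c(1L)
    frontier <- c(1L)
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(lapply(frontier,
                                          function(v) which(A[v, ] != 0)))),
                     seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) == n) {
      rownames(A) <- colnames(A) <- paste0("v", seq_len(n))
      return(A)
    }
  }
}

net_from_adjacency <- function(A, r = NULL) {
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  nodes <- rownames(A)
  if (is.null(r)) r <- stats::runif(nrow(idx), 0.3, 1) *
      sample(c(-1, 1), nrow(idx), replace = TRUE)
  make_net(nodes, cbind(nodes[idx[, 1]], nodes[idx[, 2]]), r = r)
}
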