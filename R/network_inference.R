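#' Autoscale a community matrix
#'
#' Standardizes every taxon column to zero mean and unit standard deviation
#' (the sample, n-1, convention), the normalisation applied before computing
#' the correlation matrix. Taxa with zero variance carry no correlation
#' information and are excluded and listed.
#'
#' @param x a [community_matrix()] or a plain samples x taxa numeric matrix.
#' @return A list with `scaled` (samples x retained taxa matrix) and
#'   `excluded` (character vector of constant taxa).
#' @export
autoscale <- function(x) {
  m <- if (inherits(x, "community_matrix")) x$biomass else as.matrix(x)
  if (nrow(m) < 2) stop("autoscaling needs at least 2 samples")
  sds <- apply(m, 2, stats::sd)
  excluded <- colnames(m)[sds == 0 | is.na(sds)]
  keep <- setdiff(colnames(m), excluded)
  scaled <- scale(m[, keep, drop = FALSE])
  attr(scaled, "scaled:center") <- NULL
  attr(scaled, "scaled:scale") <- NULL
  list(scaled = scaled, excluded = excluded)
}

#' Critical correlation coefficient at a given sample size
#'
#' Two-sided critical value of Pearson's r at significance level `alpha` for
#' `n` samples: r* = t*/sqrt(df + t*^2) with df = n - 2 and t* the
#' (1 - alpha/2) Student-t quantile. A pair of taxa is connected by an edge
#' iff |r| >= r*; this reproduces the "significant at P <= 0.05 for the
#' sample size in each class" edge rule as a threshold on |r|.
#'
#' @param n_samples number of samples (>= 4).
#' @param alpha two-sided significance level in (0, 1).
#' @return The critical |r| in (0, 1).
#' @examples
#' critical_r(84, 0.05)   # ~0.2146
#' @export
critical_r <- function(n_samples, alpha = 0.05) {
  stopifnot(is.numeric(n_samples), length(n_samples) == 1)
  if (n_samples < 4) stop("critical_r needs n_samples >= 4")
  stopifnot(alpha > 0, alpha < 1)
  df <- n_samples - 2
  tstar <- stats::qt(1 - alpha / 2, df = df)
  tstar / sqrt(df + tstar^2)
}

#' Pairwise correlation matrix of autoscaled taxa
#'
#' @param scaled samples x taxa numeric matrix (typically `autoscale()$scaled`;
#'   Pearson r is scale-invariant so raw columns give identical results).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `correlation_matrix`: list with `r` (symmetric
#'   matrix, unit diagonal), `n_samples`, `method`.
#' @export
correlation_matrix <- function(scaled, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scaled <- as.matrix(scaled)
  if (nrow(scaled) < 4) stop("correlation matrix needs >= 4 samples")
  if (ncol(scaled) < 2) stop("correlation matrix needs >= 2 taxa")
  r <- stats::cor(scaled, method = method)
  r <- (r + t(r)) / 2        # enforce exact symmetry
  diag(r) <- 1
  structure(list(r = r, n_samples = nrow(scaled), method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("correlation_matrix: %d taxa, n = %d (%s)\n",
              ncol(x$r), x$n_samples, x$method))
  invisible(x)
}

#' Build the signed interaction network
#'
#' Thresholds a correlation matrix at the critical value for its sample size:
#' every taxon pair with |r| >= r*(n, alpha) becomes an undirected edge
#' carrying the correlation `r`, its `sign` ("positive"/"negative") and
#' `weight` = |r|. Ties at the threshold are included. Isolated taxa stay in
#' the node set, flagged via degree 0.
#'
#' @param corr a [correlation_matrix()].
#' @param alpha two-sided significance level for edges (default 0.05).
#' @param keep_taxa optional character vector restricting the node set (e.g. a
#'   prevalence filter computed upstream).
#' @return An object of class `interaction_network`: list with `graph` (an
#'   igraph object whose edges carry r/sign/weight), `n_samples`, `alpha`,
#'   `r_critical`, `method`.
#' @export
build_network <- function(corr, alpha = 0.05, keep_taxa = NULL) {
  stopifnot(inherits(corr, "correlation_matrix"))
  r <- corr$r
  if (!is.null(keep_taxa)) {
    unknown <- setdiff(keep_taxa, colnames(r))
    if (length(unknown) > 0)
      stop("unknown taxa in keep_taxa: ", paste(unknown, collapse = ", "))
    r <- r[keep_taxa, keep_taxa, drop = FALSE]
  }
  rc <- critical_r(corr$n_samples, alpha)
  taxa <- colnames(r)
  idx <- which(upper.tri(r) & abs(r) >= rc, arr.ind = TRUE)
  # order edges deterministically by taxon names
  if (nrow(idx) > 0) idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rvals <- r[idx]
  g <- igraph::make_empty_graph(n = length(taxa), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = taxa)
  if (nrow(idx) > 0) {
    edges <- rbind(taxa[idx[, 1]], taxa[idx[, 2]])
    g <- igraph::add_edges(g, as.vector(edges))
    g <- igraph::set_edge_attr(g, "r", value = rvals)
    g <- igraph::set_edge_attr(g, "sign",
                               value = ifelse(rvals > 0, "positive",
                                              "negative"))
    g <- igraph::set_edge_attr(g, "weight", value = abs(rvals))
  }
  structure(list(graph = g, n_samples = corr$n_samples, alpha = alpha,
                 r_critical = rc, method = corr$method),
            class = "interaction_network")
}

#' Infer a network from a community matrix in one step
#'
#' Convenience wrapper: autoscale, correlate, apply the prevalence filter from
#' the configuration, threshold.
#'
#' @param x a [community_matrix()] (single class).
#' @param config a [zoonet_config()].
#' @return An `interaction_network`.
#' @export
infer_network <- function(x, config = zoonet_config()) {
  stopifnot(inherits(x, "community_matrix"))
  sc <- autoscale(x)
  keep <- colnames(sc$scaled)
  if (config$min_occurrence_fraction > 0) {
    occ <- colMeans(x$biomass[, keep, drop = FALSE] > 0)
    keep <- keep[occ >= config$min_occurrence_fraction]
  }
  if (length(keep) < 2) stop("fewer than 2 taxa pass the occurrence filter")
  corr <- correlation_matrix(sc$scaled[, keep, drop = FALSE],
                             method = config$correlation_method)
  build_network(corr, alpha = config$alpha)
}

#' @export
print.interaction_network <- function(x, ...) {
  g <- x$graph
  es <- igraph::edge_attr(g, "sign")
  cat(sprintf(paste0("interaction_network: %d taxa, %d edges ",
                     "(%d positive, %d negative)\n"),
              igraph::vcount(g), igraph::ecount(g),
              sum(es == "positive"), sum(es == "negative")))
  cat(sprintf("n = %d, alpha = %g, |r| threshold = %.4f\n",
              x$n_samples, x$alpha, x$r_critical))
  invisible(x)
}

#' Edge table of an interaction network
#'
#' @param net an `interaction_network`.
#' @return data.frame with columns taxon_a, taxon_b, r, weight, sign, ordered
#'   by taxon names.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- net$graph
  if (igraph::ecount(g) == 0)
    return(data.frame(taxon_a = character(), taxon_b = character(),
                      r = numeric(), weight = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  el <- igraph::as_edgelist(g)
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  d <- data.frame(taxon_a = el[, 1], taxon_b = el[, 2],
                  r = igraph::edge_attr(g, "r"),
                  weight = igraph::edge_attr(g, "weight"),
                  sign = igraph::edge_attr(g, "sign"),
                  stringsAsFactors = FALSE)
  d <- d[order(d$taxon_a, d$taxon_b), ]
  rownames(d) <- NULL
  d
}
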