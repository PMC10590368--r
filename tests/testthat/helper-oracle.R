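# Independent brute-force reference for all network metrics, built on
# explicit enumeration of simple paths (no igraph, no shared code with the
# package). Feasible for graphs up to ~8 nodes.

bf_all_paths <- function(A, s, t) {
  res <- list()
  rec <- function(path) {
    cur <- path[length(path)]
    if (cur == t) {
      res[[length(res) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (nb in which(A[cur, ] != 0))
      if (!(nb %in% path)) rec(c(path, nb))
  }
  rec(s)
  res
}

# All metrics from path enumeration on a 0/1 adjacency matrix.
bf_metrics <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A != 0)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw_raw <- numeric(n)
  if (n >= 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      paths <- bf_all_paths(A, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, 1L) - 1L
      L <- min(lens)
      dist[s, t] <- dist[t, s] <- L
      sp <- paths[lens == L]
      sigma <- length(sp)
      for (p in sp) {
        inner <- p[-c(1, length(p))]
        for (v in inner) btw_raw[v] <- btw_raw[v] + 1 / sigma
      }
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) if (comp[i] == 0L) {
    cid <- cid + 1L
    comp[is.finite(dist[i, ])] <- cid
  }
  csize <- as.integer(table(comp))[comp]
  norm <- (csize - 1) * (csize - 2) / 2
  nbc <- ifelse(norm > 0, btw_raw / norm, 0)
  ncc <- vapply(seq_len(n), function(v) {
    reach <- dist[v, ][is.finite(dist[v, ]) & dist[v, ] > 0]
    if (length(reach) == 0) 0 else 1 / mean(reach)
  }, 1.0)
  ccf <- vapply(seq_len(n), function(v) {
    nbs <- which(A[v, ] != 0)
    k <- length(nbs)
    if (k < 2) return(0)
    e_n <- sum(A[nbs, nbs] != 0) / 2
    e_n / (k * (k - 1) / 2)
  }, 1.0)
  m <- sum(A != 0) / 2
  kbar <- mean(deg)
  density <- if (n > 1) 2 * m / (n * (n - 1)) else NA_real_
  finite <- is.finite(dist) & dist > 0
  list(degree = deg, ncc = ncc, nbc = nbc, ccf = ccf,
       clustering_coefficient = mean(ccf),
       network_centralization =
         if (n > 2) (n / (n - 2)) * (max(deg) / (n - 1) - density)
         else NA_real_,
       shortest_paths_count = sum(finite),
       shortest_paths_pct = 100 * sum(finite) / (n * (n - 1)),
       characteristic_path_length =
         if (m > 0) mean(dist[finite]) else NA_real_,
       avg_neighbors = kbar, density = density,
       heterogeneity = if (kbar > 0) sqrt(mean((deg - kbar)^2)) / kbar
                       else NA_real_)
}

# Weighted shortest-path distances by path enumeration (W: weight matrix).
bf_weighted_dist <- function(A, W) {
  n <- nrow(A)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- bf_all_paths(A, s, t)
    if (length(paths) == 0) next
    wlen <- vapply(paths, function(p)
      sum(W[cbind(p[-length(p)], p[-1])]), 1.0)
    dist[s, t] <- dist[t, s] <- min(wlen)
  }
  dist
}
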