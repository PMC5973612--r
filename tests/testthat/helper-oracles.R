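# Brute-force oracles, independent of igraph's algorithms: everything here
# works on a plain 0/1 adjacency matrix.

adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# All-pairs shortest paths by Floyd-Warshall on the adjacency matrix.
oracle_cpl <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  ut <- d[upper.tri(d)]
  list(cpl = mean(ut[is.finite(ut)]), n_unreachable_pairs = sum(!is.finite(ut)))
}

# Average local clustering by explicit neighbour-pair enumeration.
oracle_cc <- function(g) {
  a <- adj_matrix(g)
  n <- nrow(a)
  cci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        if (a[nb[u], nb[v]] > 0) e <- e + 1
      }
    }
    cci[i] <- 2 * e / (k * (k - 1))
  }
  mean(cci)
}

# Distinct unordered non-loop pairs appearing in a directed link table.
oracle_projection_edges <- function(links) {
  keep <- links$resource != links$consumer
  a <- pmin(links$resource[keep], links$consumer[keep])
  b <- pmax(links$resource[keep], links$consumer[keep])
  length(unique(paste(a, b, sep = "\r")))
}

# Linear-interpolation quantile written out longhand (type-7 definition).
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Random simple undirected graph on n nodes with edge probability p.
random_small_graph <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p)
  a <- a + t(a)
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# Draws from the zeta (discrete power-law) distribution by inverse CDF.
sample_zeta <- function(n, alpha, kmin = 1, kmax = 100000) {
  ks <- kmin:kmax
  pk <- ks^(-alpha)
  cdf <- cumsum(pk) / sum(pk)
  ks[findInterval(stats::runif(n), cdf) + 1]
}
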