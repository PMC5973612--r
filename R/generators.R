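#' Synthetic control networks
#'
#' Generators for undirected simple graphs with known topology class, used
#' as positive and negative controls for the small-world test and the
#' degree-distribution fitter. All generators are deterministic for a fixed
#' `seed` and leave the caller's RNG state untouched.
#'
#' @name synthetic_networks
NULL

with_opt_seed <- function(seed, expr) {
  f <- function() expr
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}

check_ws_params <- function(n, k) {
  if (k < 2 || k %% 2 != 0) abort("`k` must be an even integer >= 2.")
  if (n <= k) abort("`n` must exceed `k`.")
}

#' @describeIn synthetic_networks Watts-Strogatz small-world graph: a ring
#'   lattice on `n` nodes with `k` neighbours each (k/2 per side), each edge
#'   rewired independently with probability `p`. Exactly nk/2 edges; the
#'   canonical positive control (high clustering, short paths for small
#'   p > 0).
#' @param n Number of nodes.
#' @param k Even number of lattice neighbours per node.
#' @param p Rewiring probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An undirected simple `igraph` graph.
#' @export
watts_strogatz <- function(n, k, p, seed = NULL) {
  check_ws_params(n, k)
  if (p < 0 || p > 1) abort("`p` must be in [0, 1].")
  with_opt_seed(seed, {
    igraph::sample_smallworld(dim = 1, size = n, nei = k / 2, p = p,
                              loops = FALSE, multiple = FALSE)
  })
}

#' @describeIn synthetic_networks Deterministic ring lattice (circulant
#'   graph): node i linked to its k/2 nearest neighbours on each side.
#'   Negative control: high clustering but long paths, so it must fail the
#'   CPL condition of the small-world test.
#' @export
ring_lattice <- function(n, k) {
  check_ws_params(n, k)
  igraph::make_lattice(length = n, dim = 1, nei = k / 2, periodic = TRUE)
}

#' @describeIn synthetic_networks Barabasi-Albert preferential attachment:
#'   growth with `m` edges per arriving node, giving a heavy-tailed
#'   (power-law-like) degree distribution. Edge count is approximately
#'   m(n - m) (early nodes attach to fewer than m targets).
#' @param m Edges added per new node (n > m >= 1).
#' @export
preferential_attachment <- function(n, m, seed = NULL) {
  if (m < 1 || n <= m) abort("Need n > m >= 1.")
  with_opt_seed(seed, {
    igraph::sample_pa(n, m = m, directed = FALSE)
  })
}

#' @describeIn synthetic_networks Uniform-degree graph: degrees drawn
#'   uniformly on \[d_min, d_max\] (sum forced even), realized as a simple
#'   graph by the configuration model with rejection/repair; up to
#'   `max_tries` redraws before erroring. Fixture for the uniform
#'   degree-distribution class.
#' @param d_min,d_max Degree range, 1 <= d_min <= d_max < n.
#' @param max_tries Redraw attempts before giving up.
#' @export
uniform_degree <- function(n, d_min, d_max, seed = NULL, max_tries = 50) {
  if (d_min < 1 || d_max < d_min || d_max >= n) {
    abort("Need 1 <= d_min <= d_max < n.")
  }
  with_opt_seed(seed, {
    for (try in seq_len(max_tries)) {
      # (sample(d_min:d_max) would misfire when d_min == d_max)
      degs <- d_min - 1L + sample.int(d_max - d_min + 1L, n, replace = TRUE)
      if (sum(degs) %% 2 == 1) {
        # repair parity: nudge one node up (or down at the ceiling)
        i <- sample.int(n, 1)
        degs[i] <- if (degs[i] < d_max) degs[i] + 1 else degs[i] - 1
      }
      g <- tryCatch(
        igraph::sample_degseq(degs, method = "fast.heur.simple"),
        error = function(e) NULL
      )
      if (!is.null(g) && igraph::is_simple(g)) return(g)
    }
    abort(sprintf("No simple realization found in %d tries.", max_tries))
  })
}

#' Orient an undirected graph into a directed trophic network
#'
#' Fixture helper: the empirical webs are directed (resource -> consumer)
#' while the generators above are undirected, so each edge is oriented
#' uniformly at random.
#'
#' @param g An undirected `igraph` graph.
#' @param seed Optional integer seed.
#' @param name Label for the resulting network.
#' @return A [trophic_network()] with L equal to the edge count of `g`.
#' @export
orient_random <- function(g, seed = NULL, name = "") {
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  el <- igraph::as_edgelist(g, names = FALSE)
  labels <- as.character(seq_len(igraph::vcount(g)))
  flip <- with_opt_seed(seed, stats::runif(nrow(el)) < 0.5)
  links <- data.frame(
    resource = labels[ifelse(flip, el[, 2], el[, 1])],
    consumer = labels[ifelse(flip, el[, 1], el[, 2])]
  )
  trophic_network(links, nodes = labels, name = name)
}

#' Write a graph as a plain-text edge list
#'
#' @param g An `igraph` graph or [trophic_network()].
#' @param path Output path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, delimiter = "\t") {
  if (inherits(g, "trophic_network")) {
    lines <- c(
      paste0("#nodes: ", paste(g$nodes, collapse = delimiter)),
      paste(g$links$resource, g$links$consumer, sep = delimiter)
    )
  } else {
    stopifnot(igraph::is_igraph(g))
    el <- igraph::as_edgelist(g)
    lines <- paste(el[, 1], el[, 2], sep = delimiter)
  }
  writeLines(lines, path)
  invisible(path)
}
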