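#' Connectance of a directed food web
#'
#' Connectance is the realized fraction of possible directed links,
#' C = L / S^2 (self-links are possible in a food web, hence the S^2
#' denominator rather than S(S-1)).
#'
#' @param S Number of nodes (trophic species), >= 1.
#' @param L Number of directed links, >= 0.
#' @return C = L / S^2.
#' @examples
#' connectance(27, 198) # 0.2716...
#' @export
connectance <- function(S, L) {
  if (length(S) != 1 || is.na(S) || S < 1) abort("`S` must be a single count >= 1.")
  if (length(L) != 1 || is.na(L) || L < 0) abort("`L` must be a single count >= 0.")
  L / S^2
}

#' Characteristic path length
#'
#' Mean shortest-path distance, counted in edges, over all unordered node
#' pairs that are mutually reachable. Unreachable pairs are excluded from
#' the average and reported separately (they are not assigned a penalty
#' distance), so CPL stays finite on fragmented webs.
#'
#' @param g An undirected simple `igraph` graph (see [to_projection()]).
#' @return A list with `cpl` (mean distance over reachable pairs) and
#'   `n_unreachable_pairs`. Errors if no pair is connected.
#' @examples
#' path3 <- igraph::make_graph(~ a - b - c)
#' characteristic_path_length(path3)$cpl # (1 + 1 + 2) / 3
#' @export
characteristic_path_length <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) < 2) abort("CPL needs at least 2 nodes.")
  d <- igraph::distances(g, mode = "all")
  ut <- d[upper.tri(d)]
  reachable <- is.finite(ut)
  if (!any(reachable)) abort("CPL undefined: no pair of nodes is connected.")
  list(
    cpl = mean(ut[reachable]),
    n_unreachable_pairs = sum(!reachable)
  )
}

#' Average clustering coefficient
#'
#' For each node i with degree Ki >= 2, the local coefficient is
#' CCi = 2 Ei / (Ki (Ki - 1)), where Ei is the number of edges among i's
#' neighbours. Nodes with degree < 2 contribute CCi = 0 (the zero
#' convention) and are included in the average over all S nodes; this is
#' what drags the mean down in webs dominated by poorly connected species.
#'
#' @param g An undirected simple `igraph` graph.
#' @return The mean of CCi over all nodes, in \[0, 1\].
#' @examples
#' clustering_coefficient(igraph::make_full_graph(3)) # 1
#' clustering_coefficient(igraph::make_star(5, mode = "undirected")) # 0
#' @export
clustering_coefficient <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) < 1) abort("Clustering needs at least 1 node.")
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' Degree sequence of a projection
#'
#' @param g An undirected simple `igraph` graph.
#' @return Integer vector of node degrees (one per node; sums to 2E).
#' @export
degree_sequence <- function(g) {
  stopifnot(igraph::is_igraph(g))
  as.integer(igraph::degree(g))
}

#' Summarize the topology of a food web
#'
#' Computes all structural properties used by the small-world test:
#' connectance from the directed link count, and characteristic path
#' length, clustering coefficient and degree sequence from the undirected
#' simple projection.
#'
#' @param net A [trophic_network()], or an igraph graph (taken as its own
#'   projection, with L = E).
#' @param name Optional label overriding the network's own.
#' @return An object of class `topology_summary` with fields `name`, `S`,
#'   `L`, `E` (projection edge count), `C`, `CPL`, `CC`, `degrees` and
#'   `n_unreachable_pairs`. Use [tidy()] for a one-row tibble.
#' @export
summarize_topology <- function(net, name = NULL) {
  if (igraph::is_igraph(net)) {
    g <- to_projection(net)
    S <- igraph::vcount(g)
    L <- igraph::ecount(g)
    label <- igraph::graph_attr(g, "name")
  } else {
    stopifnot(inherits(net, "trophic_network"))
    g <- to_projection(net)
    S <- net$S
    L <- net$L
    label <- net$name
  }
  if (!is.null(name)) label <- name
  if (is.null(label) || length(label) != 1 || is.na(label)) label <- ""
  pl <- characteristic_path_length(g)
  structure(
    list(
      name = label,
      S = S,
      L = L,
      E = igraph::ecount(g),
      C = connectance(S, L),
      CPL = pl$cpl,
      CC = clustering_coefficient(g),
      degrees = degree_sequence(g),
      n_unreachable_pairs = pl$n_unreachable_pairs
    ),
    class = "topology_summary"
  )
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(
    "<topology_summary> %s: S = %d, L = %d, C = %.3f, CPL = %.3f, CC = %.3f\n",
    if (nzchar(x$name)) x$name else "(unnamed)", x$S, x$L, x$C, x$CPL, x$CC
  ))
  if (x$n_unreachable_pairs > 0) {
    cat(sprintf("  %d unreachable pair(s) excluded from CPL\n",
                x$n_unreachable_pairs))
  }
  invisible(x)
}

#' @rdname summarize_topology
#' @param x A `topology_summary`.
#' @param ... Unused.
#' @export
tidy.topology_summary <- function(x, ...) {
  tibble(
    name = x$name, S = x$S, L = x$L, E = x$E, C = x$C,
    CPL = x$CPL, CC = x$CC,
    n_unreachable_pairs = x$n_unreachable_pairs
  )
}
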