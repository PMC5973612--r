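#' Construct a trophic network from a link table
#'
#' A trophic network is a directed graph of feeding links: each row of
#' `links` is one resource -> consumer pair. Node identity is the opaque,
#' case-sensitive label; no taxonomic interpretation is attempted.
#' Duplicate directed links are collapsed with a warning.
#'
#' @param links A data frame whose first two columns are resource and
#'   consumer labels (coerced to character). Extra columns are ignored.
#' @param nodes Optional character vector of node labels; must contain every
#'   link endpoint. Use it to declare isolated nodes.
#' @param name Label for the web (used in result tables).
#' @return An object of class `trophic_network` with fields `name`, `nodes`,
#'   `links` (tibble with columns `resource`, `consumer`), `S` (node count),
#'   `L` (directed link count, self-loops included) and `n_self_loops`.
#' @examples
#' net <- trophic_network(data.frame(resource = c("a", "b"), consumer = c("b", "c")))
#' net$S # 3
#' net$L # 2
#' @export
trophic_network <- function(links, nodes = NULL, name = "") {
  if (!is.data.frame(links) || ncol(links) < 2) {
    abort("`links` must be a data frame with at least two columns (resource, consumer).")
  }
  resource <- as.character(links[[1]])
  consumer <- as.character(links[[2]])
  if (anyNA(resource) || anyNA(consumer)) {
    abort("Link endpoints must not be missing.")
  }
  key <- paste(resource, consumer, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warn(sprintf("Collapsed %d duplicate link(s).", sum(dup)))
    resource <- resource[!dup]
    consumer <- consumer[!dup]
  }
  endpoint_labels <- unique(c(resource, consumer))
  if (is.null(nodes)) {
    nodes <- endpoint_labels
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) abort("Node labels must be unique.")
    missing <- setdiff(endpoint_labels, nodes)
    if (length(missing) > 0) {
      abort(sprintf(
        "Link endpoints not declared in `nodes`: %s",
        paste(utils::head(missing, 5), collapse = ", ")
      ))
    }
  }
  if (length(nodes) < 1) abort("A network needs at least one node.")
  structure(
    list(
      name = as.character(name),
      nodes = nodes,
      links = tibble(resource = resource, consumer = consumer),
      S = length(nodes),
      L = length(resource),
      n_self_loops = sum(resource == consumer)
    ),
    class = "trophic_network"
  )
}

#' @export
print.trophic_network <- function(x, ...) {
  cat(sprintf(
    "<trophic_network> %s: S = %d nodes, L = %d directed links (%d self-loop%s)\n",
    if (nzchar(x$name)) x$name else "(unnamed)",
    x$S, x$L, x$n_self_loops, if (x$n_self_loops == 1) "" else "s"
  ))
  invisible(x)
}

#' Read a food web from a delimited edge list
#'
#' Parses a plain-text edge list with one resource/consumer pair per row.
#' Lines starting with `#` are comments, except for an optional node
#' declaration of the form `#nodes: a<delim>b<delim>c` which registers labels
#' (so isolated nodes survive the round trip). A third column, if present, is
#' ignored (interaction strength in some deposits).
#'
#' @param path Path to the file.
#' @param delimiter Field separator (default tab).
#' @param directed Ignored for parsing (links are stored as written); kept so
#'   callers can document intent. Default `TRUE`.
#' @param name Web label; defaults to the file name without extension.
#' @return A [trophic_network()].
#' @export
read_edge_list <- function(path, delimiter = "\t", directed = TRUE,
                           name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  declared <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]], which = "right")
    if (!nzchar(trimws(line))) next
    if (startsWith(trimws(line), "#")) {
      body <- sub("^\\s*#\\s*", "", line)
      if (grepl("^nodes?:", body, ignore.case = TRUE)) {
        labels <- strsplit(sub("^nodes?:\\s*", "", body, ignore.case = TRUE),
                           delimiter, fixed = TRUE)[[1]]
        declared <- c(declared, trimws(labels[nzchar(trimws(labels))]))
      }
      next
    }
    fields <- strsplit(line, delimiter, fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 2 || !nzchar(fields[1]) || !nzchar(fields[2])) {
      abort(sprintf("Malformed row at line %d of %s: need at least 2 fields.",
                    i, path))
    }
    rows[[length(rows) + 1]] <- fields[1:2]
  }
  if (length(rows) == 0 && length(declared) == 0) {
    abort(sprintf("No links or node declarations found in %s", path))
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  m <- do.call(rbind, rows)
  links <- if (is.null(m)) {
    data.frame(resource = character(), consumer = character())
  } else {
    data.frame(resource = m[, 1], consumer = m[, 2])
  }
  nodes <- unique(c(links$resource, links$consumer, declared))
  trophic_network(links, nodes = nodes, name = name)
}

#' Read a food web from a binary adjacency matrix
#'
#' The file must be a square 0/1 matrix in CSV form with node labels as both
#' header row and first column; entry (i, j) = 1 is read as the directed link
#' i -> j. Diagonal ones become self-loops (cannibalism) and are counted in
#' `n_self_loops`.
#'
#' @param path Path to the CSV file.
#' @param name Web label; defaults to the file name without extension.
#' @return A [trophic_network()].
#' @export
read_adjacency_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Adjacency matrix must be square; got %d x %d.",
                  nrow(m), ncol(m)))
  }
  if (!identical(rownames(m), colnames(m))) {
    abort("Row and column labels of the adjacency matrix must match.")
  }
  suppressWarnings(storage.mode(m) <- "numeric")
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    abort("Adjacency matrix entries must be 0 or 1.")
  }
  idx <- which(m == 1, arr.ind = TRUE)
  links <- data.frame(
    resource = rownames(m)[idx[, 1]],
    consumer = colnames(m)[idx[, 2]]
  )
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  trophic_network(links, nodes = rownames(m), name = name)
}

#' Project a trophic network onto its undirected simple graph
#'
#' All structural metrics (characteristic path length, clustering, degree)
#' are defined on the undirected simple projection: self-loops are dropped
#' and reciprocal link pairs (a -> b and b -> a) are merged into one edge.
#' The directed link count L is untouched (connectance uses it).
#'
#' @param net A [trophic_network()] or an igraph graph.
#' @return An undirected simple `igraph` graph with graph attributes
#'   `loops_dropped` and `reciprocal_merged` recording what the projection
#'   removed, and `name` carried over.
#' @examples
#' net <- trophic_network(
#'   data.frame(resource = c("a", "b", "a"), consumer = c("b", "a", "a"))
#' )
#' g <- to_projection(net)
#' igraph::ecount(g) # 1
#' @export
to_projection <- function(net) {
  if (igraph::is_igraph(net)) {
    g <- net
    if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
    return(g)
  }
  stopifnot(inherits(net, "trophic_network"))
  g <- igraph::graph_from_data_frame(
    net$links, directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  loops <- net$n_self_loops
  und <- igraph::as_undirected(g, mode = "collapse")
  und <- igraph::simplify(und, remove.multiple = TRUE, remove.loops = TRUE)
  merged <- (net$L - loops) - igraph::ecount(und)
  und <- igraph::set_graph_attr(und, "loops_dropped", loops)
  und <- igraph::set_graph_attr(und, "reciprocal_merged", merged)
  und <- igraph::set_graph_attr(und, "name", net$name)
  und
}

#' Write a per-web results table to CSV
#'
#' @param rows A data frame of per-web result records (one row per web), as
#'   produced by [run_analysis()].
#' @param path Output file path.
#' @param digits Decimal places for floating-point columns (default 2,
#'   the conventional reporting precision for these metrics).
#' @return `rows` (rounded), invisibly.
#' @export
write_results_table <- function(rows, path, digits = 2) {
  stopifnot(is.data.frame(rows))
  out <- dplyr::mutate(
    as_tibble(rows),
    dplyr::across(dplyr::where(is.double), ~ round(.x, digits))
  )
  readr::write_csv(out, path)
  invisible(out)
}
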