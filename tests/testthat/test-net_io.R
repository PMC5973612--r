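test_that("edge lists are parsed, deduplicated, and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "a\tb", "b\tc", "a\tc\t0.5"), path)
  net <- read_edge_list(path)
  expect_s3_class(net, "trophic_network")
  expect_equal(net$S, 3)
  expect_equal(net$L, 3)

  writeLines(c("a\tb", "a\tb"), path)
  expect_warning(net <- read_edge_list(path), "1 duplicate")
  expect_equal(net$S, 2)
  expect_equal(net$L, 1)

  writeLines(c("a\tb", "only-one-field"), path)
  expect_error(read_edge_list(path), "line 2")
  writeLines(character(), path)
  expect_error(read_edge_list(path), "No links")

  # node declarations keep isolated species
  writeLines(c("#nodes: a\tb\tc\td", "a\tb"), path)
  net <- read_edge_list(path)
  expect_equal(net$S, 4)
  expect_equal(net$L, 1)
})

test_that("a generated 33-node 183-link web round-trips through disk", {
  # same (S, L) shape as a subpolar channel web: 33 species, 183 links
  net <- orient_random(generate_er(33, 183, seed = 11), seed = 12,
                       name = "fixture33")
  expect_equal(net$S, 33)
  expect_equal(net$L, 183)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- read_edge_list(path, name = "fixture33")
  expect_equal(back$S, net$S)
  expect_equal(back$L, net$L)
  expect_setequal(back$nodes, net$nodes)
})

test_that("adjacency matrices are read with self-loops flagged", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(0L, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  m["a", "b"] <- 1L
  m["b", "c"] <- 1L
  write.csv(m, path)
  net <- read_adjacency_matrix(path)
  expect_equal(net$S, 3)
  expect_equal(net$L, 2)
  expect_equal(net$n_self_loops, 0)

  m["c", "c"] <- 1L
  write.csv(m, path)
  expect_equal(read_adjacency_matrix(path)$n_self_loops, 1)

  m4 <- matrix(1L, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m4) <- 0L
  write.csv(m4, path)
  expect_equal(read_adjacency_matrix(path)$L, 12)

  write.csv(m4[, 1:3], path)
  expect_error(read_adjacency_matrix(path), "square")
  m4[1, 2] <- 2L
  write.csv(m4, path)
  expect_error(read_adjacency_matrix(path), "0 or 1")
})

test_that("projection drops loops, merges reciprocals, and is idempotent", {
  net <- trophic_network(
    data.frame(resource = c("a", "b", "a"), consumer = c("b", "a", "a"))
  )
  g <- to_projection(net)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::graph_attr(g, "loops_dropped"), 1)
  expect_equal(igraph::graph_attr(g, "reciprocal_merged"), 1)

  chain <- trophic_network(
    data.frame(resource = c("a", "b"), consumer = c("b", "c"))
  )
  expect_equal(igraph::ecount(to_projection(chain)), 2)

  # projecting an already-simple undirected graph changes nothing
  g2 <- to_projection(g)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  lat <- ring_lattice(12, 4)
  sorted_edges <- function(g) {
    el <- igraph::as_edgelist(g)
    el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  expect_equal(sorted_edges(to_projection(lat)), sorted_edges(lat))
})

test_that("projection edge count matches set-comparison oracle on random webs", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      links <- data.frame(
        resource = as.character(sample.int(50, 300, replace = TRUE)),
        consumer = as.character(sample.int(50, 300, replace = TRUE))
      )
      links <- links[!duplicated(links), ]
      net <- trophic_network(links, nodes = as.character(1:50))
      g <- to_projection(net)
      expect_equal(igraph::ecount(g), oracle_projection_edges(net$links))
      expect_lte(igraph::ecount(g), net$L)
    }
  })
})

test_that("results tables round-trip at the printed precision", {
  rows <- tibble::tibble(
    name = c("webA", "webB"), S = c(33L, 27L), L = c(183L, 198L),
    C = c(0.168044, 0.271605), CPL = c(1.4637, 1.5313),
    CC = c(0.3211, 0.6644), DD_best_model = c("uniform", "poisson"),
    CPL_ratio = c(0.98123, 1.0511), CC_ratio = c(1.3517, 0.911),
    SW_conf = c(TRUE, FALSE), SWS = c(1.377, 0.87), SW_sws = c(TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_results_table(rows, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$C, round(rows$C, 2))
  expect_equal(back$S, rows$S)
  expect_equal(back$SW_conf, rows$SW_conf)
  expect_equal(nrow(write_results_table(rows[0, ], path)), 0)
  expect_equal(nrow(readr::read_csv(path, show_col_types = FALSE)), 0)
})
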