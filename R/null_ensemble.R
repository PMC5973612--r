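#' Generate one Erdos-Renyi G(n, M) random graph
#'
#' Samples uniformly from all simple undirected graphs with exactly `S`
#' nodes and `L` edges — the null model matched on size and link count.
#'
#' @param S Node count.
#' @param L Edge count, 0 <= L <= S(S-1)/2.
#' @param seed Optional integer; when given, the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return An undirected simple `igraph` graph.
#' @export
generate_er <- function(S, L, seed = NULL) {
  max_edges <- S * (S - 1) / 2
  if (L < 0 || L > max_edges) {
    abort(sprintf("`L` must be between 0 and S(S-1)/2 = %d.", max_edges))
  }
  draw <- function() igraph::sample_gnm(S, L, directed = FALSE, loops = FALSE)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Empirical percentile confidence interval
#'
#' Two-sided interval between the (1-level)/2 and 1-(1-level)/2 empirical
#' quantiles of a Monte-Carlo replicate vector, using linear interpolation
#' between order statistics (R quantile type 7).
#'
#' @param values Numeric vector of replicate values (length >= 2).
#' @param level Coverage probability in (0, 1); default 0.99.
#' @return Numeric vector `c(low, high)`.
#' @export
percentile_ci <- function(values, level = 0.99) {
  if (length(values) < 2) abort("Need at least 2 values for a percentile CI.")
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    abort("`level` must be in (0, 1).")
  }
  alpha <- (1 - level) / 2
  unname(quantile(values, probs = c(alpha, 1 - alpha), type = 7, names = FALSE))
}

new_sw_ensemble <- function(metric, replicates, level, n_rep, seed, S, L,
                            n_skipped = 0L) {
  ci <- percentile_ci(replicates, level)
  structure(
    list(
      metric = metric,
      replicates = replicates,
      mean = mean(replicates),
      ci_low = ci[1],
      ci_high = ci[2],
      level = level,
      n_rep = n_rep,
      n_skipped = n_skipped,
      seed = seed,
      S = S,
      L = L
    ),
    class = "sw_ensemble"
  )
}

#' Null distributions of CPL and CC from matched random graphs
#'
#' Generates `n_rep` Erdos-Renyi G(S, L) graphs and computes the
#' characteristic path length and clustering coefficient of each, giving
#' the Monte-Carlo null distributions the empirical web is tested against.
#' Replicate r uses a sub-seed drawn deterministically from `seed`, so
#' results are reproducible and extending `n_rep` keeps the earlier
#' replicates unchanged.
#'
#' @param S,L Matched node and edge counts for the null model. `L` is an
#'   undirected edge count: pass the projection's E, or the web's raw
#'   directed L to treat printed link counts as edges (see
#'   [run_analysis()]'s `null_edges`).
#' @param n_rep Number of replicates (default 1000).
#' @param seed Integer seed for the ensemble.
#' @param level CI coverage (default 0.99).
#' @return A list with components `cpl` and `cc`, each an `sw_ensemble`
#'   holding the replicate values, their mean and the percentile CI.
#'   Replicates in which no node pair is connected are skipped; more than
#'   1 percent skipped is an error.
#' @examples
#' ens <- ensemble_metrics(30, 60, n_rep = 50, seed = 1)
#' ens$cc$mean # close to 60 / choose(30, 2)
#' @export
ensemble_metrics <- function(S, L, n_rep = 1000, seed = 1, level = 0.99) {
  if (n_rep < 2) abort("`n_rep` must be at least 2.")
  sub_seeds <- withr::with_seed(seed, sample.int(2147483646L, n_rep))
  cpl <- numeric(0)
  cc <- numeric(0)
  skipped <- 0L
  for (r in seq_len(n_rep)) {
    g <- generate_er(S, L, seed = sub_seeds[r])
    res <- tryCatch(characteristic_path_length(g), error = function(e) NULL)
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    cpl <- c(cpl, res$cpl)
    cc <- c(cc, clustering_coefficient(g))
  }
  if (skipped > 0.01 * n_rep) {
    abort(sprintf("%d of %d replicates had no connected pair; null model %s",
                  skipped, n_rep, "is degenerate for these (S, L)."))
  }
  list(
    cpl = new_sw_ensemble("CPL", cpl, level, n_rep, seed, S, L, skipped),
    cc = new_sw_ensemble("CC", cc, level, n_rep, seed, S, L, skipped)
  )
}

#' @export
print.sw_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sw_ensemble> %s over %d ER(S = %d, L = %d) graphs: mean %.4f, %.0f%% CI [%.4f, %.4f]\n",
    x$metric, length(x$replicates), x$S, x$L, x$mean, 100 * x$level,
    x$ci_low, x$ci_high
  ))
  invisible(x)
}

#' @rdname ensemble_metrics
#' @param x An `sw_ensemble`.
#' @param ... Unused.
#' @export
tidy.sw_ensemble <- function(x, ...) {
  tibble(
    metric = x$metric, S = x$S, L = x$L,
    n_rep = length(x$replicates), n_skipped = x$n_skipped,
    mean = x$mean, ci_low = x$ci_low, ci_high = x$ci_high,
    level = x$level, seed = x$seed
  )
}

#' Histogram of ensemble replicates with the percentile CI
#'
#' @param object An `sw_ensemble` from [ensemble_metrics()].
#' @param empirical Optional empirical metric value to mark on the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sw_ensemble <- function(object, empirical = NULL, ...) {
  df <- tibble(value = object$replicates)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = object$metric, y = "replicates",
      title = sprintf("%s null distribution, ER(S = %d, L = %d)",
                      object$metric, object$S, object$L),
      subtitle = sprintf("dashed: %.0f%% percentile CI", 100 * object$level)
    )
  if (!is.null(empirical)) {
    p <- p + ggplot2::geom_vline(xintercept = empirical, colour = "red")
  }
  p
}
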