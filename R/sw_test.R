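check_matched <- function(topo, ens) {
  if (ens$S != topo$S) {
    abort(sprintf("Ensemble S = %d does not match the web's S = %d.",
                  ens$S, topo$S))
  }
  if (!ens$L %in% c(topo$L, topo$E)) {
    abort(sprintf(
      "Ensemble L = %d matches neither the web's raw L = %d nor its projection E = %d.",
      ens$L, topo$L, topo$E
    ))
  }
  invisible(TRUE)
}

#' Confidence-interval small-world classification
#'
#' The CI rule: a web is small-world when its empirical CPL lies within or
#' below the 99% percentile CI of the random CPL (CPL_emp <= ci_high,
#' non-strict) AND its empirical CC lies above the 99% CI of the random CC
#' (CC_emp > ci_high, strict). Ratios against the ensemble means (the
#' lambda/gamma coordinates) are reported alongside but play no role in
#' the rule itself.
#'
#' @param topo A `topology_summary` from [summarize_topology()].
#' @param cpl_ens,cc_ens `sw_ensemble` objects from [ensemble_metrics()],
#'   generated with matched (S, L).
#' @return A list with `cpl_ratio`, `cc_ratio`, `cpl_ok`, `cc_ok`,
#'   `is_small_world_conf`.
#' @export
classify_conf <- function(topo, cpl_ens, cc_ens) {
  stopifnot(inherits(topo, "topology_summary"))
  check_matched(topo, cpl_ens)
  check_matched(topo, cc_ens)
  cpl_ok <- topo$CPL <= cpl_ens$ci_high
  cc_ok <- topo$CC > cc_ens$ci_high
  list(
    cpl_ratio = topo$CPL / cpl_ens$mean,
    cc_ratio = topo$CC / cc_ens$mean,
    cpl_ok = cpl_ok,
    cc_ok = cc_ok,
    is_small_world_conf = cpl_ok && cc_ok
  )
}

#' Humphries-Gurney small-world-ness
#'
#' S^ws = (CC_emp / mean CC_rand) / (CPL_emp / mean CPL_rand), i.e. the
#' clustering ratio over the path-length ratio. The null distribution of
#' S^ws is obtained by scoring every random replicate against the ensemble
#' means; the web is small-world under this criterion when S^ws > 1 and
#' S^ws exceeds the upper bound of the null's 99% CI.
#'
#' @inheritParams classify_conf
#' @return A list with `sws`, `sws_ci_high`, `is_small_world_sws` and the
#'   null replicate values `sws_null`. A zero random-CC mean makes S^ws
#'   undefined: `sws` is `NA` and the classification `FALSE`.
#' @export
small_world_ness <- function(topo, cpl_ens, cc_ens) {
  stopifnot(inherits(topo, "topology_summary"))
  check_matched(topo, cpl_ens)
  check_matched(topo, cc_ens)
  if (cc_ens$mean <= 0 || cpl_ens$mean <= 0) {
    warn("Zero ensemble mean: S^ws undefined for this web.")
    return(list(sws = NA_real_, sws_ci_high = NA_real_,
                is_small_world_sws = FALSE, sws_null = numeric(0)))
  }
  sws <- (topo$CC / cc_ens$mean) / (topo$CPL / cpl_ens$mean)
  n <- min(length(cpl_ens$replicates), length(cc_ens$replicates))
  sws_null <- (cc_ens$replicates[seq_len(n)] / cc_ens$mean) /
    (cpl_ens$replicates[seq_len(n)] / cpl_ens$mean)
  sws_null <- sws_null[is.finite(sws_null)]
  ci_high <- percentile_ci(sws_null, cc_ens$level)[2]
  list(
    sws = sws,
    sws_ci_high = ci_high,
    is_small_world_sws = sws > 1 && sws > ci_high,
    sws_null = sws_null
  )
}

#' Full small-world verdict for one web
#'
#' Applies both criteria — the CI rule ([classify_conf()]) and the
#' small-world-ness metric ([small_world_ness()]) — and bundles the result.
#'
#' @inheritParams classify_conf
#' @return An object of class `sw_verdict`; use [tidy()] for a one-row
#'   tibble with columns `name`, `cpl_ratio`, `cc_ratio`, `cpl_ok`,
#'   `cc_ok`, `sw_conf`, `sws`, `sws_ci_high`, `sw_sws`.
#' @export
sw_classify <- function(topo, cpl_ens, cc_ens) {
  conf <- classify_conf(topo, cpl_ens, cc_ens)
  sws <- small_world_ness(topo, cpl_ens, cc_ens)
  structure(
    c(list(name = topo$name), conf, sws[c("sws", "sws_ci_high",
                                          "is_small_world_sws")]),
    class = "sw_verdict"
  )
}

#' @export
print.sw_verdict <- function(x, ...) {
  cat(sprintf(
    paste0("<sw_verdict> %s: CPL ratio %.2f (ok: %s), CC ratio %.2f (ok: %s)",
           " -> SW(conf) = %s; S^ws = %.2f (CI high %.2f) -> SW(sws) = %s\n"),
    if (nzchar(x$name)) x$name else "(unnamed)",
    x$cpl_ratio, x$cpl_ok, x$cc_ratio, x$cc_ok, x$is_small_world_conf,
    x$sws, x$sws_ci_high, x$is_small_world_sws
  ))
  invisible(x)
}

#' @rdname sw_classify
#' @param x An `sw_verdict`.
#' @param ... Unused.
#' @export
tidy.sw_verdict <- function(x, ...) {
  tibble(
    name = x$name,
    cpl_ratio = x$cpl_ratio, cc_ratio = x$cc_ratio,
    cpl_ok = x$cpl_ok, cc_ok = x$cc_ok,
    sw_conf = x$is_small_world_conf,
    sws = x$sws, sws_ci_high = x$sws_ci_high,
    sw_sws = x$is_small_world_sws
  )
}

#' Compare the two small-world criteria across webs
#'
#' @param verdicts A list of `sw_verdict` objects (or an `sw_analysis`).
#' @return A list with `counts` (webs classified small-world under each
#'   criterion) and `disagreements` (tibble of webs where the criteria
#'   differ).
#' @export
compare_methods <- function(verdicts) {
  if (inherits(verdicts, "sw_analysis")) verdicts <- verdicts$verdicts
  stopifnot(length(verdicts) >= 1)
  tab <- purrr::map_dfr(verdicts, tidy)
  counts <- tibble(
    method = c("ci_rule", "small_world_ness"),
    n_small_world = c(sum(tab$sw_conf, na.rm = TRUE),
                      sum(tab$sw_sws, na.rm = TRUE)),
    n_webs = nrow(tab)
  )
  disagreements <- dplyr::filter(
    dplyr::select(tab, "name", "sw_conf", "sw_sws"),
    .data$sw_conf != .data$sw_sws
  )
  list(counts = counts, disagreements = disagreements)
}
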