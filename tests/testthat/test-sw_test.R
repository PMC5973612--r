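# Forged ensembles with known means/CIs for rule-application tests.
fake_ens <- function(metric, values, S, L, level = 0.99) {
  swnet:::new_sw_ensemble(metric, values, level, length(values), 1L, S, L)
}

fake_topo <- function(S, L, E, CPL, CC, name = "web") {
  structure(
    list(name = name, S = S, L = L, E = E, C = L / S^2, CPL = CPL, CC = CC,
         degrees = integer(S), n_unreachable_pairs = 0L),
    class = "topology_summary"
  )
}

test_that("the CI rule applies the stated inequalities", {
  cpl_ens <- fake_ens("CPL", seq(2.0, 2.5, length.out = 500), 50, 100)
  cc_ens <- fake_ens("CC", seq(0.05, 0.10, length.out = 500), 50, 100)

  # empirical CPL below the CI, CC above it -> small-world
  v <- classify_conf(fake_topo(50, 100, 100, 1.8, 0.30), cpl_ens, cc_ens)
  expect_true(v$cpl_ok)
  expect_true(v$cc_ok)
  expect_true(v$is_small_world_conf)

  # CC inside the CI -> not small-world
  v <- classify_conf(fake_topo(50, 100, 100, 1.8, 0.08), cpl_ens, cc_ens)
  expect_false(v$cc_ok)
  expect_false(v$is_small_world_conf)

  # CPL within the CI still passes (non-strict "within or to the left")
  v <- classify_conf(fake_topo(50, 100, 100, 2.3, 0.30), cpl_ens, cc_ens)
  expect_true(v$cpl_ok)

  # CC equal to ci_high fails (strict "to the right")
  v <- classify_conf(fake_topo(50, 100, 100, 1.8, cc_ens$ci_high),
                     cpl_ens, cc_ens)
  expect_false(v$cc_ok)

  # mismatched ensemble is an error
  expect_error(classify_conf(fake_topo(60, 100, 100, 1.8, 0.3),
                             cpl_ens, cc_ens), "match")
})

test_that("classification is monotone in the empirical metrics", {
  cpl_ens <- fake_ens("CPL", seq(2.0, 2.5, length.out = 500), 50, 100)
  cc_ens <- fake_ens("CC", seq(0.05, 0.10, length.out = 500), 50, 100)
  cc_grid <- seq(0.01, 0.4, length.out = 40)
  ok <- vapply(cc_grid, function(cc) {
    classify_conf(fake_topo(50, 100, 100, 2.0, cc), cpl_ens, cc_ens)$cc_ok
  }, logical(1))
  expect_true(all(diff(ok) >= 0)) # false -> true only, never back
  cpl_grid <- seq(3.5, 1.0, length.out = 40)
  ok <- vapply(cpl_grid, function(cpl) {
    classify_conf(fake_topo(50, 100, 100, cpl, 0.3), cpl_ens, cc_ens)$cpl_ok
  }, logical(1))
  expect_true(all(diff(ok) >= 0))
})

test_that("small-world-ness is the clustering ratio over the path ratio", {
  cpl_ens <- fake_ens("CPL", seq(2.0, 2.5, length.out = 500), 39, 100)
  cc_ens <- fake_ens("CC", seq(0.05, 0.10, length.out = 500), 39, 100)
  # cc_ratio == cpl_ratio -> S^ws = 1
  topo <- fake_topo(39, 100, 100, 1.5 * cpl_ens$mean, 1.5 * cc_ens$mean)
  expect_equal(small_world_ness(topo, cpl_ens, cc_ens)$sws, 1)

  # ratios 1.35 / 0.98 (a temperate shelf web's printed coordinates)
  topo <- fake_topo(39, 100, 100, 0.98 * cpl_ens$mean, 1.35 * cc_ens$mean)
  res <- small_world_ness(topo, cpl_ens, cc_ens)
  expect_equal(res$sws, 1.35 / 0.98, tolerance = 1e-12)
  expect_equal(round(res$sws, 4), 1.3776)

  # zero random clustering -> undefined, classification FALSE
  cc_zero <- fake_ens("CC", rep(0, 500), 39, 100)
  expect_warning(res <- small_world_ness(topo, cpl_ens, cc_zero), "undefined")
  expect_true(is.na(res$sws))
  expect_false(res$is_small_world_sws)
})

test_that("an ER graph scored against its own ensemble has S^ws near 1", {
  S <- 50
  L <- 150
  ens <- ensemble_metrics(S, L, n_rep = 300, seed = 17)
  sws_vals <- withr::with_seed(18, replicate(30, {
    topo <- summarize_topology(generate_er(S, L))
    sw_classify(topo, ens$cpl, ens$cc)$sws
  }))
  expect_equal(mean(sws_vals), 1, tolerance = 0.1)
})

test_that("ring lattices pass the clustering test but fail the path test", {
  topo <- summarize_topology(ring_lattice(100, 6))
  ens <- ensemble_metrics(100, 300, n_rep = 300, seed = 19)
  v <- sw_classify(topo, ens$cpl, ens$cc)
  expect_true(v$cc_ok)
  expect_false(v$cpl_ok)
  expect_false(v$is_small_world_conf)
})

test_that("rewired lattices register as small-world by S^ws", {
  ens <- ensemble_metrics(100, 300, n_rep = 300, seed = 23)
  hits <- vapply(1:20, function(s) {
    topo <- summarize_topology(watts_strogatz(100, 6, 0.05, seed = 100 + s))
    sw_classify(topo, ens$cpl, ens$cc)$is_small_world_sws
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("method comparison counts criteria and lists disagreements", {
  mk <- function(name, conf, sws) {
    structure(list(name = name, cpl_ratio = 1, cc_ratio = 1, cpl_ok = conf,
                   cc_ok = conf, is_small_world_conf = conf, sws = 1.5,
                   sws_ci_high = 1.2, is_small_world_sws = sws),
              class = "sw_verdict")
  }
  res <- compare_methods(list(mk("a", FALSE, FALSE), mk("b", FALSE, FALSE)))
  expect_equal(res$counts$n_small_world, c(0, 0))
  expect_equal(nrow(res$disagreements), 0)

  res <- compare_methods(list(mk("a", FALSE, TRUE), mk("b", TRUE, TRUE)))
  expect_equal(res$counts$n_small_world, c(1, 2))
  expect_equal(res$disagreements$name, "a")
})

test_that("the CI rule is at most as permissive as S^ws on rewired lattices", {
  # reported direction, not asserted per-seed: conf hits <= sws hits
  ens <- ensemble_metrics(100, 300, n_rep = 300, seed = 29)
  verdicts <- lapply(1:15, function(s) {
    topo <- summarize_topology(watts_strogatz(100, 6, 0.1, seed = 200 + s))
    sw_classify(topo, ens$cpl, ens$cc)
  })
  res <- compare_methods(verdicts)
  expect_lte(res$counts$n_small_world[res$counts$method == "ci_rule"],
             res$counts$n_small_world[res$counts$method == "small_world_ness"])
})
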