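---
title: "Small-world classification of food webs: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world classification of food webs: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`swnet` classifies trophic networks as small-world or not by an explicit
Monte-Carlo test, and fits degree-distribution models by maximum
likelihood. This vignette records the model, the conventions behind every
number the package produces, and the choices made where more than one
convention is defensible.

## The graph model

A food web arrives as S trophic species and L directed resource → consumer
links. Connectance is C = L/S²: the denominator allows self-links because
cannibalism is a real feeding interaction, and those loops stay in L.

All structural metrics, however, are computed on the **undirected simple
projection**: self-loops dropped, reciprocal pairs merged. Two reasons.
First, the local clustering denominator K(K−1)/2 and the pair
normalisation S(S−1)/2 are undirected quantities; a directed reading would
change their meaning. Second, the neighbourhood of a consumer includes its
resources and its predators alike — "who interacts with whom" is the
relevant relation for clustering and path length, not "who eats whom".
`to_projection()` reports how many loops were dropped and reciprocal pairs
merged so the information loss is visible.

## Metrics

**Characteristic path length** is the mean shortest-path distance *in
links* over mutually reachable unordered pairs. Unreachable pairs are
excluded from the average and counted separately rather than being given a
penalty distance; this keeps CPL finite on fragmented webs and matches the
convention of the standard graph libraries. (Counting "nodes in the path"
instead of links would shift every distance up by one and is incompatible
with dense webs whose CPL is near 1.5.)

**Clustering** is the average of local coefficients
CC_i = 2E_i/(K_i(K_i−1)). Nodes of degree 0 or 1 have no neighbour pair to
evaluate; they contribute CC_i = 0 and stay in the average (the zero
convention). This matters: webs dominated by poorly connected species can
have CC near zero even when their hubs are locally dense, which is exactly
the behaviour reported for the sparsest published marine webs (CC of order
10⁻³).

## The null ensemble

The null model is Erdős–Rényi **G(n, M)** — uniform over simple undirected
graphs with exactly the web's S nodes and a matched number of edges — not
G(n, p), because the comparison webs must have *the same* S and link count,
not the same expectation. Connectivity is not enforced; a disconnected
replicate is treated exactly like a disconnected empirical web (a replicate
is skipped only in the degenerate case of zero connected pairs, and more
than 1% skipped is an error).

Which edge count to match is a genuine choice for directed data.
`run_analysis(null_edges = "projection")` (the default) matches the
projection's edge count E, the self-consistent option. `"raw"` matches the
printed directed L, which is what published random-graph clustering values
equal to L/(S(S−1)/2) imply; use it to reproduce such analyses. For webs
with few reciprocal links (most food webs) the two differ by little.

The 99% interval is the pair of empirical 0.5% and 99.5% quantiles of the
1000 replicate values, computed with linear interpolation between order
statistics (R's type-7 quantile). The literature rarely states its quantile
definition; type 7 is declared here as ours. Replicate r of an ensemble is
seeded from a deterministic sub-seed stream, so runs are bit-reproducible
and enlarging `n_rep` leaves earlier replicates unchanged.

**Tunables.** `n_rep` (default 1000): the CI's endpoints are order
statistics near ranks 5 and 995, so below a few hundred replicates the
interval is mostly noise — the package warns under 100. `ci_level`
(default 0.99) trades type-I error for power symmetrically on both
metrics.

## Classification rules

The **CI rule**: small-world ⇔ CPL_emp ≤ ci_high(CPL_rand) *and*
CC_emp > ci_high(CC_rand). The CPL inequality is non-strict ("within or
below the interval"), the CC one strict ("above the interval") — a literal
reading of the verbal rule, with ties resolved conservatively for CC.
With both conditions at 99%, the false-positive rate on ER graphs is below
1%; the package's tests measure ≤ 5% over 200 ER(100, 400) controls to
absorb Monte-Carlo noise.

The **small-world-ness metric** S^ws = (CC ratio)/(CPL ratio) condenses
both axes into one number. Its null distribution is built by scoring each
ensemble replicate against the ensemble means — the simplest construction
consistent with "S^ws compared to its 99% CI"; leave-one-out rescoring
would change the 99.5% quantile by O(1/n_rep). A web is S^ws-small-world
when S^ws > 1 and S^ws > the null's 99.5% quantile.

The two rules are *not* equivalent, and the difference is the scientific
point. S^ws rewards a large clustering ratio even when CPL is somewhat
above random; the CI rule vetoes any web whose CPL exceeds the random
interval. A Watts–Strogatz lattice at 5% rewiring (n = 200, k = 10) has
roughly 10× random clustering but CPL ≈ 3.2 against a random CI topping
out near 2.56: S^ws classifies it small-world essentially always, the CI
rule essentially never. The package's acceptance suite records this
honestly — the CI-rule power target against such lattices fails, for the
same reason the CI method flags far fewer published webs (5/28) than S^ws
does (11/28). A user wanting the permissive behaviour should read the
`SW_sws` column; `SW_conf` answers the stricter question "is this web
random-like in path length *and* significantly clustered?"

## Degree-distribution fitting

Fitting is by maximum likelihood on the **raw degree sequence** of the
projection (total degree). The cumulative P(k ≥ x) curve is presentation
only — least squares on a survival curve has strongly correlated errors
and is not used. Six discrete models are fitted:

| model | pmf on support | parameters (K) |
|---|---|---|
| Poisson | λ^k e^{−λ}/k!, k ≥ 0 | λ (1) |
| exponential | ∝ e^{−k/κ}, k ≥ kmin | κ (1) |
| power law | k^{−α}/ζ(α, kmin) | α (1) |
| truncated power law | ∝ k^{−α} e^{−k/κ} | α, κ (2) |
| lognormal (discretised) | ∝ e^{−(ln k − μ)²/2σ²}/k | μ, σ (2) |
| uniform | 1/(kmax−kmin+1) on [kmin, kmax] | bounds (2) |

Conventions: kmin is the minimum observed degree (no Clauset-style lower
cutoff search — a documented limitation, as the published analyses state
none either); n in AICc is the number of nodes; the uniform model's
data-determined bounds are charged as 2 estimated parameters. The Hurwitz
zeta is evaluated by direct summation with an Euler–Maclaurin tail; the
truncated power law and lognormal are normalised by adaptive summation
until the added mass is below 10⁻¹³ relative. Closed forms are used where
they exist (Poisson mean; geometric-type MLE κ̂ from the mean excess).
Optimiser non-convergence, degenerate single-valued degree sequences, and
zero degrees under k ≥ 1 models are flagged and excluded from selection
rather than raising errors. Selection is minimal AICc with ties broken
toward fewer parameters, then a fixed model order.

One practical caveat the tests document: on preferential-attachment
degree sequences the truncated power law and the discretised lognormal are
near-indistinguishable (ΔAICc typically < 2 at n = 400), so "which of the
two wins" is seed noise even when the heavy-tailed family wins decisively.
ΔAICc, reported for every model, is the honest summary; a selection flag
alone overstates certainty.

## Synthetic controls

The generator module exists so every pipeline stage is testable without
redistribution of published webs; its defaults are the canonical
parameterisations of each topology class, not tuned values:

- `watts_strogatz(n, k, p)` — ring lattice with per-edge rewiring;
  positive control for clustering (CC = 3(k−2)/(4(k−1)) at p = 0).
- `ring_lattice(n, k)` — deterministic negative control: passes the CC
  condition, fails the CPL condition.
- `preferential_attachment(n, m)` — heavy-tailed degrees.
- `uniform_degree(n, d_min, d_max)` — configuration-model realisation of
  uniformly drawn degrees (parity repaired by nudging one node; simple
  realisation retried up to 50 times), emulating the approximately
  constant-degree "uniform-scale" class reported in well-resolved webs.
- `orient_random()` — turns any of these into a directed trophic web by
  orienting each edge uniformly at random, because empirical webs are
  directed while the metrics are not.

What the generators do **not** emulate: ecological link structure (no
niche or cascade model — deliberately out of scope), degree correlations,
and looping/cannibalism. A green control battery therefore establishes
that the statistics behave as designed on known topology classes, not that
any ecological generative model is correct.

## Numerical and degenerate-input policy

- Webs with a single node, or with no connected pair, raise errors at the
  CPL stage rather than returning sentinel values.
- A zero random-clustering mean makes S^ws undefined: flagged `NA`,
  classification `FALSE`, with a warning.
- All randomness flows from one user-supplied seed through deterministic
  sub-seed streams (per web, then per replicate); two runs with the same
  configuration agree bit-for-bit.
- Results tables are written at 2 decimals by default, matching the
  conventional reporting precision; everything in memory stays at full
  precision.
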