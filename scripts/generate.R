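#!/usr/bin/env Rscript
# Writes a synthetic control network as a plain-text edge list.
#   Rscript scripts/generate.R --kind watts_strogatz --n 200 --k 10 --p 0.05 \
#     --seed 1 --out ws.tsv
# Kinds: er (--n, --l), watts_strogatz (--n, --k, --p), ring_lattice
# (--n, --k), preferential_attachment (--n, --m), uniform_degree
# (--n, --dmin, --dmax). --directed orients each edge at random so the file
# reads back as a directed trophic web.

suppressMessages({
  library(optparse)
  library(swnet)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--kind", type = "character"),
  make_option("--n", type = "integer"),
  make_option("--k", type = "integer"),
  make_option("--p", type = "double", default = 0),
  make_option("--l", type = "integer"),
  make_option("--m", type = "integer", default = 2L),
  make_option("--dmin", type = "integer", default = 2L),
  make_option("--dmax", type = "integer", default = 8L),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--directed", action = "store_true", default = FALSE),
  make_option("--out", type = "character", default = "network.tsv")
)))

g <- switch(opts$kind,
  er = generate_er(opts$n, opts$l, seed = opts$seed),
  watts_strogatz = watts_strogatz(opts$n, opts$k, opts$p, seed = opts$seed),
  ring_lattice = ring_lattice(opts$n, opts$k),
  preferential_attachment = preferential_attachment(opts$n, opts$m,
                                                    seed = opts$seed),
  uniform_degree = uniform_degree(opts$n, opts$dmin, opts$dmax,
                                  seed = opts$seed),
  stop("Unknown --kind")
)
if (opts$directed) g <- orient_random(g, seed = opts$seed + 1L)
write_edge_list(g, opts$out)
message(sprintf("Wrote %s", opts$out))
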