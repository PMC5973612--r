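#!/usr/bin/env Rscript
# Command-line front end for the per-web small-world analysis.
#   Rscript scripts/analyze.R --input DIR [--replicates 1000] [--ci 0.99]
#     [--seed 1] [--null-edges projection|raw] [--delimiter '\t'] --out DIR

suppressMessages({
  library(optparse)
  library(swnet)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--input", type = "character",
              help = "Directory of edge-list files (or one file)"),
  make_option("--replicates", type = "integer", default = 1000L),
  make_option("--ci", type = "double", default = 0.99),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--null-edges", type = "character", default = "projection",
              dest = "null_edges", help = "projection or raw"),
  make_option("--delimiter", type = "character", default = "\t"),
  make_option("--out", type = "character", default = "sw_results")
)))
if (is.null(opts$input)) stop("--input is required")

res <- run_analysis(
  opts$input,
  n_rep = opts$replicates,
  ci_level = opts$ci,
  seed = opts$seed,
  null_edges = opts$null_edges,
  delimiter = opts$delimiter,
  out_dir = opts$out
)
message(sprintf("Analyzed %d web(s); results in %s", nrow(res$results),
                opts$out))
print(res)
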