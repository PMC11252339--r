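#!/usr/bin/env Rscript

# Thin shell over reorientr::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R --config cfg.yaml --out dir/
#          [--seed N] [--stages simulate,maps,bmr,...]

suppressPackageStartupMessages({
  library(optparse)
  library(reorientr)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
              help = "YAML/JSON file of sim_config arguments (optional)"),
  make_option("--out", type = "character", default = "run",
              help = "output directory [default %default]"),
  make_option("--seed", type = "integer", default = NULL,
              help = "override the config's master seed"),
  make_option("--stages", type = "character", default = NULL,
              help = "comma-separated stage list (default: all)")
)))

cfg <- if (is.null(opts$config)) sim_config() else read_run_config(opts$config)
if (!is.null(opts$seed)) {
  cfg$seed <- opts$seed
  cfg <- reorientr:::validate_sim_config(cfg)
}
stages <- if (is.null(opts$stages)) {
  c("simulate", "maps", "bmr", "context", "population", "decode", "rate",
    "behavior")
} else {
  strsplit(opts$stages, ",")[[1]]
}
run_pipeline(cfg, opts$out, stages = stages)
cat("pipeline outputs written to", opts$out, "\n")
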