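#!/usr/bin/env Rscript

# Thin shell wrapper around ffpeconcord::run_pipeline().
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] --out DIR [--seed N]

suppressPackageStartupMessages({
  library(optparse)
  library(ffpeconcord)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = NULL)
)))

cfg <- validate_config(opts$config)
if (!is.null(opts$seed)) {
  raw <- if (is.null(opts$config)) list() else yaml::read_yaml(opts$config)
  raw$seed <- opts$seed
  cfg <- validate_config(raw)
}
rep <- run_pipeline(cfg, out_dir = opts$out)
print(rep)
cat("Report written to", opts$out, "\n")
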