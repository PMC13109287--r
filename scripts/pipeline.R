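#!/usr/bin/env Rscript
# Thin command-line wrapper over surfcomp::run_pipeline().
#
# Usage:
#   Rscript scripts/pipeline.R --out runs/exp1 [--config run.yaml]
#     [--seed 1337] [--stages generate,features,train,analyze,report]

suppressMessages({
  library(surfcomp)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
    help = "YAML run configuration (optional)"),
  make_option("--out", type = "character", default = "runs/run1"),
  make_option("--seed", type = "integer", default = NULL,
    help = "overrides the config seed"),
  make_option("--stages", type = "character", default = NULL,
    help = "comma-separated stage subset")
)))

cfg <- if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
if (!is.null(opts$seed)) {
  cfg$seed <- opts$seed
  cfg$generator$seed <- opts$seed
}
if (!is.null(opts$stages)) {
  cfg$stages <- strsplit(opts$stages, ",")[[1]]
}
run_pipeline(cfg, opts$out)
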