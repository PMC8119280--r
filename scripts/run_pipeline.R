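#!/usr/bin/env Rscript

# Thin command-line wrapper over stairbold::run_pipeline(): runs the full
# simulate -> classify -> behavior -> BOLD -> GLM -> ANOVA -> cluster
# threshold -> ROI pipeline with the default study-condition configuration.
#
#   Rscript scripts/run_pipeline.R --out <dir> [--seed <int>]
#       [--n-hc <int>] [--n-scz <int>] [--n-iter <int>]

suppressPackageStartupMessages({
  library(stairbold)
  library(optparse)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "pipeline_output"),
  make_option("--seed", type = "integer", default = 20200819L),
  make_option("--n-hc", type = "integer", default = 19L, dest = "n_hc"),
  make_option("--n-scz", type = "integer", default = 15L, dest = "n_scz"),
  make_option("--n-iter", type = "integer", default = 1000L, dest = "n_iter")
)))

cfg <- pipeline_config(n_hc = opts$n_hc, n_scz = opts$n_scz,
                       n_iter = opts$n_iter, seed = opts$seed)
report <- run_pipeline(cfg, opts$out, seed = opts$seed)
cat(sprintf("pipeline complete: %d subjects, %d ROI(s); report at %s\n",
            report$n_subjects, report$n_rois,
            file.path(opts$out, "report.json")))
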