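#!/usr/bin/env Rscript

# Thin command-line wrapper over the connectograd pipeline.
#
# Usage:
#   Rscript scripts/connectograd.R <subcommand> [options]
#
# Subcommands: simulate | qc | gradient | cluster | seedconn | glm | all |
#              report (report re-runs 'all' and prints the summary table)

suppressMessages({
  library(connectograd)
  library(optparse)
})

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) {
  message("usage: connectograd.R <simulate|qc|gradient|cluster|seedconn|glm|all|report> [options]")
  quit(status = 2)
}
subcommand <- args[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--out-dir", type = "character", default = "connectograd_out",
              dest = "out_dir"),
  make_option("--seed", type = "integer", default = 1),
  make_option("--n-subjects", type = "integer", default = 10,
              dest = "n_subjects"),
  make_option("--n-volumes", type = "integer", default = 200,
              dest = "n_volumes"),
  make_option("--noise-sd", type = "double", default = 0.5,
              dest = "noise_sd"),
  make_option("--n-modes", type = "integer", default = 2, dest = "n_modes"),
  make_option("--fd-threshold", type = "double", default = 0.5,
              dest = "fd_threshold")
)), args = args[-1])

stage_order <- c("simulate", "qc", "gradient", "cluster", "seedconn", "glm")
stages <- switch(subcommand,
  simulate = "simulate",
  qc       = c("simulate", "qc"),
  gradient = c("simulate", "gradient"),
  cluster  = c("simulate", "gradient", "cluster"),
  seedconn = c("simulate", "seedconn"),
  glm      = c("simulate", "gradient", "cluster", "glm"),
  all      = stage_order,
  report   = stage_order,
  { message("unknown subcommand: ", subcommand); quit(status = 2) })

cfg <- synth_config(seed = opts$seed, n_subjects = opts$n_subjects,
                    n_volumes = opts$n_volumes, noise_sd = opts$noise_sd)
manifest <- run_pipeline(cfg, opts$out_dir, stages = stages,
                         n_modes = opts$n_modes,
                         fd_threshold_mm = opts$fd_threshold)
if (subcommand %in% c("all", "report")) report_pipeline(manifest)
message("outputs in ", opts$out_dir)
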