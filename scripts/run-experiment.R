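#!/usr/bin/env Rscript
# Thin command-line wrapper over recsel::run_experiment().
#
#   Rscript scripts/run-experiment.R --config exp.yaml [--replicates N]
#                                    [--seed S] [--out DIR]
#   Rscript scripts/run-experiment.R --landscape brapa --out DIR
#   Rscript scripts/run-experiment.R --summarize DIR --out FILE
#
# The YAML config mirrors recsel::experiment_config(); --replicates, --seed
# and --out override the corresponding config fields. --landscape writes the
# three fitted synthetic landscapes of a species preset as TSV and exits.
# --summarize re-aggregates a trajectories.csv written by a previous run.

suppressPackageStartupMessages({
  library(optparse)
  library(recsel)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--replicates", type = "integer", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--out", type = "character", default = NULL),
  make_option("--landscape", type = "character", default = NULL,
              help = "species preset (brapa|osativa): dump landscapes only"),
  make_option("--summarize", type = "character", default = NULL,
              help = "directory holding trajectories.csv: re-aggregate only")
)))

if (!is.null(opts$summarize)) {
  if (is.null(opts$out)) stop("--summarize requires --out FILE")
  traj <- read.csv(file.path(opts$summarize, "trajectories.csv"))
  write.csv(summarize_gain_ratios(traj), opts$out, row.names = FALSE)
  quit(status = 0)
}

if (!is.null(opts$landscape)) {
  if (is.null(opts$out)) stop("--landscape requires --out DIR")
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  genome <- gen_landscape(synthetic_genome_config(opts$landscape))
  for (s in names(genome$landscapes)) {
    write_landscape(genome$landscapes[[s]]$maps,
                    file.path(opts$out, paste0("landscape_", s, ".tsv")))
  }
  quit(status = 0)
}

if (is.null(opts$config)) stop("--config FILE is required")
ec <- read_experiment_config(opts$config)
if (!is.null(opts$replicates)) ec$n_replicates <- opts$replicates
if (!is.null(opts$seed)) ec$base_seed <- opts$seed
if (!is.null(opts$out)) ec$out_dir <- opts$out

res <- run_experiment(ec)
ratios <- res$gain_ratios
if (!is.null(ratios)) {
  last <- ratios[ratios$generation == max(ratios$generation), ]
  for (i in seq_len(nrow(last))) {
    message(sprintf("gain ratio %s at g=%d: %.3f",
                    last$scenario_pair[i], last$generation[i],
                    last$gain_ratio[i]))
  }
}
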