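#!/usr/bin/env Rscript
# Fit the animal model to the real colony data (user-supplied download).
#
# The study's data are deposited at https://osf.io/hsjv7. This script is not
# run automatically: download the deposit yourself and export two CSVs in
# the package dialects —
#   pedigree CSV: animal,sire,dam[,sex,generation]   ("0"/empty = unknown)
#   trials  CSV: male,partner,stranger,trait,value   (one row per record)
# then run
#   Rscript analysis/05_osf_real_data.R <pedigree.csv> <trials.csv> [out_dir]
#
# With the production chain schedule this reproduces the published analysis
# shape: per-trait posterior heritabilities (VP and RSC receptor densities
# expected high, behaviours near zero) with diagnostics.

suppressPackageStartupMessages(library(voleherit))
args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2) {
  stop("usage: Rscript analysis/05_osf_real_data.R <pedigree.csv> ",
       "<trials.csv> [out_dir]", call. = FALSE)
}
ped <- read_pedigree(args[1])
trials <- read_trials(args[2])
out_dir <- if (length(args) >= 3) args[3] else "results/real_data"

report <- run_heritability(trials, ped,
                           config = gibbs_config_production(seed = 1),
                           out_dir = out_dir)
for (tr in names(report$traits)) {
  cat("\n==", tr, "==\n")
  print(report$traits[[tr]]$estimate)
}
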