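#!/usr/bin/env Rscript

## Stage 1: generate the synthetic study.
##
## Emulates the study design the pipeline targets: three conditions (WT,
## Plasmid-C control, septin-2 knockdown KD11) x three replicates, 95% null
## peptides, 93.5% of regulated peptides down in KD11, a DRVYHPF spike-in in
## every run, 10% missing identifications, decoy and false-target PSM rows,
## and one annotation term planted with preferentially regulated proteins.
## Raw mzML runs, PSM tables, the GMT and the ground truth are written as a
## fixture bundle for the downstream stages.

suppressPackageStartupMessages(library(lfqpipe))

fixture_dir <- "scratch/fixtures"
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(
  n_peptides = 400, n_proteins = 80,
  planted_term_odds = 10, term_size_range = c(10, 25),
  seed = 20260927
)
ex <- generate_experiment(cfg)
manifest <- write_fixture_bundle(ex, fixture_dir)

gt <- ex$ground_truth$peptides
cat(sprintf("simulated %d runs, %d peptides (%d proteins), %.1f%% null\n",
            manifest$n_runs, cfg$n_peptides, cfg$n_proteins,
            100 * mean(gt$is_null[!gt$is_standard])))
cat(sprintf("regulated peptides down in KD11: %.1f%%\n",
            100 * mean(gt$log2fc[!gt$is_null & !gt$is_standard] < 0)))
cat("fixture bundle written to ", fixture_dir, "\n")
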