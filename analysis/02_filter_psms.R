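#!/usr/bin/env Rscript

## Stage 2: post-search PSM filtering.
##
## Applies the score floor (Mowse-like score > 20), searches for the lowest
## score threshold holding the concatenated target-decoy FDR at 1%, and
## reduces the retained targets to unique (run, peptide, charge)
## identifications by dropping lower-scoring duplicates.

suppressPackageStartupMessages(library(lfqpipe))

fixture_dir <- "scratch/fixtures"
manifest <- jsonlite::read_json(file.path(fixture_dir, "manifest.json"),
                                simplifyVector = TRUE)
psm_files <- file.path(fixture_dir, manifest$files$psm)
stopifnot(length(psm_files) > 0)
psms_raw <- do.call(rbind, lapply(psm_files, read_psm_table))

filt <- filter_to_fdr(psms_raw, score_floor = 20, fdr_target = 0.01)
unique_psms <- deduplicate_psms(filt$psms)

report <- list(
  n_input = nrow(psms_raw),
  n_decoys_input = sum(psms_raw$is_decoy),
  n_discarded_floor = filt$n_discarded_floor,
  score_threshold = filt$threshold,
  estimated_fdr = filt$fdr,
  n_retained = nrow(filt$psms),
  n_unique = nrow(unique_psms)
)
jsonlite::write_json(report, "results/psm_filter_report.json",
                     auto_unbox = TRUE, digits = NA)
write_psm_table(cbind(unique_psms, is_decoy = FALSE),
                "scratch/unique_psms.tsv")

cat(sprintf("PSMs in: %d (of which %d decoys); floor removed %d\n",
            report$n_input, report$n_decoys_input, report$n_discarded_floor))
cat(sprintf("1%% FDR threshold: score >= %.2f (estimated FDR %.4f)\n",
            report$score_threshold, report$estimated_fdr))
cat(sprintf("retained %d targets -> %d unique identifications\n",
            report$n_retained, report$n_unique))
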