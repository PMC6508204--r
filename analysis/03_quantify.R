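#!/usr/bin/env Rscript

## Stage 3: SIC quantitation.
##
## For every identified peptide: extract the 10 ppm selected ion
## chromatogram in every run, detect elution peaks with multi-pass CWT
## (minimum widths 20/10/5/2 s, max 80 s, S/N >= 10, boundaries by descent
## on the raw data), align retention times across runs, fill in runs lacking
## an identification from the alignment-predicted retention time, normalize
## to the spiked DRVYHPF standard, and apply the 1000-area reporting floor.

suppressPackageStartupMessages(library(lfqpipe))

fixture_dir <- "scratch/fixtures"
mzml_files <- list.files(fixture_dir, pattern = "\\.mzML$", full.names = TRUE)
runs <- lapply(mzml_files, read_ms1_mzml)
names(runs) <- vapply(runs, function(r) r$run_id, "")
psms <- read_psm_table("scratch/unique_psms.tsv")

qm <- quantify_runs(runs, psms)
qm <- normalize_to_standard(qm)
qm <- apply_floor(qm, 1000)
write_quant_matrix(qm, "results/quant")

fl <- table(qm$flags)
cat(sprintf("quantified %d peptides x %d runs\n", nrow(qm$area),
            ncol(qm$area)))
cat(sprintf("cells: %s\n",
            paste(names(fl), fl, sep = "=", collapse = ", ")))
cat(sprintf("floored cells: %d (%.1f%%)\n", sum(qm$floored),
            100 * mean(qm$floored)))
cat(sprintf("spike-in normalization factors: %s\n",
            paste(sprintf("%.3f", qm$normalization$scale_factors),
                  collapse = " ")))
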