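#!/usr/bin/env Rscript

## Stage 4: differential expression.
##
## Two-tailed unpaired equal-variance t-tests on log2 normalized areas per
## peptide, Storey q-values, KD11/WT fold changes, strict significance
## (|log2 FC| > 1 and q < 0.05), protein-level roll-up by peptide-area
## summation with re-testing, for both contrasts (KD11 vs WT, PlasmidC vs
## WT).

suppressPackageStartupMessages(library(lfqpipe))

qm <- read_quant_matrix("results/quant")
qm$area <- qm$area[qm$peptides$peptide != "DRVYHPF", , drop = FALSE]
qm$flags <- qm$flags[rownames(qm$area), , drop = FALSE]
qm$floored <- qm$floored[rownames(qm$area), , drop = FALSE]
qm$peptides <- qm$peptides[qm$peptides$peptide != "DRVYHPF", , drop = FALSE]

groups <- setNames(sub("_[0-9]+$", "", qm$run_ids), qm$run_ids)
prot <- protein_rollup(qm)

for (ct in list(c("KD11", "WT"), c("PlasmidC", "WT"))) {
  key <- paste(ct, collapse = "_vs_")
  de_pep <- diff_expression(qm, groups, ct, level = "peptide")
  de_pro <- diff_expression(prot, groups, ct, level = "protein")
  s <- classify_and_summarize(de_pep, de_pro)
  write.table(rbind(de_pep, de_pro),
              file.path("results", paste0("de_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(volcano_table(de_pep),
              file.path("results", paste0("volcano_", key, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(s, file.path("results",
                                    paste0("summary_", key, ".json")),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d/%d peptides significant (%.1f%%), %.1f%% down, %d proteins\n",
              key, s$n_significant, s$n_tested, s$pct_significant,
              if (is.na(s$pct_down)) 0 else s$pct_down,
              s$n_significant_proteins))
}
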