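#!/usr/bin/env Rscript

## Stage 5: multivariate summaries and enrichment.
##
## PCA of the log2 quantitation matrix (runs as observations), hierarchical
## clustering of the significant peptides (correlation distance, average
## linkage), and Fisher-exact term enrichment of the differential proteins
## against the unchanged-protein background with Bonferroni correction.

suppressPackageStartupMessages(library(lfqpipe))

qm <- read_quant_matrix("results/quant")
keep <- qm$peptides$peptide != "DRVYHPF"
area <- qm$area[keep, , drop = FALSE]
prot_map <- setNames(qm$peptides$protein_acc[keep],
                     qm$peptides$peptide[keep])

pc <- pca_scores(area)
scores <- data.frame(run_id = rownames(pc$scores), pc$scores,
                     check.names = FALSE)
write.table(scores, "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("PCA explained variance:",
    sprintf("%.1f%%", 100 * pc$explained_variance), "\n")

de <- read.delim("results/de_KD11_vs_WT.tsv")
sig_pep <- de$unit_id[de$level == "peptide" & de$significant]
if (length(sig_pep) >= 2) {
  hm <- hierarchical_heatmap(area[rownames(area) %in% sig_pep, ,
                                  drop = FALSE])
  ordered <- data.frame(peptide = rownames(hm$matrix), hm$matrix,
                        check.names = FALSE)
  write.table(ordered, "results/heatmap_matrix.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("clustered %d significant peptides; KD11 runs %s one subtree\n",
              nrow(hm$matrix),
              if (length(unique(cutree(hm$col_hclust, 2)[
                grepl("^KD11", colnames(hm$matrix))])) == 1)
                "form" else "do not form"))
}

de_prot <- de$unit_id[de$level == "protein" & de$significant]
bg_prot <- setdiff(de$unit_id[de$level == "protein"], de_prot)
annotation <- read_gmt("scratch/fixtures/annotation.gmt")
if (length(de_prot)) {
  enr <- enrich_terms(de_prot, bg_prot, annotation)
  write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
              row.names = FALSE)
  top <- enr[1, ]
  cat(sprintf("top enriched term: %s (k/K = %d/%d, n/N = %d/%d, p = %.2e, Bonferroni = %.2e)\n",
              top$term_id, top$k, top$K, top$n, top$N, top$p,
              top$p_adjusted))
} else {
  cat("no differential proteins; enrichment skipped\n")
}
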