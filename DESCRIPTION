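Package: lfqpipe
Title: Label-Free Quantitative Proteomics via Extracted Ion Chromatogram Peak Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end label-free quantification (LFQ) pipeline for
    centroided MS1 proteomics data: selected ion chromatogram (SIC) extraction
    in a ppm mass window, multi-pass continuous-wavelet-transform peak
    detection with boundary descent on raw intensities, retention-time
    alignment with missing-identification fill-in, spike-in normalization to a
    standard peptide, target-decoy FDR filtering of peptide-spectrum matches,
    Storey q-value differential expression with protein roll-up, and
    downstream PCA, hierarchical clustering and Fisher-exact term enrichment
    against an unchanged-protein background. Includes a ground-truthed
    synthetic raw-data generator so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    mzR,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
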