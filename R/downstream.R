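#' Principal component analysis of a quantitation matrix
#'
#' Runs PCA on the runs (observations = runs, variables = peptides or
#' proteins) after log2 transform and row centering. Rows constant across
#' runs are dropped. No unit scaling by default: areas are already on a
#' common normalized scale.
#'
#' @param qm a `quant_matrix` or numeric matrix (rows = units, columns =
#'   runs); values must be positive when `log2` is `TRUE`.
#' @param n_components number of components to report (default 3; truncated
#'   with a warning when fewer runs are available).
#' @param log2_transform log2-transform areas first (default `TRUE`).
#' @param scale_rows unit-scale rows as well (default `FALSE`).
#' @return list with `scores` (runs x components), `explained_variance`
#'   (fractions, non-increasing) and `n_units_used`.
#' @export
pca_scores <- function(qm, n_components = 3, log2_transform = TRUE,
                       scale_rows = FALSE) {
  x <- if (inherits(qm, "quant_matrix")) qm$area else qm
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (log2_transform) x <- log2(x)
  keep <- apply(x, 1, function(r) var(r) > 0)
  n_runs <- ncol(x)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0) {
    ## all rows constant across runs: every run sits at the origin
    warning("no rows vary across runs; returning zero scores")
    scores <- matrix(0, n_runs, n_components,
                     dimnames = list(colnames(x),
                                     paste0("PC", seq_len(n_components))))
    return(list(scores = scores,
                explained_variance = rep(0, n_components),
                n_units_used = 0L))
  }
  max_comp <- min(ncol(x) - 1L, nrow(x))
  if (n_components > max_comp) {
    warning(sprintf("only %d components available; truncating", max_comp))
    n_components <- max_comp
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = scale_rows)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev[seq_len(n_components)],
       n_units_used = nrow(x))
}

#' Hierarchical clustering of significant units for a heat map
#'
#' Agglomerative clustering (average linkage) of the log2, row-z-scored
#' matrix: correlation distance between rows (units share a profile shape),
#' Euclidean distance between columns (runs differ in level once rows are
#' z-scored; a homogeneous signature leaves no between-column correlation
#' signal). Emits the z-scored matrix reordered by the dendrogram leaf
#' orders.
#'
#' @param qm a `quant_matrix` or positive numeric matrix, typically already
#'   restricted to significant units (>= 2 rows).
#' @param log2_transform log2-transform before z-scoring (default `TRUE`).
#' @return list with `row_hclust`, `col_hclust` (`hclust` objects),
#'   `row_order`, `col_order` (leaf orders) and `matrix` (the reordered
#'   z-scored matrix).
#' @export
hierarchical_heatmap <- function(qm, log2_transform = TRUE) {
  x <- if (inherits(qm, "quant_matrix")) qm$area else qm
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (log2_transform) x <- log2(x)
  mu <- rowMeans(x)
  sdev <- apply(x, 1, sd)
  sdev[sdev == 0] <- 1
  z <- (x - mu) / sdev
  cor_dist <- function(m) {
    cc <- suppressWarnings(cor(t(m)))
    cc[!is.finite(cc)] <- 0
    stats::as.dist(1 - cc)
  }
  rh <- stats::hclust(cor_dist(z), method = "average")
  ch <- stats::hclust(stats::dist(t(z)), method = "average")
  list(row_hclust = rh, col_hclust = ch,
       row_order = rh$order, col_order = ch$order,
       matrix = z[rh$order, ch$order, drop = FALSE])
}

#' Term enrichment of differential proteins against an unchanged background
#'
#' One-sided Fisher exact test per term for over-representation of the term
#' among differentially expressed proteins relative to the background of
#' unchanged proteins, with Bonferroni correction over all tested terms
#' (terms containing no differential protein still count toward the number
#' of tests).
#'
#' @param de_proteins character vector of differential protein accessions.
#' @param background_proteins character vector of unchanged (non-differential)
#'   protein accessions; must be disjoint from `de_proteins`.
#' @param annotation named list of character vectors (term -> accessions),
#'   e.g. from [read_gmt()].
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return data frame sorted by p: `term_id`, `term_name`, `k` (DE in term),
#'   `K` (DE total), `n` (background in term), `N` (background total), `p`,
#'   `p_adjusted`.
#' @export
enrich_terms <- function(de_proteins, background_proteins, annotation,
                         adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  de_proteins <- unique(de_proteins)
  background_proteins <- unique(background_proteins)
  if (!length(de_proteins)) stop("empty differential protein set")
  if (!length(annotation)) stop("empty annotation")
  if (length(intersect(de_proteins, background_proteins)))
    stop("differential and background sets must be disjoint")
  K <- length(de_proteins)
  N <- length(background_proteins)
  desc <- attr(annotation, "descriptions")
  rows <- lapply(names(annotation), function(term) {
    members <- annotation[[term]]
    k <- sum(de_proteins %in% members)
    nn <- sum(background_proteins %in% members)
    tab <- matrix(c(k, K - k, nn, N - nn), 2, 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term_id = term,
               term_name = if (!is.null(desc)) desc[[term]] %||% term else term,
               k = k, K = K, n = nn, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "bonferroni") {
    pmin(1, out$p * nrow(out))
  } else stats::p.adjust(out$p, "BH")
  out[order(out$p), , drop = FALSE]
}

#' Read / write GMT gene-set files
#'
#' One term per line: term id, description, then tab-separated member
#' accessions.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- lapply(parts, function(x) x[-(1:2)])
  names(terms) <- vapply(parts, `[[`, "", 1)
  attr(terms, "descriptions") <- setNames(vapply(parts, `[[`, "", 2),
                                          names(terms))
  terms
}

#' @param annotation named list of character vectors; optional
#'   `descriptions` attribute.
#' @rdname read_gmt
#' @export
write_gmt <- function(annotation, path) {
  desc <- attr(annotation, "descriptions")
  lines <- vapply(names(annotation), function(term) {
    d <- if (!is.null(desc)) desc[[term]] %||% term else term
    paste(c(term, d, annotation[[term]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
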