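#' Statistical parameters for differential expression
#'
#' @param log_transform test on log2-transformed areas (default `TRUE`).
#' @param fc_threshold significance requires |log2 fold change| strictly
#'   greater than this (default 1).
#' @param q_threshold significance requires q strictly below this (default
#'   0.05).
#' @param pi0_lambda_grid lambda grid for Storey's null-proportion estimate.
#' @param pi0_method `"smoother"` (cubic smoothing spline over the grid,
#'   evaluated at its largest lambda) or `"fixed"` (use `pi0 = 1`,
#'   equivalent to Benjamini-Hochberg).
#' @return a `stat_params` list.
#' @export
stat_params <- function(log_transform = TRUE,
                        fc_threshold = 1,
                        q_threshold = 0.05,
                        pi0_lambda_grid = seq(0, 0.90, by = 0.05),
                        pi0_method = c("smoother", "fixed")) {
  stopifnot(fc_threshold > 0, q_threshold > 0,
            !is.unsorted(pi0_lambda_grid, strictly = TRUE),
            all(pi0_lambda_grid >= 0 & pi0_lambda_grid < 1))
  structure(list(log_transform = isTRUE(log_transform),
                 fc_threshold = fc_threshold, q_threshold = q_threshold,
                 pi0_lambda_grid = pi0_lambda_grid,
                 pi0_method = match.arg(pi0_method)),
            class = "stat_params")
}

#' Two-sample equal-variance t-test on peak areas
#'
#' Two-tailed unpaired Student's t with pooled variance, optionally on log2
#' areas. Degenerate zero-pooled-variance inputs give p = 1 when the group
#' means are equal and the smallest representable p (flagged) when not.
#'
#' @param a,b numeric area vectors, >= 2 observations each, positive when
#'   `log_transform`.
#' @param params a [stat_params()].
#' @return list with `statistic`, `df`, `p` and `degenerate`.
#' @export
peptide_test <- function(a, b, params = stat_params()) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (params$log_transform) {
    if (any(a <= 0) || any(b <= 0)) stop("areas must be positive for log2 transform")
    a <- log2(a); b <- log2(b)
  }
  va <- var(a); vb <- var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = FALSE))
    }
    return(list(statistic = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2,
                p = .Machine$double.xmin, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 over a lambda grid (Storey's smoother:
#' `pi0(lambda) = #{p > lambda} / (m (1 - lambda))` smoothed by a cubic
#' spline and read off at the largest lambda, clamped to (0, 1]), then
#' computes `q_i = min over p_(j) >= p_(i) of pi0 * m * p_(j) / j`. With
#' `pi0 = 1` this reduces exactly to Benjamini-Hochberg adjusted p-values.
#'
#' @param p p-values in (0, 1].
#' @param params a [stat_params()].
#' @param pi0 optional fixed pi0 overriding estimation.
#' @return numeric vector of q-values in input order, with attribute `pi0`.
#' @export
qvalues <- function(p, params = stat_params(), pi0 = NULL) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0 <- if (m < 10 || params$pi0_method == "fixed") 1 else
      estimate_pi0(p, params$pi0_lambda_grid)
  }
  o <- order(p)
  ranked <- pi0 * m * p[o] / seq_len(m)
  qo <- rev(cummin(rev(ranked)))
  qo <- pmin(qo, 1)
  q <- numeric(m)
  q[o] <- qo
  attr(q, "pi0") <- pi0
  q
}

estimate_pi0 <- function(p, lambda) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Fold change between two groups of areas
#'
#' @param wt,kd positive area vectors (baseline and treatment groups).
#' @return list with `ratio` (`mean(kd)/mean(wt)`) and `log2fc`.
#' @export
fold_change <- function(wt, kd) {
  mw <- mean(wt); mk <- mean(kd)
  if (mw <= 0 || mk <= 0) stop("group means must be positive")
  list(ratio = mk / mw, log2fc = log2(mk / mw))
}

#' Differential expression across two conditions of a quantitation matrix
#'
#' Runs [peptide_test()], [fold_change()] and [qvalues()] on every row for a
#' `treatment` vs `baseline` contrast, classifying each unit as significant
#' when `|log2fc| > fc_threshold` (strict) and `q < q_threshold` (strict).
#'
#' @param qm a (normalized, floored) `quant_matrix`, or a plain numeric
#'   matrix with run-id column names.
#' @param groups named character vector or factor mapping each run id to its
#'   condition.
#' @param contrast length-2 character vector `c(treatment, baseline)`, e.g.
#'   `c("KD11", "WT")`; the ratio reported is treatment / baseline.
#' @param params a [stat_params()].
#' @param level label stored in the `level` column (`"peptide"` or
#'   `"protein"`).
#' @return a `de_result` data frame: `unit_id`, `level`, `mean_baseline`,
#'   `mean_treatment`, `ratio`, `log2fc`, `p`, `q`, `significant`,
#'   `direction`; attribute `pi0`.
#' @export
diff_expression <- function(qm, groups, contrast, params = stat_params(),
                            level = "peptide") {
  x <- if (inherits(qm, "quant_matrix")) qm$area else qm
  stopifnot(is.matrix(x), length(contrast) == 2)
  groups <- setNames(as.character(groups), names(groups))
  cols_t <- colnames(x)[groups[colnames(x)] == contrast[1]]
  cols_b <- colnames(x)[groups[colnames(x)] == contrast[2]]
  if (length(cols_t) < 2 || length(cols_b) < 2)
    stop("need >= 2 replicates per contrast group")
  n <- nrow(x)
  p <- ratio <- lfc <- mb <- mt <- numeric(n)
  for (i in seq_len(n)) {
    a <- x[i, cols_t]; b <- x[i, cols_b]
    p[i] <- peptide_test(a, b, params)$p
    fc <- fold_change(b, a)
    ratio[i] <- fc$ratio; lfc[i] <- fc$log2fc
    mb[i] <- mean(b); mt[i] <- mean(a)
  }
  q <- qvalues(p, params)
  out <- data.frame(
    unit_id = rownames(x) %||% as.character(seq_len(n)),
    level = level,
    mean_baseline = mb, mean_treatment = mt,
    ratio = ratio, log2fc = lfc, p = p, q = as.numeric(q),
    significant = abs(lfc) > params$fc_threshold & q < params$q_threshold,
    direction = ifelse(lfc < 0, "down", ifelse(lfc > 0, "up", "flat")),
    stringsAsFactors = FALSE
  )
  attr(out, "pi0") <- attr(q, "pi0")
  class(out) <- c("de_result", "data.frame")
  out
}

#' Protein roll-up by peptide area summation
#'
#' Protein-level quantitation: each protein's cell is the sum of its
#' peptides' cells per run. Peptides without a protein mapping are grouped
#' under `"UNMAPPED"` with a warning. Provenance flags propagate: a protein
#' cell is marked inferred/floored if any member peptide cell is.
#'
#' @param qm a `quant_matrix`.
#' @return a protein-level `quant_matrix` (rows = protein accessions).
#' @export
protein_rollup <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  prot <- qm$peptides$protein_acc
  if (any(is.na(prot) | prot == "")) {
    warning("peptides without protein mapping assigned to 'UNMAPPED'")
    prot[is.na(prot) | prot == ""] <- "UNMAPPED"
  }
  g <- factor(prot)
  area <- rowsum(qm$area, g)
  inferred <- rowsum((qm$flags == "inferred") + 0, g) > 0
  floored <- rowsum(qm$floored + 0, g) > 0
  flags <- ifelse(inferred, "inferred", "detected")
  peptides <- data.frame(peptide = rownames(area), charge = NA_integer_,
                         mz = NA_real_, protein_acc = rownames(area),
                         stringsAsFactors = FALSE)
  structure(list(area = area, flags = flags, floored = floored,
                 peptides = peptides, run_ids = qm$run_ids, warps = NULL,
                 normalization = qm$normalization),
            class = "quant_matrix")
}

#' Summarize a differential-expression result
#'
#' @param de a `de_result` from [diff_expression()].
#' @param de_protein optional protein-level `de_result` for the same
#'   contrast, used for the significant-protein count.
#' @return list with `n_tested`, `n_significant`, `pct_significant`,
#'   `pct_down` (among significant; `NA` when none), and
#'   `n_significant_proteins` when `de_protein` is given.
#' @export
classify_and_summarize <- function(de, de_protein = NULL) {
  sig <- de$significant
  out <- list(
    n_tested = nrow(de),
    n_significant = sum(sig),
    pct_significant = 100 * mean(sig),
    pct_down = if (any(sig)) 100 * mean(de$direction[sig] == "down")
               else NA_real_
  )
  if (!is.null(de_protein)) {
    out$n_significant_proteins <- sum(de_protein$significant)
  }
  out
}

#' Volcano-plot table
#'
#' @param de a `de_result`.
#' @return data frame with `unit_id`, `log2fc`, `neg_log10_q`,
#'   `significant`, consistent with the classifier.
#' @export
volcano_table <- function(de) {
  data.frame(unit_id = de$unit_id, log2fc = de$log2fc,
             neg_log10_q = -log10(de$q), significant = de$significant,
             stringsAsFactors = FALSE)
}
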