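#' Target-decoy FDR at a score threshold
#'
#' Concatenated target-decoy estimate: the number of decoy PSMs scoring at or
#' above the threshold divided by the number of target PSMs scoring at or
#' above it (1 is used in the denominator when no targets survive).
#'
#' @param psms data frame with at least `score` and `is_decoy` columns.
#' @param threshold finite score threshold.
#' @return estimated FDR (fraction, can exceed 1 on decoy-dominated sets).
#' @export
estimate_fdr_at_threshold <- function(psms, threshold) {
  if (is.null(psms) || nrow(psms) == 0) stop("no PSMs")
  stopifnot(is.finite(threshold))
  above <- psms$score >= threshold
  n_decoy <- sum(above & psms$is_decoy)
  n_target <- sum(above & !psms$is_decoy)
  n_decoy / max(1L, n_target)
}

#' Filter PSMs to a target FDR by score thresholding
#'
#' Discards PSMs at or below `score_floor`, then chooses the smallest score
#' threshold at which the concatenated target-decoy FDR estimate is at or
#' below `fdr_target`, and returns the target PSMs at or above that
#' threshold. Decoy rows never appear in the output.
#'
#' @param psms data frame with `score` and `is_decoy` columns (non-empty).
#' @param score_floor hard score floor applied before the FDR search
#'   (default 20; PSMs must score strictly above it).
#' @param fdr_target FDR level in (0, 1) (default 0.01).
#' @return list with `psms` (retained target rows), `threshold` (chosen score
#'   threshold, `Inf` if unattainable), `fdr` (estimate at the threshold) and
#'   `n_discarded_floor`.
#' @export
filter_to_fdr <- function(psms, score_floor = 20, fdr_target = 0.01) {
  if (is.null(psms) || nrow(psms) == 0) stop("no PSMs")
  stopifnot(fdr_target > 0, fdr_target < 1)
  n0 <- nrow(psms)
  psms <- psms[psms$score > score_floor, , drop = FALSE]
  n_floor <- n0 - nrow(psms)
  empty <- psms[0, !(names(psms) %in% "is_decoy"), drop = FALSE]
  if (nrow(psms) == 0) {
    warning("no PSMs above the score floor; returning empty set")
    return(list(psms = empty, threshold = Inf, fdr = NA_real_,
                n_discarded_floor = n_floor))
  }
  ## sort descending; walking down the list, FDR at threshold = score[i] is
  ## (#decoys so far) / (#targets so far) counting all rows scoring >= it
  o <- order(psms$score, decreasing = TRUE)
  sc <- psms$score[o]
  dec <- psms$is_decoy[o]
  cum_dec <- cumsum(dec)
  cum_tar <- cumsum(!dec)
  ## at candidate threshold sc[i], all rows j with sc[j] >= sc[i] count; ties
  ## share the counts of the last tied position
  last_tied <- findInterval(-sc, -sc)  # index of last row with same score
  fdr_at <- cum_dec[last_tied] / pmax(1L, cum_tar[last_tied])
  ok <- which(fdr_at <= fdr_target)
  if (!length(ok)) {
    warning(sprintf("no score threshold attains FDR <= %g; returning empty set",
                    fdr_target))
    return(list(psms = empty, threshold = Inf, fdr = NA_real_,
                n_discarded_floor = n_floor))
  }
  ## smallest threshold = lowest qualifying score (largest index)
  i <- max(ok)
  thr <- sc[i]
  keep <- psms$score >= thr & !psms$is_decoy
  list(psms = psms[keep, !(names(psms) %in% "is_decoy"), drop = FALSE],
       threshold = thr,
       fdr = fdr_at[i],
       n_discarded_floor = n_floor)
}

#' Reduce PSMs to unique peptide identifications
#'
#' Keeps exactly one PSM per (run, peptide, charge): the highest-scoring one,
#' with ties broken by the smallest absolute difference between observed and
#' theoretical precursor m/z, then by original row order.
#'
#' @param psms data frame of (filtered, target) PSMs with columns `run_id`,
#'   `peptide`, `charge`, `precursor_mz`, `score`.
#' @return the deduplicated data frame, in original row order of the winners.
#' @export
deduplicate_psms <- function(psms) {
  if (is.null(psms) || nrow(psms) == 0) return(psms)
  theo <- tryCatch(peptide_mz(psms$peptide, psms$charge),
                   error = function(e) rep(NA_real_, nrow(psms)))
  mz_err <- abs(psms$precursor_mz - theo)
  mz_err[is.na(mz_err)] <- Inf
  key <- paste(psms$run_id, psms$peptide, psms$charge, sep = "\r")
  o <- order(key, -psms$score, mz_err, seq_len(nrow(psms)))
  keep <- o[!duplicated(key[o])]
  psms[sort(keep), , drop = FALSE]
}

#' Read / write a PSM table in the pipeline's TSV schema
#'
#' Columns: `run_id`, `peptide`, `charge`, `precursor_mz`, `rt_sec`, `score`,
#' `is_decoy`, `protein_acc` (additional columns are preserved).
#'
#' @param path file path.
#' @return `read_psm_table()` returns the data frame.
#' @export
read_psm_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("run_id", "peptide", "charge", "precursor_mz", "rt_sec",
            "score", "is_decoy", "protein_acc")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("PSM table ", path, " lacks columns: ",
                         paste(miss, collapse = ", "))
  df$is_decoy <- as.logical(df$is_decoy)
  df
}

#' @param psms PSM data frame.
#' @rdname read_psm_table
#' @export
write_psm_table <- function(psms, path) {
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
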