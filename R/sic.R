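#' Extract a selected ion chromatogram (SIC)
#'
#' One intensity point per MS1 scan: the sum of centroid intensities whose
#' m/z lies within `ppm_window` parts per million of `target_mz`
#' (`|mz - target| / target <= ppm_window * 1e-6`, boundaries inclusive).
#' Scans with no matching centroid contribute intensity 0.
#'
#' @param run an `ms1_run`.
#' @param target_mz target m/z (Th), > 0.
#' @param ppm_window half-width of the mass window in ppm (default 10).
#' @return a `sic_trace`: list with `run_id`, `target_mz`, `ppm_window`,
#'   `rt` (seconds, strictly increasing, one per scan) and `intensity`.
#' @export
extract_sic <- function(run, target_mz, ppm_window = 10) {
  stopifnot(inherits(run, "ms1_run"), target_mz > 0)
  tol <- target_mz * ppm_window * 1e-6
  intensity <- numeric(run$n_scans)
  pk <- run$peaks
  if (nrow(pk)) {
    mz <- NULL  # data.table NSE
    sel <- pk[mz >= target_mz - tol & mz <= target_mz + tol]
    if (nrow(sel)) {
      sums <- sel[, list(int = sum(intensity)), by = "scan"]
      intensity[sums$scan] <- sums$int
    }
  }
  new_sic_trace(run, target_mz, ppm_window, intensity)
}

new_sic_trace <- function(run, target_mz, ppm_window, intensity) {
  structure(list(run_id = run$run_id, target_mz = target_mz,
                 ppm_window = ppm_window, rt = run$rt,
                 intensity = intensity),
            class = "sic_trace")
}

## Vectorized SIC extraction for many disjoint targets in one pass over the
## run's centroids; falls back to per-target extraction if windows overlap.
## Returns a list of sic_trace in the order of `target_mz`.
extract_sic_multi <- function(run, target_mz, ppm_window = 10) {
  stopifnot(inherits(run, "ms1_run"))
  m <- length(target_mz)
  o <- order(target_mz)
  tmz <- target_mz[o]
  tol <- tmz * ppm_window * 1e-6
  lo <- tmz - tol
  hi <- tmz + tol * (1 + 1e-12)  # keep upper boundary inclusive
  if (any(hi[-m] > lo[-1])) {
    return(lapply(target_mz, function(t) extract_sic(run, t, ppm_window)))
  }
  intens <- matrix(0, nrow = run$n_scans, ncol = m)
  pk <- run$peaks
  if (nrow(pk)) {
    bounds <- as.vector(rbind(lo, hi))
    slot <- findInterval(pk$mz, bounds)
    inwin <- slot %% 2L == 1L
    if (any(inwin)) {
      tgt <- o[(slot[inwin] + 1L) %/% 2L]
      dd <- data.table::data.table(tgt = tgt, scan = pk$scan[inwin],
                                   int = pk$intensity[inwin])
      sums <- dd[, list(int = sum(int)), by = c("tgt", "scan")]
      intens[cbind(sums$scan, sums$tgt)] <- sums$int
    }
  }
  lapply(seq_len(m), function(i)
    new_sic_trace(run, target_mz[i], ppm_window, intens[, i]))
}

#' Trapezoidal integration of a SIC segment
#'
#' Integrates the raw trace intensity between two retention-time bounds
#' (closed interval, trapezoid rule on the scan grid), in intensity-seconds.
#'
#' @param trace a `sic_trace`.
#' @param left_rt,right_rt integration bounds in seconds, `left_rt <
#'   right_rt`, both within the trace span.
#' @return the peak area (intensity * seconds).
#' @export
integrate_peak <- function(trace, left_rt, right_rt) {
  stopifnot(inherits(trace, "sic_trace"))
  if (!(left_rt < right_rt)) stop("left_rt must be < right_rt")
  rt <- trace$rt
  if (left_rt < rt[1] || right_rt > rt[length(rt)]) {
    stop("integration bounds outside trace span")
  }
  sel <- which(rt >= left_rt & rt <= right_rt)
  if (length(sel) < 2) return(0)
  x <- rt[sel]
  y <- trace$intensity[sel]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.sic_trace <- function(x, ...) {
  cat(sprintf("<sic_trace %s @ m/z %.4f +/- %g ppm: %d scans, max %.3g>\n",
              x$run_id, x$target_mz, x$ppm_window, length(x$rt),
              max(x$intensity)))
  invisible(x)
}
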