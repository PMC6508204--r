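#' Retention-time alignment across runs
#'
#' Fits, for every run, a strictly monotone mapping from that run's retention
#' times to a reference run's retention times, anchored on the apexes of
#' peptides whose peaks were detected (MS/MS-anchored, not inferred) in both
#' runs. The reference run is the one with the most detected anchors (ties:
#' first by run order) and receives the identity mapping.
#'
#' The fit is a locally weighted regression (degree-1 loess; ordinary least
#' squares below 10 anchors) through the anchor apex pairs, evaluated on a
#' grid, made monotone by isotonic regression, and interpolated linearly with
#' linear extrapolation beyond the anchor range. Up to `top_n` anchors per
#' run, preferring the highest identification scores.
#'
#' @param apexes data frame with one row per detected (run, peptide) peak:
#'   columns `run_id`, `peptide`, `apex_rt` and optionally `score` (used to
#'   pick the top anchors).
#' @param reference reference `run_id`, or `NULL` to auto-select.
#' @param top_n maximum number of anchors per run (default 200).
#' @param min_anchors minimum shared anchors required (default 5).
#' @return a `warp_set`: named list (one per run) of `warp_fun` objects, each
#'   with `fun` (run RT to reference RT), `inverse`, `anchors`, `residuals`
#'   and `reference`.
#' @export
align_retention_times <- function(apexes, reference = NULL, top_n = 200,
                                  min_anchors = 5) {
  stopifnot(all(c("run_id", "peptide", "apex_rt") %in% names(apexes)))
  runs <- unique(apexes$run_id)
  if (is.null(apexes$score)) apexes$score <- 0
  by_run <- split(apexes, apexes$run_id)[runs]
  if (is.null(reference)) {
    n_det <- vapply(by_run, nrow, integer(1))
    reference <- runs[which.max(n_det)]
  }
  ref <- by_run[[reference]]
  out <- setNames(vector("list", length(runs)), runs)
  for (rid in runs) {
    if (rid == reference) {
      out[[rid]] <- identity_warp(rid, reference)
      next
    }
    cur <- by_run[[rid]]
    shared <- merge(cur[, c("peptide", "apex_rt", "score")],
                    ref[, c("peptide", "apex_rt")],
                    by = "peptide", suffixes = c("_run", "_ref"))
    if (nrow(shared) < min_anchors) {
      stop(sprintf("insufficient anchors for run %s: %d < %d", rid,
                   nrow(shared), min_anchors))
    }
    shared <- shared[order(-shared$score), ][seq_len(min(top_n, nrow(shared))), ]
    out[[rid]] <- fit_warp(shared$apex_rt_run, shared$apex_rt_ref, rid,
                           reference)
  }
  structure(out, class = "warp_set", reference = reference)
}

identity_warp <- function(run_id, reference) {
  structure(list(run_id = run_id, reference = reference,
                 fun = identity, inverse = identity,
                 anchors = data.frame(rt_run = numeric(0),
                                      rt_ref = numeric(0)),
                 residuals = numeric(0)),
            class = "warp_fun")
}

fit_warp <- function(rt_run, rt_ref, run_id, reference) {
  o <- order(rt_run)
  rt_run <- rt_run[o]; rt_ref <- rt_ref[o]
  grid <- seq(min(rt_run), max(rt_run), length.out = 256)
  if (length(rt_run) >= 10) {
    fit <- stats::loess(rt_ref ~ rt_run, degree = 1, span = 0.75,
                        family = "symmetric",
                        control = stats::loess.control(surface = "direct"))
    pred <- stats::predict(fit, data.frame(rt_run = grid))
    fitted_at_anchor <- stats::predict(fit, data.frame(rt_run = rt_run))
  } else {
    fit <- stats::lm(rt_ref ~ rt_run)
    pred <- stats::predict(fit, data.frame(rt_run = grid))
    fitted_at_anchor <- stats::predict(fit, data.frame(rt_run = rt_run))
  }
  ## enforce strict monotonicity: isotonic regression plus a hair of slope
  iso <- stats::isoreg(grid, pred)$yf
  iso <- iso + seq_along(iso) * 1e-9
  fun <- warp_interpolator(grid, iso)
  inv <- warp_interpolator(iso, grid)
  structure(list(run_id = run_id, reference = reference, fun = fun,
                 inverse = inv,
                 anchors = data.frame(rt_run = rt_run, rt_ref = rt_ref),
                 residuals = rt_ref - fitted_at_anchor),
            class = "warp_fun")
}

## linear interpolation inside the fitted range, linear extrapolation using
## the boundary slopes outside it
warp_interpolator <- function(x, y) {
  n <- length(x)
  slope_lo <- (y[2] - y[1]) / (x[2] - x[1])
  slope_hi <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  force(x); force(y)
  function(v) {
    out <- stats::approx(x, y, xout = v, rule = 2)$y
    lo <- v < x[1]; hi <- v > x[n]
    out[lo] <- y[1] + (v[lo] - x[1]) * slope_lo
    out[hi] <- y[n] + (v[hi] - x[n]) * slope_hi
    out
  }
}

#' Map retention times through a warping function
#'
#' @param warp a `warp_fun` from [align_retention_times()].
#' @param rt retention times in the run's own frame (seconds).
#' @param inverse if `TRUE`, map reference-frame times into the run's frame.
#' @return mapped retention times (seconds).
#' @export
warp_rt <- function(warp, rt, inverse = FALSE) {
  stopifnot(inherits(warp, "warp_fun"))
  if (inverse) warp$inverse(rt) else warp$fun(rt)
}

#' Infer a peak for a peptide lacking an identification in a run
#'
#' Extracts the peptide's SIC in the run and searches the detected peaks for
#' an apex within `search_halfwindow` of the alignment-predicted retention
#' time; the nearest such peak is returned, flagged `inferred`. If none is
#' found, a fixed window of `fallback_window` seconds centred on the
#' predicted time is integrated instead.
#'
#' @param run an `ms1_run`.
#' @param target_mz the peptide's precursor m/z (Th).
#' @param predicted_rt alignment-predicted apex retention time in the run's
#'   frame (seconds); must lie within the run's RT span.
#' @param params [peak_detect_params()] for detection on the fresh trace.
#' @param ppm_window SIC mass window (ppm).
#' @param search_halfwindow half-width of the apex search window (seconds).
#' @param fallback_window width of the blind integration window (seconds).
#' @param trace,peaks optional precomputed `sic_trace` and detected peak
#'   table for this (run, m/z), to avoid recomputation.
#' @return a one-row peak data frame with `inferred = TRUE` and a `method`
#'   column (`"matched"` or `"window"`).
#' @export
infer_missing_peak <- function(run, target_mz, predicted_rt,
                               params = peak_detect_params(),
                               ppm_window = 10,
                               search_halfwindow = 30,
                               fallback_window = 20,
                               trace = NULL, peaks = NULL) {
  if (is.null(trace)) trace <- extract_sic(run, target_mz, ppm_window)
  span <- range(trace$rt)
  if (predicted_rt < span[1] || predicted_rt > span[2]) {
    stop(sprintf("predicted retention time %.1f s outside run span [%.1f, %.1f]",
                 predicted_rt, span[1], span[2]))
  }
  if (is.null(peaks)) peaks <- detect_peaks_multipass(trace, params)
  if (nrow(peaks)) {
    d <- abs(peaks$apex_rt - predicted_rt)
    j <- which.min(d)
    if (d[j] <= search_halfwindow) {
      hit <- peaks[j, , drop = FALSE]
      hit$inferred <- TRUE
      hit$method <- "matched"
      rownames(hit) <- NULL
      return(hit)
    }
  }
  lft <- max(span[1], predicted_rt - fallback_window / 2)
  rgt <- min(span[2], predicted_rt + fallback_window / 2)
  data.frame(apex_rt = predicted_rt, left_rt = lft, right_rt = rgt,
             area = integrate_peak(trace, lft, rgt), snr = NA_real_,
             pass_index = NA_integer_,
             apex_intensity = NA_real_, inferred = TRUE, method = "window")
}
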