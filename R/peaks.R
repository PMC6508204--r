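#' Parameters for multi-pass CWT peak detection
#'
#' The detector makes one pass per entry of `min_width_passes`, widest first,
#' each pass running continuous-wavelet-transform ridge detection with scales
#' spanning that pass's minimum width up to `max_width`. Later (narrower)
#' passes only contribute peaks that do not overlap a peak from an earlier
#' pass.
#'
#' @param min_width_passes minimum peak widths per pass in seconds, widest
#'   first (default `c(20, 10, 5, 2)`; all within `[2, 20]`).
#' @param max_width maximum peak width in seconds (default 80).
#' @param snr_threshold minimum signal-to-noise ratio: apex raw intensity
#'   over the sigma-scaled median absolute deviation of the trace outside
#'   detected peak regions (default 10).
#' @param scales_per_pass number of geometrically spaced wavelet scales per
#'   pass (default 10).
#' @return a `peak_detect_params` list.
#' @export
peak_detect_params <- function(min_width_passes = c(20, 10, 5, 2),
                               max_width = 80,
                               snr_threshold = 10,
                               scales_per_pass = 10L) {
  if (any(min_width_passes < 2 | min_width_passes > 20))
    stop_config("min_width_passes", "pass widths must lie in [2, 20] seconds")
  if (is.unsorted(rev(min_width_passes)))
    stop_config("min_width_passes", "must be ordered widest first")
  if (max_width <= max(min_width_passes))
    stop_config("max_width", "must exceed the widest pass minimum")
  if (snr_threshold <= 0) stop_config("snr_threshold", "must be > 0")
  structure(list(min_width_passes = min_width_passes, max_width = max_width,
                 snr_threshold = snr_threshold,
                 scales_per_pass = as.integer(scales_per_pass)),
            class = "peak_detect_params")
}

## Ricker (Mexican-hat) wavelet kernel FFTs are cached per (fft length,
## scale-in-points) because the detector runs on thousands of traces that
## share one scan grid.
.kernel_cache <- new.env(parent = emptyenv())

ricker_kernel_fft <- function(L, a_pts) {
  key <- paste(L, signif(a_pts, 8))
  got <- .kernel_cache[[key]]
  if (!is.null(got)) return(got)
  K <- min(ceiling(4 * a_pts), floor((L - 1) / 2))
  k <- seq_len(K)
  u <- k / a_pts
  psi0 <- 1
  psik <- (1 - u^2) * exp(-u^2 / 2)
  kern <- numeric(L)
  kern[1] <- psi0
  kern[1 + k] <- psik
  kern[L + 1 - k] <- psik
  kern <- kern / sqrt(a_pts)
  out <- list(fft = stats::fft(kern), l2 = sqrt(sum(kern^2)))
  .kernel_cache[[key]] <- out
  out
}

cwt_coefs <- function(x_fft, L, n, a_pts) {
  k <- ricker_kernel_fft(L, a_pts)
  list(coef = Re(stats::fft(x_fft * k$fft, inverse = TRUE))[seq_len(n)] / L,
       l2 = k$l2)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n] &
          v[2:(n - 1)] > 0) + 1L
}

## Link per-scale CWT maxima into ridges, largest scale first. Returns a list
## of ridges, each with the linked positions and coefficient values.
link_ridges <- function(maxima, coefs, a_pts, gap_max = 2L) {
  ns <- length(maxima)
  ridges <- list()
  active <- list()  # each: pos, scales (indices), coef, gap
  for (s in rev(seq_len(ns))) {  # widest scale first
    tol <- max(2, a_pts[s])
    cand <- maxima[[s]]
    claimed <- rep(FALSE, length(cand))
    for (i in seq_along(active)) {
      r <- active[[i]]
      if (length(cand)) {
        d <- abs(cand - r$pos)
        j <- which.min(d)
        if (length(j) && d[j] <= tol && !claimed[j]) {
          claimed[j] <- TRUE
          r$pos <- cand[j]
          r$scales <- c(r$scales, s)
          r$coef <- c(r$coef, coefs[[s]][cand[j]])
          r$gap <- 0L
          active[[i]] <- r
          next
        }
      }
      r$gap <- r$gap + 1L
      active[[i]] <- r
    }
    ## retire ridges that gapped out
    done <- vapply(active, function(r) r$gap > gap_max, logical(1))
    ridges <- c(ridges, active[done])
    active <- active[!done]
    ## unclaimed maxima start new ridges
    for (j in which(!claimed)) {
      active[[length(active) + 1L]] <- list(pos = cand[j], scales = s,
                                            coef = coefs[[s]][cand[j]],
                                            gap = 0L)
    }
  }
  c(ridges, active)
}

## Boundary determination by descent on the raw trace from the apex: walk
## outward tracking the running minimum, stopping when the intensity reaches
## the local baseline or clearly rises off the minimum (tolerating
## scan-to-scan multiplicative noise); the boundary is the running minimum.
descend_bounds <- function(x, apex, baseline) {
  n <- length(x)
  one_side <- function(step, limit) {
    i <- apex
    vmin <- x[apex]; imin <- apex
    while (i != limit) {
      i <- i + step
      if (x[i] < vmin) { vmin <- x[i]; imin <- i }
      if (x[i] <= baseline) { return(i) }
      if (x[i] > 2 * vmin + 2 * baseline) break
    }
    imin
  }
  c(one_side(-1L, 1L), one_side(1L, n))
}

#' Multi-pass CWT peak detection on a SIC trace
#'
#' For each pass (widest minimum width first) the trace is transformed with
#' Mexican-hat wavelets at `scales_per_pass` geometrically spaced scales
#' between half the pass's minimum width and half the maximum width; local
#' coefficient maxima linked across at least three scales form ridge
#' candidates. Each candidate's apex is refined on the raw intensities, its
#' boundaries are set by descent on the raw (non-transformed) data, and it is
#' kept if its signal-to-noise ratio is at least `snr_threshold` and its
#' width is compatible with the pass. Peaks from later passes are kept only
#' when their retention-time extent does not overlap an earlier-pass peak.
#'
#' @param trace a `sic_trace` (non-empty).
#' @param params a [peak_detect_params()].
#' @return a data frame (possibly empty) with columns `apex_rt`, `left_rt`,
#'   `right_rt`, `area`, `snr`, `pass_index`, `apex_intensity`, `inferred`
#'   (all `FALSE` here), sorted by `apex_rt`.
#' @export
detect_peaks_multipass <- function(trace, params = peak_detect_params()) {
  stopifnot(inherits(trace, "sic_trace"))
  x <- trace$intensity
  rt <- trace$rt
  n <- length(x)
  empty <- data.frame(apex_rt = numeric(0), left_rt = numeric(0),
                      right_rt = numeric(0), area = numeric(0),
                      snr = numeric(0), pass_index = integer(0),
                      apex_intensity = numeric(0), inferred = logical(0))
  if (n < 5 || all(x == 0)) return(empty)
  dt <- (rt[n] - rt[1]) / (n - 1)

  max_halfwidth_pts <- ceiling(4 * params$max_width / 2 / dt)
  L <- stats::nextn(n + max_halfwidth_pts + 1L, 2)
  x_fft <- stats::fft(c(x, numeric(L - n)))

  accepted <- list()
  acc_l <- numeric(0); acc_r <- numeric(0)
  for (pass in seq_along(params$min_width_passes)) {
    mw <- params$min_width_passes[pass]
    scales_s <- exp(seq(log(mw / 2), log(params$max_width / 2),
                        length.out = params$scales_per_pass))
    a_pts <- scales_s / dt
    ## noise: sigma-scaled MAD outside regions already claimed by peaks
    mask <- rep(TRUE, n)
    for (i in seq_along(acc_l)) mask[rt >= acc_l[i] & rt <= acc_r[i]] <- FALSE
    noise <- if (sum(mask) >= 5) max(stats::mad(x[mask]), 1) else 1

    cw <- lapply(a_pts, function(a) cwt_coefs(x_fft, L, n, a))
    coefs <- lapply(cw, `[[`, "coef")
    ## prune noise maxima: keep only coefficients clearly above the level
    ## expected from propagating the baseline noise through the wavelet
    maxima <- lapply(seq_along(coefs), function(s) {
      mm <- local_maxima(coefs[[s]])
      mm[coefs[[s]][mm] > 3 * noise * cw[[s]]$l2]
    })
    ridges <- link_ridges(maxima, coefs, a_pts)
    ridges <- Filter(function(r) length(r$scales) >= 3L, ridges)
    if (!length(ridges)) next
    strength <- vapply(ridges, function(r) max(r$coef), numeric(1))
    for (r in ridges[order(strength, decreasing = TRUE)]) {
      ## refine apex on the raw trace near the ridge position
      w <- max(2L, round(a_pts[min(r$scales)]))
      win <- max(1L, r$pos - w):min(n, r$pos + w)
      apex <- win[which.max(x[win])]
      snr <- x[apex] / noise
      if (snr < params$snr_threshold) next
      b <- descend_bounds(x, apex, baseline = noise)
      if (b[1] == apex && apex > 1L) b[1] <- apex - 1L
      if (b[2] == apex && apex < n) b[2] <- apex + 1L
      if (!(b[1] < apex && apex < b[2])) next
      if (b[2] - b[1] < 2L) next
      width <- rt[b[2]] - rt[b[1]]
      if (width + dt < mw) next
      if (width > params$max_width) {
        ## clip symmetrically around the apex to the maximum width
        half <- floor(params$max_width / 2 / dt)
        b <- c(max(b[1], apex - half), min(b[2], apex + half))
        width <- rt[b[2]] - rt[b[1]]
      }
      lft <- rt[b[1]]; rgt <- rt[b[2]]
      if (any(acc_l <= rgt & acc_r >= lft)) next  # overlap: earlier peak wins
      acc_l <- c(acc_l, lft); acc_r <- c(acc_r, rgt)
      accepted[[length(accepted) + 1L]] <- data.frame(
        apex_rt = rt[apex], left_rt = lft, right_rt = rgt,
        area = integrate_peak(trace, lft, rgt), snr = snr,
        pass_index = pass, apex_intensity = x[apex], inferred = FALSE)
    }
  }
  if (!length(accepted)) return(empty)
  out <- do.call(rbind, accepted)
  out[order(out$apex_rt), , drop = FALSE]
}
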