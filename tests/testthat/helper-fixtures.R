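## Shared fixture builders. Everything is generated in code; no data files.

## A SIC trace built directly from vectors (bypassing a full run).
make_trace <- function(rt, intensity, target_mz = 500, run_id = "fixture") {
  structure(list(run_id = run_id, target_mz = target_mz, ppm_window = 10,
                 rt = rt, intensity = intensity),
            class = "sic_trace")
}

## A noiseless Gaussian elution peak sampled on a uniform grid.
gaussian_trace <- function(sigma, amp = 1e4, dt = sigma / 4,
                           center = NULL, span = NULL) {
  span <- span %||% (16 * sigma)
  center <- center %||% (span / 2)
  rt <- seq(0, span, by = dt)
  make_trace(rt, amp * exp(-(rt - center)^2 / (2 * sigma^2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## A tiny in-memory MS1 run assembled by hand.
make_run <- function(rt, scan, mz, intensity, run_id = "handmade") {
  structure(list(run_id = run_id, rt = rt,
                 peaks = data.table::data.table(scan = scan, mz = mz,
                                                intensity = intensity),
                 n_scans = length(rt)),
            class = "ms1_run")
}

## Small default experiment shared by several tests (cached per session).
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_peptides = 60, n_proteins = 15, frac_null = 0.7,
                          seed = 101)
      cache <<- generate_experiment(cfg)
    }
    cache
  }
})
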