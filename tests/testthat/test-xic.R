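test_that("SIC window arithmetic is ppm-exact and boundary-inclusive", {
  ## 10 ppm around 500 Th accepts [499.995, 500.005]
  run <- make_run(rt = c(0, 1, 2, 3), scan = c(1L, 2L, 3L, 4L),
                  mz = c(499.995, 500.005, 499.9949, 500.0051),
                  intensity = c(10, 20, 40, 80))
  tr <- extract_sic(run, 500, 10)
  expect_equal(tr$intensity, c(10, 20, 0, 0))
  expect_equal(length(tr$rt), run$n_scans)
  ## no centroids near the target: all-zero trace of scan length
  tr2 <- extract_sic(run, 900, 10)
  expect_equal(tr2$intensity, rep(0, 4))
})

test_that("multi-target extraction equals one-at-a-time extraction", {
  ex <- small_experiment()
  run <- ex$runs[[3]]
  mzs <- head(ex$ground_truth$peptides$mz, 20)
  multi <- lfqpipe:::extract_sic_multi(run, mzs, 10)
  for (i in seq_along(mzs)) {
    single <- extract_sic(run, mzs[i], 10)
    expect_equal(multi[[i]]$intensity, single$intensity)
  }
})

test_that("trapezoidal integration matches rectangles and closed forms", {
  flat <- make_trace(rt = seq(0, 10, 1), intensity = rep(100, 11))
  expect_equal(integrate_peak(flat, 0, 10), 1000)
  zero <- make_trace(rt = seq(0, 10, 1), intensity = rep(0, 11))
  expect_equal(integrate_peak(zero, 0, 10), 0)
  expect_error(integrate_peak(flat, -5, 10), "outside")
  expect_error(integrate_peak(flat, 8, 2))
  ## sampled Gaussian vs amplitude * sigma * sqrt(2 pi), dt <= sigma / 3
  for (sigma in c(1, 3, 8)) {
    tr <- gaussian_trace(sigma, amp = 5000, dt = sigma / 3)
    got <- integrate_peak(tr, min(tr$rt), max(tr$rt))
    expect_equal(got, 5000 * sigma * sqrt(2 * pi), tolerance = 0.02)
  }
})

test_that("a flat noise trace yields no peaks", {
  set.seed(31)
  tr <- make_trace(rt = 0:400, intensity = runif(401, 0, 50))
  expect_equal(nrow(detect_peaks_multipass(tr)), 0L)
})

test_that("a single noiseless Gaussian is found once, at the right place", {
  sigma <- 2  # 8 s wide peak
  tr <- gaussian_trace(sigma, amp = 2e4, dt = 0.5, center = 100, span = 300)
  pks <- detect_peaks_multipass(tr)
  expect_equal(nrow(pks), 1L)
  expect_lte(abs(pks$apex_rt - 100), 0.5)
  expect_equal(pks$area, 2e4 * sigma * sqrt(2 * pi), tolerance = 0.05)
  expect_true(pks$left_rt < pks$apex_rt && pks$apex_rt < pks$right_rt)
})

test_that("wide and narrow peaks are assigned to the right passes", {
  dt <- 0.25
  rt <- seq(0, 300, dt)
  s_wide <- 15 / 4; s_narrow <- 3 / 4  # 15 s and 3 s peaks, 60 s apart
  y <- 3e4 * exp(-(rt - 100)^2 / (2 * s_wide^2)) +
       3e4 * exp(-(rt - 160)^2 / (2 * s_narrow^2))
  pks <- detect_peaks_multipass(make_trace(rt, y))
  expect_equal(nrow(pks), 2L)
  wide <- pks[which.min(abs(pks$apex_rt - 100)), ]
  narrow <- pks[which.min(abs(pks$apex_rt - 160)), ]
  expect_gt(narrow$pass_index, wide$pass_index)
})

test_that("isolated peaks are detected exactly once regardless of width", {
  for (width in c(3, 6, 12, 20)) {
    sigma <- width / 4
    tr <- gaussian_trace(sigma, amp = 1e5, dt = min(0.5, sigma / 3),
                         center = 150, span = 300)
    pks <- detect_peaks_multipass(tr)
    expect_equal(nrow(pks), 1L, info = paste("width", width))
    expect_lte(abs(pks$apex_rt - 150), 1)
  }
})

test_that("reported peaks always satisfy the boundary invariants", {
  ex <- small_experiment()
  run <- ex$runs[[1]]
  mzs <- ex$ground_truth$peptides$mz[1:25]
  for (tr in lfqpipe:::extract_sic_multi(run, mzs, 10)) {
    pks <- detect_peaks_multipass(tr)
    if (!nrow(pks)) next
    expect_true(all(pks$left_rt < pks$apex_rt))
    expect_true(all(pks$apex_rt < pks$right_rt))
    expect_true(all(pks$right_rt - pks$left_rt <= 80))
    expect_true(all(pks$area >= 0))
    expect_true(all(pks$snr >= 10))
  }
})

make_qm <- function(area, peptides = NULL, flags = NULL) {
  m <- nrow(area); n <- ncol(area)
  structure(list(
    area = area,
    flags = flags %||% matrix("detected", m, n, dimnames = dimnames(area)),
    floored = matrix(FALSE, m, n, dimnames = dimnames(area)),
    peptides = peptides %||% data.frame(
      peptide = rownames(area), charge = 2L, mz = NA_real_,
      protein_acc = paste0("PR", seq_len(m)), stringsAsFactors = FALSE),
    run_ids = colnames(area), warps = NULL, normalization = NULL),
    class = "quant_matrix")
}

test_that("spike-in normalization is a no-op on identical runs and is scale invariant", {
  area <- matrix(c(100, 2000, 5e4, 100, 2000, 5e4), ncol = 2,
                 dimnames = list(c("DRVYHPF", "PEPA", "PEPB"), c("r1", "r2")))
  qm <- make_qm(area)
  norm <- normalize_to_standard(qm)
  expect_equal(norm$area, area)

  ## run 2 = run 1 with every intensity doubled, standard included: after
  ## normalization both runs report identical areas
  scaled <- make_qm(sweep(area, 2, c(1, 2), `*`))
  norm2 <- normalize_to_standard(scaled)
  expect_equal(norm2$area[, 1], norm2$area[, 2])
  expect_equal(unname(norm2$area[, 1]), unname(1.5 * area[, 1]))
})

test_that("random per-run scale factors are removed by normalization", {
  set.seed(32)
  base <- matrix(exp(runif(60, log(2e3), log(1e6))), 10, 6)
  rownames(base) <- c("DRVYHPF", paste0("PEP", 1:9))
  colnames(base) <- paste0("r", 1:6)
  fac <- runif(6, 0.5, 2)
  qm <- make_qm(sweep(base, 2, fac, `*`))
  norm <- normalize_to_standard(qm)
  std <- norm$area["DRVYHPF", ]
  expect_equal(unname(std), rep(mean(std), 6))
  expect_error(normalize_to_standard(make_qm(base[-1, , drop = FALSE])),
               "not present")
})

test_that("the reporting floor censors and flags boundary cases exactly", {
  area <- matrix(c(999, 1000, 1001, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("r1", "r2")))
  qm <- apply_floor(make_qm(area), 1000)
  expect_equal(as.vector(qm$area), c(1000, 1000, 1001, 1000))
  expect_equal(as.vector(qm$floored), c(TRUE, FALSE, FALSE, TRUE))
  allzero <- apply_floor(make_qm(matrix(0, 2, 2,
    dimnames = list(c("a", "b"), c("r1", "r2")))), 1000)
  expect_true(all(allzero$area == 1000) && all(allzero$floored))
})
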