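test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_peptides = 25, n_proteins = 5, seed = 3)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$runs, b$runs)
  expect_identical(a$psms, b$psms)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$annotation, b$annotation)
  ## and a different seed changes the raw data
  c <- generate_experiment(synth_config(n_peptides = 25, n_proteins = 5,
                                        seed = 4))
  expect_false(identical(a$runs[[1]]$peaks, c$runs[[1]]$peaks))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synth_config(frac_null = 1.2), "frac_null")
  expect_error(synth_config(replicates_per_condition = 1),
               "replicates_per_condition")
  expect_error(synth_config(peak_width_range_s = c(1, 30)),
               "peak_width_range_s")
  expect_error(synth_config(regulated_conditions = "WT"),
               "regulated_conditions")
})

test_that("frac_null = 1 forces all true log2 fold changes to zero", {
  cfg <- synth_config(n_peptides = 40, n_proteins = 8, frac_null = 1,
                      seed = 5)
  gt <- generate_experiment(cfg)$ground_truth$peptides
  for (cond in cfg$conditions) {
    expect_true(all(gt[[paste0("log2fc_", cond)]] == 0))
  }
})

test_that("the spiked standard has identical true area in every run", {
  ex <- small_experiment()
  pr <- ex$ground_truth$peptide_runs
  std <- pr[pr$peptide == ex$config$standard_peptide, ]
  expect_equal(nrow(std), length(ex$runs))
  expect_equal(std$area_true, rep(ex$config$standard_abundance, nrow(std)))
  ## realized area is exempt from replicate-level noise too
  expect_equal(std$area_realized, std$area_true)
})

test_that("noiseless elution integrates to the closed-form Gaussian area", {
  cfg <- synth_config(n_peptides = 8, n_proteins = 2, intensity_cv = 0,
                      baseline_level_int = 0, mz_jitter_ppm = 0,
                      scan_interval_s = 0.5, seed = 11)
  ex <- generate_experiment(cfg)
  gt <- ex$ground_truth
  run <- ex$runs[[1]]
  pr <- gt$peptide_runs[gt$peptide_runs$run_id == run$run_id, ]
  for (i in seq_len(nrow(pr))) {
    pep <- gt$peptides[gt$peptides$peptide == pr$peptide[i], ]
    tr <- extract_sic(run, pep$mz, 10)
    got <- integrate_peak(tr, min(tr$rt), max(tr$rt))
    ## closed form: amplitude * sigma * sqrt(2*pi) = configured true area
    expect_equal(got, pr$area_true[i], tolerance = 0.02)
  }
  ## area linearity: integrated area proportional to configured abundance
  areas <- vapply(seq_len(nrow(pr)), function(i) {
    pep <- gt$peptides[gt$peptides$peptide == pr$peptide[i], ]
    integrate_peak(extract_sic(run, pep$mz, 10), min(run$rt), max(run$rt))
  }, numeric(1))
  fit <- summary(lm(areas ~ 0 + pr$area_true))
  expect_gt(fit$r.squared, 1 - 1e-6)
})

test_that("configured inter-run RT shift moves every apex by that shift", {
  cfg <- synth_config(n_peptides = 15, n_proteins = 3, intensity_cv = 0,
                      baseline_level_int = 0, rt_shift_per_run_s = 10,
                      conditions = c("WT", "KD11"),
                      regulated_conditions = "KD11", seed = 9)
  ex <- generate_experiment(cfg)
  gt <- ex$ground_truth
  r1 <- ex$runs[["WT_1"]]; r2 <- ex$runs[["WT_2"]]
  for (i in seq_len(nrow(gt$peptides))) {
    t1 <- extract_sic(r1, gt$peptides$mz[i], 10)
    t2 <- extract_sic(r2, gt$peptides$mz[i], 10)
    a1 <- t1$rt[which.max(t1$intensity)]
    a2 <- t2$rt[which.max(t2$intensity)]
    expect_lte(abs((a2 - a1) - 10), cfg$scan_interval_s)
  }
})

test_that("empty peptide set with zero baseline gives empty spectra", {
  cfg <- synth_config(n_peptides = 5, n_proteins = 1,
                      baseline_level_int = 0, seed = 2)
  empty_params <- data.frame(peptide = character(0), mz = numeric(0),
                             sigma_s = numeric(0), rt_s = numeric(0),
                             area_realized = numeric(0))
  run <- simulate_run(empty_params, 1, cfg)
  expect_equal(nrow(run$peaks), 0L)
  expect_equal(run$n_scans, length(run$rt))
})

test_that("edge-eluting peptides trigger a truncation warning", {
  cfg <- synth_config(n_peptides = 5, n_proteins = 1, seed = 2)
  params <- data.frame(peptide = "EDGEPEP", mz = 500, sigma_s = 5,
                       rt_s = 3, area_realized = 1e5)
  expect_warning(simulate_run(params, 1, cfg), "truncated")
})

test_that("PSM tables carry decoys, misses and correctness ground truth", {
  cfg <- synth_config(n_peptides = 200, n_proteins = 40,
                      frac_missing_msms = 0.3, frac_false_psms = 0.1,
                      decoy_fraction = 0.1, seed = 21)
  ex <- generate_experiment(cfg)
  all_psms <- do.call(rbind, ex$psms)
  expect_true(any(all_psms$is_decoy))
  flags <- ex$ground_truth$psm_flags
  expect_setequal(flags$psm_id, all_psms$psm_id)
  ## every decoy is flagged incorrect
  dec <- all_psms$psm_id[all_psms$is_decoy]
  expect_true(all(!flags$is_correct[flags$psm_id %in% dec]))
  ## correct identifications cover (1 - frac_missing)(1 - frac_false) of
  ## peptide-run pairs (false matches consume identification slots)
  n_pairs <- cfg$n_peptides * length(ex$runs)
  n_present <- sum(!all_psms$is_decoy &
                     all_psms$peptide %in% ex$ground_truth$peptides$peptide)
  expected <- (1 - cfg$frac_missing_msms) * (1 - cfg$frac_false_psms)
  expect_lt(abs(n_present / n_pairs - expected), 0.05)
  ## decoy scores stochastically dominated by correct-target scores
  correct_ids <- flags$psm_id[flags$is_correct]
  expect_gt(median(all_psms$score[all_psms$psm_id %in% correct_ids]),
            median(all_psms$score[all_psms$is_decoy]) + 10)
})
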