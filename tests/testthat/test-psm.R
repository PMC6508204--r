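brute_force_fdr <- function(psms, thr) {
  d <- 0L; t <- 0L
  for (i in seq_len(nrow(psms))) {
    if (psms$score[i] >= thr) {
      if (psms$is_decoy[i]) d <- d + 1L else t <- t + 1L
    }
  }
  d / max(1L, t)
}

test_that("target-decoy FDR estimate matches its definition", {
  psms <- data.frame(score = c(rep(50, 1000), rep(50, 10)),
                     is_decoy = rep(c(FALSE, TRUE), c(1000, 10)))
  expect_equal(estimate_fdr_at_threshold(psms, 40), 0.01)
  ## all decoys below the threshold
  psms2 <- data.frame(score = c(100, 90, 5, 4),
                      is_decoy = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(estimate_fdr_at_threshold(psms2, 50), 0)
  expect_error(estimate_fdr_at_threshold(psms[0, ], 10), "no PSMs")
})

test_that("FDR estimate equals a brute-force count on random sets", {
  set.seed(71)
  for (rep in 1:10) {
    psms <- simulate_psm_scores(200, frac_false = 0.2, n_decoys = 40)
    for (thr in quantile(psms$score, c(0.1, 0.5, 0.9))) {
      expect_equal(estimate_fdr_at_threshold(psms, thr),
                   brute_force_fdr(psms, thr))
    }
  }
})

## exhaustive-threshold reference: scan every distinct score as candidate
oracle_filter <- function(psms, floor = 20, target = 0.01) {
  psms <- psms[psms$score > floor, , drop = FALSE]
  cand <- sort(unique(psms$score))
  ok <- cand[vapply(cand, function(t)
    brute_force_fdr(psms, t) <= target, logical(1))]
  if (!length(ok)) return(NULL)
  thr <- min(ok)
  list(psms = psms[psms$score >= thr & !psms$is_decoy, , drop = FALSE],
       threshold = thr)
}

test_that("filter_to_fdr matches the exhaustive-threshold scan", {
  set.seed(72)
  for (rep in 1:8) {
    psms <- simulate_psm_scores(300, frac_false = 0.15, n_decoys = 45,
                                decoy_score_offset = 15)
    got <- suppressWarnings(filter_to_fdr(psms, score_floor = 20,
                                          fdr_target = 0.05))
    want <- oracle_filter(psms, 20, 0.05)
    if (is.null(want)) {
      expect_equal(nrow(got$psms), 0L)
    } else {
      expect_equal(got$threshold, want$threshold)
      expect_setequal(got$psms$peptide, want$psms$peptide)
    }
  }
})

test_that("filter_to_fdr handles clean separations and hopeless sets", {
  psms <- data.frame(peptide = paste0("P", 1:12), score = rep(c(100, 5), 6),
                     is_decoy = rep(c(FALSE, TRUE), 6))
  got <- filter_to_fdr(psms, score_floor = 20, fdr_target = 0.01)
  expect_equal(nrow(got$psms), 6)
  expect_lte(got$threshold, 100)
  expect_false(any(got$psms$is_decoy %||% FALSE))

  ## the top score is a decoy: no attainable threshold at 1%
  bad <- data.frame(peptide = paste0("P", 1:4), score = c(90, 50, 40, 30),
                    is_decoy = c(TRUE, FALSE, FALSE, FALSE))
  expect_warning(res <- filter_to_fdr(bad, 20, 0.01), "no score threshold")
  expect_equal(nrow(res$psms), 0L)

  ## idempotence: refiltering the retained targets changes nothing
  again <- suppressWarnings(filter_to_fdr(
    cbind(got$psms, is_decoy = FALSE), 20, 0.01))
  expect_setequal(again$psms$peptide, got$psms$peptide)
})

test_that("threshold counts are nested in the threshold", {
  set.seed(73)
  psms <- simulate_psm_scores(500, 0.1)
  thrs <- sort(sample(psms$score, 20))
  above <- vapply(thrs, function(t) sum(psms$score >= t), integer(1))
  expect_true(all(diff(above) <= 0))
  ## and the highest threshold beyond the top score has estimate 0
  expect_equal(estimate_fdr_at_threshold(psms, max(psms$score) + 1), 0)
})

test_that("deduplication keeps the top-scoring PSM per peptide key", {
  psms <- data.frame(
    run_id = "r1", peptide = c("AAK", "AAK", "CCK"), charge = 2L,
    precursor_mz = peptide_mz(c("AAK", "AAK", "CCK"), 2),
    rt_sec = c(10, 11, 50), score = c(45, 30, 60),
    protein_acc = "P1", stringsAsFactors = FALSE)
  got <- deduplicate_psms(psms)
  expect_equal(nrow(got), 2)
  expect_equal(got$score[got$peptide == "AAK"], 45)
  ## identity on already-unique input
  expect_identical(deduplicate_psms(got), got)
})

test_that("deduplication matches group-by-argmax brute force with ties", {
  set.seed(74)
  base <- c("ACDEFK", "GHMNPK", "QRSTVK", "WYADEK")
  n <- 60
  psms <- data.frame(
    run_id = sample(c("r1", "r2"), n, TRUE),
    peptide = sample(base, n, TRUE),
    charge = sample(2:3, n, TRUE),
    rt_sec = runif(n, 0, 100),
    score = sample(seq(20, 40, by = 5), n, TRUE),  # many exact ties
    protein_acc = "P1", stringsAsFactors = FALSE)
  psms$precursor_mz <- peptide_mz(psms$peptide, psms$charge) +
    runif(n, -0.01, 0.01)
  got <- deduplicate_psms(psms)

  keys <- unique(psms[, c("run_id", "peptide", "charge")])
  expect_equal(nrow(got), nrow(keys))
  for (i in seq_len(nrow(keys))) {
    grp <- psms[psms$run_id == keys$run_id[i] &
                  psms$peptide == keys$peptide[i] &
                  psms$charge == keys$charge[i], ]
    best <- grp[grp$score == max(grp$score), ]
    err <- abs(best$precursor_mz - peptide_mz(best$peptide, best$charge))
    best <- best[order(err), ][1, ]
    sel <- got[got$run_id == keys$run_id[i] &
                 got$peptide == keys$peptide[i] &
                 got$charge == keys$charge[i], ]
    expect_equal(sel$score, best$score)
    expect_equal(sel$precursor_mz, best$precursor_mz)
  }
})

test_that("realized FDP tracks the decoy estimate on a known score set", {
  set.seed(75)
  psms <- simulate_psm_scores(5000, frac_false = 0.05)
  res <- filter_to_fdr(psms, score_floor = 20, fdr_target = 0.05)
  kept_false <- sum(!psms$is_correct[match(res$psms$peptide, psms$peptide)])
  fdp <- kept_false / nrow(res$psms)
  ## binomial slack around the 5% estimate at this retention count
  expect_lt(abs(fdp - 0.05), 0.03)
})
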