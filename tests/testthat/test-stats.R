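test_that("the pooled-variance t-test matches the closed form", {
  p_raw <- stat_params(log_transform = FALSE)
  ## identical groups
  same <- peptide_test(c(5, 6, 7), c(5, 6, 7), p_raw)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  ## textbook case: A = (1,2,3), B = (4,5,6)
  tt <- peptide_test(c(1, 2, 3), c(4, 5, 6), p_raw)
  expect_equal(abs(tt$statistic), 3 * sqrt(3) / sqrt(2), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-3 * sqrt(3) / sqrt(2), 4), tolerance = 1e-12)
  expect_equal(tt$p, 0.0213, tolerance = 1e-2)
  ## label swap negates the statistic, p unchanged
  rev <- peptide_test(c(4, 5, 6), c(1, 2, 3), p_raw)
  expect_equal(rev$statistic, -tt$statistic)
  expect_equal(rev$p, tt$p)
})

test_that("degenerate zero-variance groups are handled as specified", {
  p_raw <- stat_params(log_transform = FALSE)
  eq <- peptide_test(c(2, 2, 2), c(2, 2), p_raw)
  expect_equal(eq$p, 1)
  expect_false(eq$degenerate)
  ne <- peptide_test(c(2, 2, 2), c(5, 5), p_raw)
  expect_equal(ne$p, .Machine$double.xmin)
  expect_true(ne$degenerate)
  expect_error(peptide_test(c(-1, 2), c(3, 4), stat_params()), "positive")
})

test_that("q-values with pi0 = 1 equal Benjamini-Hochberg exactly", {
  set.seed(51)
  for (rep in 1:20) {
    m <- sample(c(5, 20, 200, 1000), 1)
    p <- runif(m)^sample(c(1, 2), 1)  # mix of uniform and enriched
    q <- qvalues(p, pi0 = 1)
    expect_equal(as.numeric(q), p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("q-values are monotone, bounded, and at least pi0 * p", {
  set.seed(52)
  p <- c(runif(400), runif(100, 0, 1e-3))
  q <- qvalues(p)
  pi0 <- attr(q, "pi0")
  expect_true(pi0 > 0 && pi0 <= 1)
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  expect_true(all(q <= 1))
  expect_true(all(q >= pi0 * p - 1e-12))
  expect_error(qvalues(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(qvalues(c(0.5, 1.2)), "\\(0, 1\\]")
  ## all p = 1 collapses to q = 1
  expect_equal(as.numeric(qvalues(rep(1, 20))), rep(1, 20))
})

test_that("pi0 is estimated near 1 on uniform p-values", {
  set.seed(53)
  hits <- vapply(1:10, function(i) {
    p <- runif(5000)
    pi0 <- attr(qvalues(p), "pi0")
    pi0 >= 0.9 && pi0 <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fold changes follow the treatment-over-baseline convention", {
  expect_equal(fold_change(c(1, 1), c(1, 1)),
               list(ratio = 1, log2fc = 0))
  fc <- fold_change(wt = c(90, 100, 110), kd = c(40, 50, 60))
  expect_equal(fc$ratio, 0.5)
  expect_equal(fc$log2fc, -1)
  expect_error(fold_change(c(0, 0), c(1, 1)), "positive")
})

test_that("protein roll-up sums peptides and matches brute force", {
  set.seed(54)
  m <- 30; n <- 6
  area <- matrix(exp(runif(m * n, log(1e3), log(1e6))), m, n,
                 dimnames = list(paste0("PEP", 1:m), paste0("r", 1:n)))
  prot <- sample(paste0("PR", 1:7), m, TRUE)
  qm <- structure(list(
    area = area, flags = matrix("detected", m, n, dimnames = dimnames(area)),
    floored = matrix(FALSE, m, n, dimnames = dimnames(area)),
    peptides = data.frame(peptide = rownames(area), charge = 2L,
                          mz = NA_real_, protein_acc = prot),
    run_ids = colnames(area), warps = NULL, normalization = NULL),
    class = "quant_matrix")
  qm$flags[2, 3] <- "inferred"
  qm$floored[5, 1] <- TRUE
  rolled <- protein_rollup(qm)
  ## brute force group-by-sum
  for (pr in unique(prot)) {
    members <- area[prot == pr, , drop = FALSE]
    expect_equal(rolled$area[pr, ], colSums(members))
  }
  ## conservation: totals per run preserved
  expect_equal(colSums(rolled$area), colSums(area))
  ## flags propagate to the containing protein
  expect_equal(unname(rolled$flags[prot[2], 3]), "inferred")
  expect_true(rolled$floored[prot[5], 1])
  ## single-peptide protein equals its peptide row
  solo <- names(which(table(prot) == 1))
  if (length(solo)) {
    expect_equal(rolled$area[solo[1], ],
                 area[which(prot == solo[1]), ])
  }
  ## unmapped peptides grouped with a warning
  qm$peptides$protein_acc[1] <- NA
  expect_warning(r2 <- protein_rollup(qm), "UNMAPPED")
  expect_true("UNMAPPED" %in% rownames(r2$area))
})

test_that("significance classification uses strict thresholds", {
  de <- data.frame(
    unit_id = paste0("u", 1:10), level = "peptide",
    mean_baseline = 1, mean_treatment = 1, ratio = 1,
    log2fc = c(-2, -1.5, 1.2, -1.0, 0.5, -0.2, 2.5, 0.9, -1.1, 0),
    p = 0.01,
    q = c(0.01, 0.02, 0.03, 0.01, 0.01, 0.5, 0.2, 0.01, 0.04, 0.9),
    stringsAsFactors = FALSE)
  params <- stat_params()
  de$significant <- abs(de$log2fc) > params$fc_threshold &
    de$q < params$q_threshold
  de$direction <- ifelse(de$log2fc < 0, "down", "up")
  s <- classify_and_summarize(de)
  ## u4: log2fc exactly -1 with q = 0.01 is NOT significant (strict >)
  expect_false(de$significant[4])
  ## 4 significant (u1, u2, u3, u9); u1, u2, u9 are down
  expect_equal(s$n_significant, 4)
  expect_equal(s$pct_down, 75)
  expect_equal(s$n_tested, 10)
})

test_that("a hand-built 10-unit set summarizes to (3 significant, 66.7% down)", {
  de <- data.frame(
    unit_id = paste0("u", 1:10), level = "peptide",
    mean_baseline = 1, mean_treatment = 1, ratio = 1,
    log2fc = c(-2, -1.5, 1.2, rep(0.1, 7)),
    p = 0.01, q = c(0.01, 0.02, 0.03, rep(0.8, 7)),
    stringsAsFactors = FALSE)
  de$significant <- abs(de$log2fc) > 1 & de$q < 0.05
  de$direction <- ifelse(de$log2fc < 0, "down", "up")
  s <- classify_and_summarize(de)
  expect_equal(s$n_significant, 3)
  expect_equal(round(s$pct_down, 1), 66.7)
})

test_that("the volcano table mirrors the classifier", {
  ex <- small_experiment()
  set.seed(55)
  m <- 50
  area <- matrix(exp(runif(m * 6, log(2e3), log(1e6))), m, 6,
                 dimnames = list(paste0("PEP", 1:m),
                                 c(paste0("WT_", 1:3), paste0("KD11_", 1:3))))
  groups <- setNames(rep(c("WT", "KD11"), each = 3), colnames(area))
  de <- diff_expression(area, groups, c("KD11", "WT"))
  v <- volcano_table(de)
  expect_equal(nrow(v), nrow(de))
  expect_equal(v$significant, de$significant)
  expect_equal(v$neg_log10_q, -log10(de$q))
  expect_equal(v$neg_log10_q[de$q == 1], rep(0, sum(de$q == 1)))
})

test_that("diff_expression agrees with by-hand means and ratios", {
  area <- matrix(c(100, 100, 100, 50, 50, 50,
                   200, 220, 180, 400, 410, 390), 2, 6, byrow = TRUE,
                 dimnames = list(c("a", "b"),
                                 c(paste0("WT_", 1:3), paste0("KD_", 1:3))))
  groups <- setNames(rep(c("WT", "KD"), each = 3), colnames(area))
  de <- diff_expression(area, groups, c("KD", "WT"),
                        stat_params(log_transform = FALSE))
  expect_equal(de$ratio[1], 0.5)
  expect_equal(de$log2fc[1], -1)
  expect_equal(de$mean_baseline[2], 200)
  expect_equal(de$mean_treatment[2], 400)
  expect_equal(de$direction, c("down", "up"))
})
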