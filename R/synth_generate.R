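#' Generate a ground-truthed synthetic label-free proteomics experiment
#'
#' Produces, deterministically for a given configuration (including its
#' `seed`), everything the quantitation pipeline consumes plus the ground
#' truth needed to score it:
#'
#' * one centroided MS1 run per (condition, replicate), with each peptide
#'   eluting as a Gaussian peak of configured width, lognormal multiplicative
#'   intensity noise, ppm-scale m/z jitter, an additive intensity baseline,
#'   background noise centroids, and a systematic per-run retention-time
#'   drift;
#' * one PSM table per run with configurable missing identifications,
#'   incorrect (false-target) matches, and decoy rows whose scores are
#'   stochastically dominated by correct-target scores;
#' * a term annotation set over the proteins (optionally with one term
#'   enriched for regulated proteins);
#' * the ground truth: per-peptide abundances and log2 fold changes per
#'   condition, per-run true apex retention times and realized areas, and
#'   per-PSM correctness flags.
#'
#' @param config a [synth_config()].
#' @return an object of class `lfq_experiment`: a list with elements `runs`
#'   (named list of `ms1_run`), `psms` (named list of PSM data frames),
#'   `annotation` (named list of character vectors of protein accessions,
#'   with a `descriptions` attribute), `ground_truth` (list of data frames
#'   `peptides`, `runs`, `peptide_runs`, `psm_flags`) and `config`.
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  validate_synth_config(config)
  with_seed(config$seed, {
    truth <- synth_ground_truth(config)
    runs <- vector("list", nrow(truth$runs))
    psms <- vector("list", nrow(truth$runs))
    names(runs) <- names(psms) <- truth$runs$run_id
    peptide_runs <- vector("list", nrow(truth$runs))
    psm_flags <- vector("list", nrow(truth$runs))
    for (r in seq_len(nrow(truth$runs))) {
      run_row <- truth$runs[r, ]
      pp <- peptide_params_for_run(truth$peptides, run_row, config)
      runs[[r]] <- simulate_run(pp, run_row$run_index, config,
                                run_id = run_row$run_id)
      peptide_runs[[r]] <- data.frame(
        run_id = run_row$run_id, peptide = pp$peptide,
        rt_true_s = pp$rt_s, area_true = pp$area_true,
        area_realized = pp$area_realized, stringsAsFactors = FALSE
      )
      ps <- synth_psm_table(pp, run_row, truth$peptides, config)
      psms[[r]] <- ps$table
      psm_flags[[r]] <- ps$flags
    }
    truth$peptide_runs <- do.call(rbind, peptide_runs)
    truth$psm_flags <- do.call(rbind, psm_flags)
    annotation <- synth_annotation(truth$peptides, config)
    structure(
      list(runs = runs, psms = psms, annotation = annotation,
           ground_truth = truth, config = config),
      class = "lfq_experiment"
    )
  })
}

## --- ground truth -----------------------------------------------------------

random_peptide_sequences <- function(n, len_range = c(8L, 16L)) {
  aa <- names(AA_MONO)[names(AA_MONO) != "I"]  # avoid I/L mass ambiguity
  seqs <- character(0)
  while (length(seqs) < n) {
    k <- n - length(seqs)
    lens <- sample(seq(len_range[1], len_range[2]), k, replace = TRUE)
    new <- vapply(lens, function(l) paste(sample(aa, l, replace = TRUE),
                                          collapse = ""), "")
    seqs <- unique(c(seqs, new))
  }
  seqs[seq_len(n)]
}

#' Theoretical precursor m/z of a peptide sequence
#'
#' Monoisotopic mass from residue masses plus water, protonated to the given
#' charge state. Residues outside the 20 standard amino acids are an error.
#'
#' @param sequence character vector of peptide sequences.
#' @param charge integer charge state(s).
#' @return numeric vector of m/z values (Th).
#' @export
peptide_mz <- function(sequence, charge = 2L) {
  vapply(seq_along(sequence), function(i) {
    res <- strsplit(sequence[i], "")[[1]]
    m <- AA_MONO[res]
    if (anyNA(m)) stop("unknown residue in sequence: ", sequence[i])
    z <- charge[min(i, length(charge))]
    (sum(m) + 18.010565 + z * PROTON_MASS) / z
  }, numeric(1))
}

## Draw n peptide sequences whose 2+ m/z values fall inside mz_range and are
## pairwise separated by >= min_gap_th, so SIC windows never overlap.
draw_separated_peptides <- function(n, mz_range, min_gap_th = 0.06,
                                    reserved_mz = STANDARD_MZ) {
  got_seq <- character(0)
  got_mz <- reserved_mz
  while (length(got_seq) < n) {
    cand <- random_peptide_sequences(2L * (n - length(got_seq)) + 10L)
    cand <- setdiff(cand, got_seq)
    mz <- peptide_mz(cand, 2L)
    ok <- mz >= mz_range[1] & mz <= mz_range[2]
    cand <- cand[ok]; mz <- mz[ok]
    for (i in seq_along(cand)) {
      if (length(got_seq) >= n) break
      if (all(abs(got_mz - mz[i]) >= min_gap_th)) {
        got_seq <- c(got_seq, cand[i])
        got_mz <- c(got_mz, mz[i])
      }
    }
  }
  data.frame(peptide = got_seq, mz = got_mz[-1][seq_len(n)],
             stringsAsFactors = FALSE)
}

synth_ground_truth <- function(cfg) {
  peps <- draw_separated_peptides(cfg$n_peptides, cfg$mz_range_th)
  prot <- sprintf("P%04d", rep_len(seq_len(cfg$n_proteins), cfg$n_peptides))
  n <- cfg$n_peptides

  ## regulation structure: shared per protein or independent per peptide
  if (cfg$shared_protein_regulation) {
    p_null <- runif(cfg$n_proteins) < cfg$frac_null
    p_sign <- ifelse(runif(cfg$n_proteins) < cfg$frac_down, -1, 1)
    p_mag <- exp(runif(cfg$n_proteins, log(cfg$log2fc_magnitude_range[1]),
                       log(cfg$log2fc_magnitude_range[2])))
    idx <- rep_len(seq_len(cfg$n_proteins), n)
    is_null <- p_null[idx]
    lfc <- ifelse(is_null, 0, p_sign[idx] * p_mag[idx])
  } else {
    is_null <- runif(n) < cfg$frac_null
    sgn <- ifelse(runif(n) < cfg$frac_down, -1, 1)
    mag <- exp(runif(n, log(cfg$log2fc_magnitude_range[1]),
                     log(cfg$log2fc_magnitude_range[2])))
    lfc <- ifelse(is_null, 0, sgn * mag)
  }

  ## place apexes so that even the most drifted run keeps peaks in-span
  n_runs <- length(cfg$conditions) * cfg$replicates_per_condition
  max_shift <- (n_runs - 1) * cfg$rt_shift_per_run_s
  max_scale <- max(1, 1 + (n_runs - 1) * cfg$rt_scale_per_run)
  margin <- max(0.1 * cfg$gradient_length_s, 0.75 * cfg$peak_width_range_s[2])
  rt_lo <- margin
  rt_hi <- (cfg$gradient_length_s - margin - max_shift) / max_scale
  if (rt_hi <= rt_lo) {
    stop_config("rt_shift_per_run_s",
                "cumulative drift leaves no usable elution window")
  }
  width <- runif(n, cfg$peak_width_range_s[1], cfg$peak_width_range_s[2])
  peptides <- data.frame(
    peptide = peps$peptide,
    protein_acc = prot,
    charge = 2L,
    mz = peps$mz,
    rt_ref_s = runif(n, rt_lo, rt_hi),
    width_s = width,
    sigma_s = width / 4,
    abundance_base = exp(runif(n, log(cfg$abundance_range[1]),
                               log(cfg$abundance_range[2]))),
    is_null = is_null,
    log2fc = lfc,
    is_standard = FALSE,
    stringsAsFactors = FALSE
  )
  ## spiked standard: fixed abundance, mid-gradient, null by construction
  std_width <- mean(cfg$peak_width_range_s)
  peptides <- rbind(peptides, data.frame(
    peptide = cfg$standard_peptide, protein_acc = "STANDARD", charge = 2L,
    mz = STANDARD_MZ, rt_ref_s = cfg$gradient_length_s / 2,
    width_s = std_width, sigma_s = std_width / 4,
    abundance_base = cfg$standard_abundance, is_null = TRUE, log2fc = 0,
    is_standard = TRUE, stringsAsFactors = FALSE
  ))

  ## per-condition true abundances (log2fc applied in regulated conditions)
  for (cond in cfg$conditions) {
    fc <- ifelse(rep(cond %in% cfg$regulated_conditions, nrow(peptides)),
                 peptides$log2fc, 0)
    fc[peptides$is_standard] <- 0
    peptides[[paste0("abund_", cond)]] <- peptides$abundance_base * 2^fc
    peptides[[paste0("log2fc_", cond)]] <- fc
  }

  runs <- expand.grid(replicate = seq_len(cfg$replicates_per_condition),
                      condition = cfg$conditions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  runs <- runs[, c("condition", "replicate")]
  runs$run_index <- seq_len(nrow(runs))
  runs$run_id <- sprintf("%s_%d", runs$condition, runs$replicate)
  runs$rt_shift_s <- (runs$run_index - 1) * cfg$rt_shift_per_run_s
  runs$rt_scale <- 1 + (runs$run_index - 1) * cfg$rt_scale_per_run

  list(peptides = peptides, runs = runs)
}

## Per-run realized peptide parameters: drifted RT and the lognormal
## amplitude factor that constitutes the replicate-level measurement noise.
peptide_params_for_run <- function(peptides, run_row, cfg) {
  area_true <- peptides[[paste0("abund_", run_row$condition)]]
  s <- sqrt(log(1 + cfg$intensity_cv^2))
  fac <- if (cfg$intensity_cv > 0) {
    rlnorm(nrow(peptides), meanlog = -s^2 / 2, sdlog = s)
  } else rep(1, nrow(peptides))
  fac[peptides$is_standard] <- 1  # the spike-in is constant by construction
  data.frame(
    peptide = peptides$peptide, mz = peptides$mz,
    sigma_s = peptides$sigma_s,
    rt_s = peptides$rt_ref_s * run_row$rt_scale + run_row$rt_shift_s,
    area_true = area_true,
    area_realized = area_true * fac,
    stringsAsFactors = FALSE
  )
}

## --- raw-run simulation -----------------------------------------------------

#' Simulate one centroided MS1 run
#'
#' Samples every peptide's Gaussian elution profile on a uniform scan grid,
#' applies per-centroid lognormal intensity jitter, uniform ppm m/z jitter and
#' an additive baseline, and adds background noise centroids. Draws from the
#' current RNG state; [generate_experiment()] seeds it for determinism.
#'
#' @param peptide_params data frame with columns `peptide`, `mz`, `sigma_s`,
#'   `rt_s` (already drift-shifted) and `area_realized` (the run's realized
#'   peak area).
#' @param run_index integer index of the run (bookkeeping only).
#' @param config a [synth_config()]; fields `gradient_length_s`,
#'   `scan_interval_s`, `mz_jitter_ppm`, `intensity_cv`,
#'   `baseline_level_int`, `noise_peaks_per_scan` are used.
#' @param run_id label for the run.
#' @return an `ms1_run`: list with `run_id`, `rt` (scan retention times,
#'   seconds), `peaks` (data.table of `scan`, `mz`, `intensity`), `n_scans`.
#' @export
simulate_run <- function(peptide_params, run_index, config,
                         run_id = paste0("run_", run_index)) {
  rt_grid <- seq(0, config$gradient_length_s, by = config$scan_interval_s)
  n_scans <- length(rt_grid)
  s <- sqrt(log(1 + config$intensity_cv^2))
  base <- config$baseline_level_int

  contrib <- vector("list", nrow(peptide_params) + 1L)
  for (i in seq_len(nrow(peptide_params))) {
    p <- peptide_params[i, ]
    lo <- p$rt_s - 4 * p$sigma_s
    hi <- p$rt_s + 4 * p$sigma_s
    if (p$rt_s - 3 * p$sigma_s < rt_grid[1] ||
        p$rt_s + 3 * p$sigma_s > rt_grid[n_scans]) {
      warning(sprintf("peptide %s elutes at the edge of run %s; peak truncated",
                      p$peptide, run_id), call. = FALSE)
    }
    idx <- which(rt_grid >= lo & rt_grid <= hi)
    if (!length(idx)) next
    amp <- p$area_realized / (p$sigma_s * sqrt(2 * pi))
    ints <- amp * exp(-(rt_grid[idx] - p$rt_s)^2 / (2 * p$sigma_s^2))
    if (config$intensity_cv > 0) {
      ints <- ints * rlnorm(length(idx), meanlog = -s^2 / 2, sdlog = s)
    }
    if (base > 0) ints <- ints + runif(length(idx), 0, 2 * base)
    mzs <- p$mz * (1 + runif(length(idx), -config$mz_jitter_ppm,
                             config$mz_jitter_ppm) * 1e-6)
    contrib[[i]] <- data.table::data.table(scan = idx, mz = mzs,
                                           intensity = ints)
  }
  ## sparse background noise centroids
  if (base > 0 && config$noise_peaks_per_scan > 0) {
    counts <- rpois(n_scans, config$noise_peaks_per_scan)
    tot <- sum(counts)
    if (tot > 0) {
      contrib[[length(contrib)]] <- data.table::data.table(
        scan = rep(seq_len(n_scans), counts),
        mz = runif(tot, config$mz_range_th[1], config$mz_range_th[2]),
        intensity = rexp(tot, rate = 1 / base)
      )
    }
  }
  peaks <- data.table::rbindlist(contrib)
  if (nrow(peaks)) {
    data.table::setorder(peaks, scan, mz)
  } else {
    peaks <- data.table::data.table(scan = integer(0), mz = numeric(0),
                                    intensity = numeric(0))
  }
  structure(list(run_id = run_id, rt = rt_grid, peaks = peaks,
                 n_scans = n_scans), class = "ms1_run")
}

#' @export
print.ms1_run <- function(x, ...) {
  cat(sprintf("<ms1_run %s: %d MS1 scans, %.1f-%.1f s, %d centroids>\n",
              x$run_id, x$n_scans, min(x$rt), max(x$rt), nrow(x$peaks)))
  invisible(x)
}

## --- PSM tables -------------------------------------------------------------

synth_psm_table <- function(pp, run_row, peptides, cfg) {
  n <- nrow(pp)
  is_std <- peptides$is_standard
  keep <- runif(n) >= cfg$frac_missing_msms
  keep[is_std] <- TRUE
  idx <- which(keep)

  target <- data.frame(
    run_id = run_row$run_id,
    peptide = pp$peptide[idx],
    charge = 2L,
    precursor_mz = pp$mz[idx],
    rt_sec = pp$rt_s[idx] + rnorm(length(idx), 0, cfg$scan_interval_s),
    score = rnorm(length(idx), cfg$target_score_mean, cfg$score_sd),
    is_decoy = FALSE,
    protein_acc = peptides$protein_acc[idx],
    stringsAsFactors = FALSE
  )
  is_false <- runif(nrow(target)) < cfg$frac_false_psms
  is_false[peptides$is_standard[idx]] <- FALSE
  if (any(is_false)) {
    k <- sum(is_false)
    fseq <- random_peptide_sequences(k)
    target$peptide[is_false] <- fseq
    target$precursor_mz[is_false] <- peptide_mz(fseq, 2L)
    target$rt_sec[is_false] <- runif(k, 0, cfg$gradient_length_s)
    target$score[is_false] <- rnorm(k, cfg$target_score_mean -
                                      cfg$decoy_score_offset, cfg$score_sd)
    target$protein_acc[is_false] <- sprintf("PFALSE%03d", sample.int(999, k,
                                                                     replace = TRUE))
  }

  n_decoy <- round(cfg$decoy_fraction * nrow(target))
  decoy <- NULL
  if (n_decoy > 0) {
    dseq <- random_peptide_sequences(n_decoy)
    decoy <- data.frame(
      run_id = run_row$run_id, peptide = dseq, charge = 2L,
      precursor_mz = peptide_mz(dseq, 2L),
      rt_sec = runif(n_decoy, 0, cfg$gradient_length_s),
      score = rnorm(n_decoy, cfg$target_score_mean - cfg$decoy_score_offset,
                    cfg$score_sd),
      is_decoy = TRUE,
      protein_acc = sprintf("DECOY_P%03d", seq_len(n_decoy)),
      stringsAsFactors = FALSE
    )
  }
  tab <- rbind(target, decoy)
  tab$psm_id <- sprintf("%s_psm%05d", run_row$run_id, seq_len(nrow(tab)))
  flags <- data.frame(
    run_id = run_row$run_id, psm_id = tab$psm_id,
    is_correct = c(!is_false, rep(FALSE, n_decoy)),
    stringsAsFactors = FALSE
  )
  list(table = tab, flags = flags)
}

#' Simulate a bare target/decoy PSM score set with known correctness
#'
#' A focused generator for studying false-discovery-rate control in score
#' thresholding, without raw data: `n_targets` target PSMs of which a
#' fraction are incorrect matches, plus decoy PSMs drawn from the same
#' shifted score distribution as the incorrect targets (one decoy per
#' incorrect target in expectation, the working assumption of concatenated
#' target-decoy estimation).
#'
#' @param n_targets number of target PSM rows.
#' @param frac_false fraction of target rows that are incorrect matches.
#' @param n_decoys number of decoy rows; default `round(frac_false * n_targets)`.
#' @param target_score_mean,score_sd,decoy_score_offset score model as in
#'   [synth_config()].
#' @return data frame with columns `peptide`, `run_id`, `charge`,
#'   `precursor_mz`, `rt_sec`, `score`, `is_decoy`, `protein_acc`,
#'   `is_correct` (`NA` for decoys).
#' @export
simulate_psm_scores <- function(n_targets, frac_false = 0.05,
                                n_decoys = round(frac_false * n_targets),
                                target_score_mean = 45, score_sd = 12,
                                decoy_score_offset = 28) {
  n_false <- rbinom(1, n_targets, frac_false)
  n_true <- n_targets - n_false
  score <- c(rnorm(n_true, target_score_mean, score_sd),
             rnorm(n_false + n_decoys, target_score_mean - decoy_score_offset,
                   score_sd))
  n <- n_targets + n_decoys
  data.frame(
    peptide = sprintf("PEP%06d", seq_len(n)),
    run_id = "scoreset", charge = 2L, precursor_mz = 500, rt_sec = 0,
    score = score,
    is_decoy = rep(c(FALSE, FALSE, TRUE), c(n_true, n_false, n_decoys)),
    protein_acc = "P0000",
    is_correct = c(rep(TRUE, n_true), rep(FALSE, n_false),
                   rep(NA, n_decoys)),
    stringsAsFactors = FALSE
  )
}

## --- annotation -------------------------------------------------------------

synth_annotation <- function(peptides, cfg) {
  analyte <- peptides[!peptides$is_standard, ]
  prots <- unique(analyte$protein_acc)
  reg <- unique(analyte$protein_acc[!analyte$is_null])
  terms <- vector("list", cfg$n_terms)
  names(terms) <- sprintf("TERM_%03d", seq_len(cfg$n_terms))
  for (t in seq_len(cfg$n_terms)) {
    size <- min(length(prots),
                sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]), 1))
    w <- rep(1, length(prots))
    if (t == 1L && !is.null(cfg$planted_term_odds)) {
      w[prots %in% reg] <- cfg$planted_term_odds
    }
    terms[[t]] <- sort(sample(prots, size, prob = w))
  }
  planted <- seq_len(cfg$n_terms) == 1L & !is.null(cfg$planted_term_odds)
  attr(terms, "descriptions") <- setNames(
    sprintf("synthetic term %03d%s", seq_len(cfg$n_terms),
            ifelse(planted, " (planted)", "")),
    names(terms))
  terms
}
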