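#' Configuration for a synthetic label-free proteomics experiment
#'
#' Builds a validated configuration describing a ground-truthed synthetic
#' experiment: a set of tryptic-like peptides assigned to proteins, eluting as
#' Gaussian chromatographic peaks on a uniform MS1 scan grid, acquired in
#' several conditions with replicate runs, with peptide-spectrum-match (PSM)
#' tables and a term annotation set generated alongside the raw data.
#'
#' The defaults emulate the study design the pipeline targets: three
#' conditions (`WT`, `PlasmidC`, `KD11`) with three replicates each, a
#' constant spiked standard peptide `DRVYHPF` in every run, 95% null
#' peptides, and 93.5% of the regulated peptides down-regulated in the
#' knockdown condition.
#'
#' @param n_peptides number of analyte peptides (excluding the spiked
#'   standard).
#' @param n_proteins number of proteins; peptides are assigned round-robin.
#' @param conditions character vector of condition labels. The first is the
#'   baseline; fold changes are applied in `regulated_conditions`.
#' @param replicates_per_condition replicates per condition (>= 2).
#' @param regulated_conditions conditions in which non-null peptides carry
#'   their fold change (default `"KD11"`; all other conditions stay at
#'   baseline abundance).
#' @param frac_null fraction of peptides with zero log2 fold change in every
#'   condition.
#' @param log2fc_magnitude_range interval of |log2 fold change| for non-null
#'   peptides; magnitudes are drawn log-uniformly in this interval.
#' @param frac_down fraction of non-null peptides whose fold change is
#'   negative (down in the regulated condition).
#' @param shared_protein_regulation if `TRUE` (default) all peptides of a
#'   protein share the protein's null status and log2 fold change; if `FALSE`
#'   each peptide draws independently.
#' @param gradient_length_s length of each run's retention-time span in
#'   seconds. Peptide apexes are placed uniformly in the central 80%.
#' @param scan_interval_s MS1 scan cadence in seconds.
#' @param peak_width_range_s range of chromatographic peak widths in seconds
#'   (full width, approximately 4 Gaussian sigma); must lie within [2, 80].
#' @param mz_range_th precursor m/z range (Thomson).
#' @param mz_jitter_ppm half-width of the uniform per-centroid m/z jitter in
#'   parts per million.
#' @param intensity_cv coefficient of variation of the lognormal
#'   multiplicative intensity noise (applied per peptide-run amplitude and,
#'   at the same CV, per sampled centroid).
#' @param baseline_level_int mean of the additive intensity baseline; also the
#'   mean intensity of background noise centroids. 0 disables all additive
#'   noise.
#' @param noise_peaks_per_scan expected number of background noise centroids
#'   per MS1 scan (Poisson), with m/z uniform over `mz_range_th` and
#'   exponential intensities of mean `baseline_level_int`.
#' @param abundance_range true peak-area range (intensity * seconds) from
#'   which peptide baseline abundances are drawn log-uniformly.
#' @param frac_missing_msms fraction of (peptide, run) pairs lacking a PSM
#'   (each peptide is still guaranteed one PSM in at least one run).
#' @param rt_shift_per_run_s systematic retention-time shift added per run
#'   index (run r is shifted by `(r - 1) * rt_shift_per_run_s` seconds).
#' @param rt_scale_per_run multiplicative retention-time drift per run index
#'   (run r maps rt to `rt * (1 + (r - 1) * rt_scale_per_run)`), exercising
#'   nonlinear-in-run alignment.
#' @param frac_false_psms fraction of target PSM rows that are incorrect
#'   matches (random sequence, decoy-like score); recorded in the ground
#'   truth so realized false-discovery proportions can be measured.
#' @param decoy_fraction number of decoy PSM rows per run, as a fraction of
#'   that run's target PSM rows.
#' @param target_score_mean,score_sd mean and sd of the (normal) search-engine
#'   score for correct target PSMs.
#' @param decoy_score_offset decoy and false-target scores are drawn from the
#'   target distribution shifted down by this amount, making them
#'   stochastically dominated by correct-target scores.
#' @param standard_peptide sequence of the spiked standard (default
#'   `"DRVYHPF"`, angiotensin fragment), present in every run at
#'   `standard_abundance`.
#' @param standard_abundance true peak area of the standard in every run.
#' @param n_terms,term_size_range annotation set: number of terms and range
#'   of proteins per term (sampled uniformly with replacement across terms).
#' @param planted_term_odds if not `NULL`, the first term's members are
#'   sampled with this odds ratio in favour of regulated proteins, planting
#'   an enrichment signal with known truth.
#' @param seed integer seed; all generated output is deterministic given the
#'   configuration including this seed.
#'
#' @return an object of class `synth_config` (a validated named list).
#' @export
synth_config <- function(n_peptides = 300,
                         n_proteins = 60,
                         conditions = c("WT", "PlasmidC", "KD11"),
                         replicates_per_condition = 3,
                         regulated_conditions = "KD11",
                         frac_null = 0.95,
                         log2fc_magnitude_range = c(1, 3),
                         frac_down = 0.935,
                         shared_protein_regulation = TRUE,
                         gradient_length_s = 600,
                         scan_interval_s = 1,
                         peak_width_range_s = c(6, 20),
                         mz_range_th = c(400, 1800),
                         mz_jitter_ppm = 2,
                         intensity_cv = 0.1,
                         baseline_level_int = 25,
                         noise_peaks_per_scan = 20,
                         abundance_range = c(5e3, 5e6),
                         frac_missing_msms = 0.1,
                         rt_shift_per_run_s = 4,
                         rt_scale_per_run = 0,
                         frac_false_psms = 0.05,
                         decoy_fraction = 0.05,
                         target_score_mean = 45,
                         score_sd = 12,
                         decoy_score_offset = 28,
                         standard_peptide = "DRVYHPF",
                         standard_abundance = 5e5,
                         n_terms = 25,
                         term_size_range = c(10, 30),
                         planted_term_odds = NULL,
                         seed = 1L) {
  cfg <- list(
    n_peptides = n_peptides, n_proteins = n_proteins,
    conditions = conditions,
    replicates_per_condition = replicates_per_condition,
    regulated_conditions = regulated_conditions,
    frac_null = frac_null,
    log2fc_magnitude_range = log2fc_magnitude_range,
    frac_down = frac_down,
    shared_protein_regulation = isTRUE(shared_protein_regulation),
    gradient_length_s = gradient_length_s,
    scan_interval_s = scan_interval_s,
    peak_width_range_s = peak_width_range_s,
    mz_range_th = mz_range_th,
    mz_jitter_ppm = mz_jitter_ppm,
    intensity_cv = intensity_cv,
    baseline_level_int = baseline_level_int,
    noise_peaks_per_scan = noise_peaks_per_scan,
    abundance_range = abundance_range,
    frac_missing_msms = frac_missing_msms,
    rt_shift_per_run_s = rt_shift_per_run_s,
    rt_scale_per_run = rt_scale_per_run,
    frac_false_psms = frac_false_psms,
    decoy_fraction = decoy_fraction,
    target_score_mean = target_score_mean,
    score_sd = score_sd,
    decoy_score_offset = decoy_score_offset,
    standard_peptide = standard_peptide,
    standard_abundance = standard_abundance,
    n_terms = n_terms,
    term_size_range = term_size_range,
    planted_term_odds = planted_term_odds,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  if (!is_count(cfg$n_peptides)) stop_config("n_peptides", "must be a positive integer")
  if (!is_count(cfg$n_proteins)) stop_config("n_proteins", "must be a positive integer")
  if (length(cfg$conditions) < 2 || anyDuplicated(cfg$conditions))
    stop_config("conditions", "need >= 2 distinct condition labels")
  if (!is_count(cfg$replicates_per_condition) || cfg$replicates_per_condition < 2)
    stop_config("replicates_per_condition", "must be an integer >= 2")
  if (!all(cfg$regulated_conditions %in% cfg$conditions))
    stop_config("regulated_conditions", "must be a subset of conditions")
  if (cfg$conditions[1] %in% cfg$regulated_conditions)
    stop_config("regulated_conditions", "the first (baseline) condition cannot be regulated")
  for (f in c("frac_null", "frac_down", "frac_missing_msms", "frac_false_psms",
              "intensity_cv")) {
    if (!is_fraction(cfg[[f]])) stop_config(f, "must be a fraction in [0, 1]")
  }
  if (!is.numeric(cfg$decoy_fraction) || cfg$decoy_fraction < 0)
    stop_config("decoy_fraction", "must be >= 0")
  r <- cfg$log2fc_magnitude_range
  if (length(r) != 2 || r[1] <= 0 || diff(r) < 0)
    stop_config("log2fc_magnitude_range", "must be an increasing positive interval")
  w <- cfg$peak_width_range_s
  if (length(w) != 2 || w[1] < 2 || w[2] > 80 || diff(w) < 0)
    stop_config("peak_width_range_s", "must lie within [2, 80] seconds")
  if (!is.numeric(cfg$scan_interval_s) || cfg$scan_interval_s <= 0)
    stop_config("scan_interval_s", "must be > 0")
  if (!is.numeric(cfg$gradient_length_s) || cfg$gradient_length_s <= 10 * cfg$scan_interval_s)
    stop_config("gradient_length_s", "must span many scan intervals")
  if (length(cfg$mz_range_th) != 2 || cfg$mz_range_th[1] <= 0 || diff(cfg$mz_range_th) <= 0)
    stop_config("mz_range_th", "must be an increasing positive interval")
  if (length(cfg$abundance_range) != 2 || cfg$abundance_range[1] <= 0 ||
      diff(cfg$abundance_range) < 0)
    stop_config("abundance_range", "must be an increasing positive interval")
  if (cfg$standard_abundance <= 0)
    stop_config("standard_abundance", "must be > 0")
  if (!is_count(cfg$n_terms)) stop_config("n_terms", "must be a positive integer")
  invisible(cfg)
}

## Monoisotopic [M+2H]2+ of DRVYHPF; the spiked standard elutes mid-gradient.
STANDARD_MZ <- 467.2325
PROTON_MASS <- 1.007276

## Monoisotopic residue masses for synthetic peptide m/z assignment.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
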