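#' Read a centroided MS1 run from mzML
#'
#' Reads MS1 spectra only (interleaved MS2 scans are skipped and counted),
#' with retention times in seconds and centroid arrays sorted by m/z,
#' spectra ordered by retention time.
#'
#' @param path path to an mzML file.
#' @param run_id run label; defaults to the file stem.
#' @return an `ms1_run`.
#' @export
read_ms1_mzml <- function(path, run_id = sub("\\.mzML$", "", basename(path),
                                             ignore.case = TRUE)) {
  if (!file.exists(path)) stop("no such mzML file: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  is_ms1 <- hd$msLevel == 1L
  n_skipped <- sum(!is_ms1)
  if (n_skipped) message(n_skipped, " non-MS1 spectra skipped in ", path)
  idx <- which(is_ms1)
  idx <- idx[order(hd$retentionTime[idx])]
  rt <- hd$retentionTime[idx]
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  contrib <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    sp <- pk[[idx[k]]]
    if (!is.null(sp) && nrow(sp)) {
      o <- order(sp[, 1])
      contrib[[k]] <- data.table::data.table(scan = k, mz = sp[o, 1],
                                             intensity = sp[o, 2])
    }
  }
  peaks <- data.table::rbindlist(contrib)
  if (!nrow(peaks)) peaks <- data.table::data.table(scan = integer(0),
                                                    mz = numeric(0),
                                                    intensity = numeric(0))
  structure(list(run_id = run_id, rt = rt, peaks = peaks,
                 n_scans = length(idx)),
            class = "ms1_run")
}

#' Write an `ms1_run` to mzML (centroided MS1)
#'
#' @param run an `ms1_run`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ms1_mzml <- function(run, path) {
  stopifnot(inherits(run, "ms1_run"))
  n <- run$n_scans
  spectra <- split(run$peaks, factor(run$peaks$scan, levels = seq_len(n)))
  spectra <- lapply(spectra, function(d)
    cbind(mz = d$mz, intensity = d$intensity))
  counts <- vapply(spectra, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(spectra, function(s) sum(s[, 2]), numeric(1)),
    retentionTime = run$rt,
    basePeakMZ = vapply(spectra, function(s)
      if (nrow(s)) s[which.max(s[, 2]), 1] else 0, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s)
      if (nrow(s)) max(s[, 2]) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) if (nrow(s)) min(s[, 1]) else 0,
                   numeric(1)),
    highMZ = vapply(spectra, function(s) if (nrow(s)) max(s[, 1]) else 0,
                    numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(spectra, file = path, header = hdr, outformat = "mzml",
                   rtime_seconds = TRUE)
  invisible(path)
}

#' Write a synthetic experiment to disk as a fixture bundle
#'
#' Emits one mzML per run, one PSM TSV per run, the annotation GMT, ground
#' truth TSVs and a JSON manifest (files, seed, counts). Everything is
#' re-readable by the package's own readers.
#'
#' @param experiment an `lfq_experiment` from [generate_experiment()].
#' @param directory output directory (created if missing).
#' @return the manifest, invisibly as a list (also written as
#'   `manifest.json`).
#' @export
write_fixture_bundle <- function(experiment, directory) {
  stopifnot(inherits(experiment, "lfq_experiment"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE)
  if (!ok || file.access(directory, 2) != 0) {
    stop("cannot write to directory: ", directory)
  }
  files <- list(mzml = character(0), psm = character(0))
  for (rid in names(experiment$runs)) {
    f <- file.path(directory, paste0(rid, ".mzML"))
    write_ms1_mzml(experiment$runs[[rid]], f)
    files$mzml <- c(files$mzml, basename(f))
    g <- file.path(directory, paste0(rid, "_psms.tsv"))
    write_psm_table(experiment$psms[[rid]], g)
    files$psm <- c(files$psm, basename(g))
  }
  write_gmt(experiment$annotation, file.path(directory, "annotation.gmt"))
  gt <- experiment$ground_truth
  write.table(gt$peptides, file.path(directory, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gt$peptide_runs, file.path(directory, "ground_truth_runs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gt$psm_flags, file.path(directory, "ground_truth_psms.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = experiment$config$seed,
    n_runs = length(experiment$runs),
    n_peptides = experiment$config$n_peptides,
    n_terms = length(experiment$annotation),
    files = c(files,
              list(annotation = "annotation.gmt",
                   ground_truth = c("ground_truth.tsv",
                                    "ground_truth_runs.tsv",
                                    "ground_truth_psms.tsv")))
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Pipeline configuration
#'
#' Collects every stage's parameters plus input/output paths into one
#' validated object; [run_pipeline()] consumes it. Paths may be omitted when
#' the pipeline is run on an in-memory experiment. Serializable to/from YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param run_paths named character vector of mzML paths (names = run ids).
#' @param psm_paths character vector of PSM TSV paths.
#' @param annotation_path GMT path.
#' @param out_dir output directory (`NULL`: nothing written).
#' @param groups named character vector mapping run ids to conditions;
#'   `NULL` derives conditions by stripping a trailing `_<replicate>` from
#'   run ids.
#' @param contrasts list of `c(treatment, baseline)` pairs.
#' @param score_floor,fdr_target PSM filtering (Mowse-like floor, decoy FDR).
#' @param ppm_window SIC mass window, ppm.
#' @param detect_params a [peak_detect_params()].
#' @param stats a [stat_params()].
#' @param floor minimum reported area.
#' @param standard_peptide spike-in normalization standard sequence.
#' @param seed integer, recorded in provenance.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(run_paths = NULL, psm_paths = NULL,
                            annotation_path = NULL, out_dir = NULL,
                            groups = NULL,
                            contrasts = list(c("KD11", "WT"),
                                             c("PlasmidC", "WT")),
                            score_floor = 20, fdr_target = 0.01,
                            ppm_window = 10,
                            detect_params = peak_detect_params(),
                            stats = stat_params(),
                            floor = 1000,
                            standard_peptide = "DRVYHPF",
                            seed = 1L) {
  for (p in c(run_paths, psm_paths, annotation_path)) {
    if (!is.null(p) && !file.exists(p)) stop_config("paths", paste("missing file:", p))
  }
  structure(list(run_paths = run_paths, psm_paths = psm_paths,
                 annotation_path = annotation_path, out_dir = out_dir,
                 groups = groups, contrasts = contrasts,
                 score_floor = score_floor, fdr_target = fdr_target,
                 ppm_window = ppm_window, detect_params = detect_params,
                 stats = stats, floor = floor,
                 standard_peptide = standard_peptide,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(rapply(config, unclass, how = "replace"))
  if (!is.null(x$groups)) x$groups <- as.list(x$groups)  # keep names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  dp <- do.call(peak_detect_params, y$detect_params %||% list())
  sp <- do.call(stat_params, y$stats %||% list())
  y$detect_params <- NULL; y$stats <- NULL
  y$groups <- unlist(y$groups)
  do.call(pipeline_config, c(y, list(detect_params = dp, stats = sp)))
}

#' Run the full label-free quantitation pipeline
#'
#' Executes, in order: PSM FDR filtering and deduplication; SIC extraction
#' and multi-pass CWT peak detection; retention-time alignment and
#' missing-identification fill-in; spike-in normalization and the reported
#' floor; per-contrast peptide t-tests, Storey q-values and classification;
#' protein roll-up with re-testing at protein level; PCA and hierarchical
#' clustering; and term enrichment of differential proteins against the
#' unchanged-protein background. Deterministic given its inputs.
#'
#' @param config a [pipeline_config()].
#' @param experiment optional in-memory `lfq_experiment`; when `NULL`, runs
#'   and PSMs are read from the paths in `config`.
#' @return a list bundle: `quant` (floored, normalized `quant_matrix`),
#'   `filter_report`, `de` (per contrast: `peptide`, `protein`, `summary`,
#'   `volcano`), `pca`, `heatmap`, `enrichment` (`NULL` without annotation),
#'   and `provenance`.
#' @export
run_pipeline <- function(config, experiment = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(experiment)) {
    runs <- experiment$runs
    psms_raw <- do.call(rbind, experiment$psms)
    annotation <- experiment$annotation
  } else {
    runs <- stage("read_runs", {
      rl <- lapply(seq_along(config$run_paths), function(i)
        read_ms1_mzml(config$run_paths[i],
                      run_id = names(config$run_paths)[i] %||%
                        sub("\\.mzML$", "", basename(config$run_paths[i]))))
      names(rl) <- vapply(rl, function(r) r$run_id, "")
      rl
    })
    psms_raw <- stage("read_psms",
                      do.call(rbind, lapply(config$psm_paths, read_psm_table)))
    annotation <- if (!is.null(config$annotation_path)) {
      stage("read_annotation", read_gmt(config$annotation_path))
    } else NULL
  }
  groups <- config$groups %||%
    setNames(sub("_[0-9]+$", "", names(runs)), names(runs))

  filt <- stage("filter_psms",
                filter_to_fdr(psms_raw, config$score_floor, config$fdr_target))
  psms <- stage("deduplicate", deduplicate_psms(filt$psms))
  if (!nrow(psms)) stop("pipeline stage 'filter_psms' retained no PSMs")

  qm <- stage("quantify",
              quantify_runs(runs, psms, ppm_window = config$ppm_window,
                            detect_params = config$detect_params))
  qm <- stage("normalize", normalize_to_standard(qm, config$standard_peptide))
  qm <- stage("floor", apply_floor(qm, config$floor))
  ## the spiked standard is bookkeeping, not an analyte
  analyte <- qm$peptides$peptide != config$standard_peptide
  qa <- qm
  qa$area <- qa$area[analyte, , drop = FALSE]
  qa$flags <- qa$flags[analyte, , drop = FALSE]
  qa$floored <- qa$floored[analyte, , drop = FALSE]
  qa$peptides <- qa$peptides[analyte, , drop = FALSE]

  prot <- stage("rollup", protein_rollup(qa))
  de <- list()
  for (ct in config$contrasts) {
    key <- paste(ct, collapse = "_vs_")
    de_pep <- stage(paste0("diffexp_", key),
                    diff_expression(qa, groups, ct, config$stats, "peptide"))
    de_pro <- stage(paste0("diffexp_protein_", key),
                    diff_expression(prot, groups, ct, config$stats, "protein"))
    de[[key]] <- list(peptide = de_pep, protein = de_pro,
                      summary = classify_and_summarize(de_pep, de_pro),
                      volcano = volcano_table(de_pep))
  }

  pca <- stage("pca", pca_scores(qa))
  primary <- de[[1]]
  sig_pep <- primary$peptide$unit_id[primary$peptide$significant]
  heat <- if (length(sig_pep) >= 2) {
    stage("heatmap", hierarchical_heatmap(
      qa$area[rownames(qa$area) %in% sig_pep, , drop = FALSE]))
  } else NULL

  enrichment <- NULL
  if (!is.null(annotation)) {
    de_prot <- primary$protein$unit_id[primary$protein$significant]
    bg_prot <- setdiff(primary$protein$unit_id, de_prot)
    if (length(de_prot)) {
      enrichment <- stage("enrich",
                          enrich_terms(de_prot, bg_prot, annotation))
    }
  }

  provenance <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("lfqpipe")),
    thresholds = list(score_floor = config$score_floor,
                      fdr_target = config$fdr_target,
                      fc_threshold = config$stats$fc_threshold,
                      q_threshold = config$stats$q_threshold,
                      floor = config$floor,
                      ppm_window = config$ppm_window),
    counts = list(
      psms_in = nrow(psms_raw),
      psms_filtered = nrow(filt$psms),
      psms_unique = nrow(psms),
      peptides_quantified = nrow(qa$area),
      proteins_quantified = nrow(prot$area),
      runs = length(runs)
    ),
    psm_score_threshold = filt$threshold
  )
  bundle <- list(quant = qm, filter_report = filt[c("threshold", "fdr",
                                                    "n_discarded_floor")],
                 de = de, pca = pca, heatmap = heat,
                 enrichment = enrichment, provenance = provenance,
                 groups = groups)
  if (!is.null(config$out_dir)) write_pipeline_outputs(bundle, config)
  bundle
}

write_pipeline_outputs <- function(bundle, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$out_dir
  write_quant_matrix(bundle$quant, file.path(od, "quant"))
  for (key in names(bundle$de)) {
    d <- bundle$de[[key]]
    write.table(rbind(d$peptide, d$protein),
                file.path(od, paste0("de_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(d$summary, file.path(od, paste0("summary_", key,
                                                         ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  scores <- data.frame(run_id = rownames(bundle$pca$scores),
                       bundle$pca$scores, check.names = FALSE)
  write.table(scores, file.path(od, "pca_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$enrichment)) {
    write.table(bundle$enrichment, file.path(od, "enrichment.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(bundle$provenance, file.path(od, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}
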