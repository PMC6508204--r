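#' Build a peptides-by-runs quantitation matrix from MS1 runs and PSMs
#'
#' The quantitation core: for every unique identified peptide, extract its
#' SIC in every run, detect peaks by multi-pass CWT, and fill each cell of
#' the peptides x runs matrix:
#'
#' * runs where the peptide has a PSM take the detected peak whose apex lies
#'   nearest the PSM retention time (within `match_halfwindow`); if detection
#'   found nothing there, a fixed window around the PSM time is integrated
#'   (flag `"window"`);
#' * runs lacking a PSM are filled in through retention-time alignment: the
#'   peptide's reference-frame apex (averaged over runs where it was
#'   detected) is mapped into the run's frame and [infer_missing_peak()] is
#'   applied (flag `"inferred"`).
#'
#' The returned matrix is raw (un-normalized, un-floored); follow with
#' [normalize_to_standard()] and [apply_floor()].
#'
#' @param runs named list of `ms1_run` (names are run ids).
#' @param psms data frame of filtered, deduplicated target PSMs.
#' @param ppm_window SIC mass window in ppm (default 10).
#' @param detect_params a [peak_detect_params()].
#' @param match_halfwindow PSM-to-peak apex match half-window, seconds.
#' @param fallback_window blind integration window width, seconds.
#' @param align logical: perform RT alignment (required for fill-in when any
#'   cell lacks a PSM).
#' @return a `quant_matrix`: list with `area` (numeric matrix), `flags`
#'   (character matrix: `"detected"`, `"window"`, `"inferred"`), `floored`
#'   (logical matrix), `peptides` (data frame: `peptide`, `charge`, `mz`,
#'   `protein_acc`), `run_ids`, `warps` (the `warp_set` or `NULL`) and
#'   `normalization` (`NULL` until normalized).
#' @export
quantify_runs <- function(runs, psms,
                          ppm_window = 10,
                          detect_params = peak_detect_params(),
                          match_halfwindow = 30,
                          fallback_window = 20,
                          align = TRUE) {
  stopifnot(length(runs) >= 1, nrow(psms) >= 1)
  run_ids <- names(runs)
  if (is.null(run_ids)) {
    run_ids <- vapply(runs, function(r) r$run_id, "")
    names(runs) <- run_ids
  }

  ## unique peptide roster from the identifications
  pk <- paste(psms$peptide, psms$charge, sep = "/")
  roster <- data.frame(
    peptide = psms$peptide[!duplicated(pk)],
    charge = psms$charge[!duplicated(pk)],
    stringsAsFactors = FALSE
  )
  roster$mz <- vapply(seq_len(nrow(roster)), function(i) {
    sel <- psms$peptide == roster$peptide[i] & psms$charge == roster$charge[i]
    median(psms$precursor_mz[sel])
  }, numeric(1))
  roster$protein_acc <- psms$protein_acc[!duplicated(pk)]
  roster <- roster[order(roster$peptide), , drop = FALSE]
  m <- nrow(roster)
  n <- length(run_ids)

  ## extract + detect once per (run, peptide)
  traces <- vector("list", n); names(traces) <- run_ids
  peaks <- vector("list", n); names(peaks) <- run_ids
  for (rid in run_ids) {
    traces[[rid]] <- extract_sic_multi(runs[[rid]], roster$mz, ppm_window)
    peaks[[rid]] <- lapply(traces[[rid]], detect_peaks_multipass,
                           params = detect_params)
  }

  area <- matrix(NA_real_, m, n, dimnames = list(roster$peptide, run_ids))
  flags <- matrix(NA_character_, m, n, dimnames = dimnames(area))
  apex <- matrix(NA_real_, m, n, dimnames = dimnames(area))

  ## PSM-anchored cells
  psm_rt <- tapply(psms$rt_sec, list(factor(psms$peptide, roster$peptide),
                                     factor(psms$run_id, run_ids)), median)
  psm_score <- tapply(psms$score, list(factor(psms$peptide, roster$peptide),
                                       factor(psms$run_id, run_ids)), max)
  for (j in seq_len(n)) {
    rid <- run_ids[j]
    for (i in seq_len(m)) {
      rt0 <- psm_rt[i, j]
      if (is.na(rt0)) next
      pks <- peaks[[rid]][[i]]
      hit <- NULL
      if (nrow(pks)) {
        d <- abs(pks$apex_rt - rt0)
        k <- which.min(d)
        if (d[k] <= match_halfwindow) hit <- pks[k, ]
      }
      if (!is.null(hit)) {
        area[i, j] <- hit$area
        apex[i, j] <- hit$apex_rt
        flags[i, j] <- "detected"
      } else {
        tr <- traces[[rid]][[i]]
        span <- range(tr$rt)
        lft <- max(span[1], rt0 - fallback_window / 2)
        rgt <- min(span[2], rt0 + fallback_window / 2)
        area[i, j] <- if (lft < rgt) integrate_peak(tr, lft, rgt) else 0
        apex[i, j] <- rt0
        flags[i, j] <- "window"
      }
    }
  }

  ## alignment on detected apexes, then fill-in for PSM-less cells
  warps <- NULL
  if (align && n > 1) {
    det <- which(flags == "detected", arr.ind = TRUE)
    anchors <- data.frame(
      run_id = run_ids[det[, 2]],
      peptide = roster$peptide[det[, 1]],
      apex_rt = apex[det],
      score = psm_score[det],
      stringsAsFactors = FALSE
    )
    warps <- align_retention_times(anchors)
  }
  for (i in seq_len(m)) {
    missing_j <- which(is.na(area[i, ]))
    if (!length(missing_j)) next
    det_j <- which(flags[i, ] == "detected")
    ref_rt <- if (length(det_j) && !is.null(warps)) {
      mean(vapply(det_j, function(j)
        warp_rt(warps[[run_ids[j]]], apex[i, j]), numeric(1)))
    } else if (length(det_j)) {
      mean(apex[i, det_j])
    } else NA_real_
    for (j in missing_j) {
      rid <- run_ids[j]
      tr <- traces[[rid]][[i]]
      if (is.na(ref_rt)) {  # never detected anywhere: nothing to anchor on
        area[i, j] <- 0
        flags[i, j] <- "inferred"
        next
      }
      pred <- if (!is.null(warps)) {
        warp_rt(warps[[rid]], ref_rt, inverse = TRUE)
      } else ref_rt
      span <- range(tr$rt)
      pred <- min(max(pred, span[1]), span[2])
      hit <- infer_missing_peak(runs[[rid]], roster$mz[i], pred,
                                params = detect_params,
                                ppm_window = ppm_window,
                                search_halfwindow = match_halfwindow,
                                fallback_window = fallback_window,
                                trace = tr, peaks = peaks[[rid]][[i]])
      area[i, j] <- hit$area
      apex[i, j] <- hit$apex_rt
      flags[i, j] <- "inferred"
    }
  }

  structure(list(area = area, flags = flags,
                 floored = matrix(FALSE, m, n, dimnames = dimnames(area)),
                 peptides = roster, run_ids = run_ids, warps = warps,
                 normalization = NULL),
            class = "quant_matrix")
}

#' Normalize a quantitation matrix to the spiked standard peptide
#'
#' Divides each run's peak areas by that run's standard-peptide area, then
#' rescales by the across-run mean standard area so magnitudes remain in
#' raw-area units. After normalization the standard's area is identical in
#' every run.
#'
#' @param qm a `quant_matrix`.
#' @param standard_peptide sequence of the spiked standard (default
#'   `"DRVYHPF"`).
#' @return the normalized `quant_matrix`, with a `normalization` record
#'   (per-run standard areas and scale factors).
#' @export
normalize_to_standard <- function(qm, standard_peptide = "DRVYHPF") {
  stopifnot(inherits(qm, "quant_matrix"))
  i <- which(qm$peptides$peptide == standard_peptide)
  if (!length(i)) stop("standard peptide ", standard_peptide,
                       " not present in the matrix")
  std <- qm$area[i[1], ]
  bad <- which(!is.finite(std) | std <= 0 | qm$floored[i[1], ])
  if (length(bad)) {
    stop("standard peptide missing or floored in run(s): ",
         paste(qm$run_ids[bad], collapse = ", "))
  }
  target <- mean(std)
  factors <- target / std
  qm$area <- sweep(qm$area, 2, factors, `*`)
  qm$normalization <- list(standard_peptide = standard_peptide,
                           standard_area = std, scale_factors = factors,
                           target = target)
  qm
}

#' Apply the minimum reported-area floor
#'
#' Cells below `floor` are censored to `floor` and flagged; all other cells
#' are unchanged. The floor represents the typical spectral noise level
#' below which areas are not considered quantifiable.
#'
#' @param qm a `quant_matrix`.
#' @param floor minimum reported SIC peak area (default 1000).
#' @return the floored `quant_matrix`.
#' @export
apply_floor <- function(qm, floor = 1000) {
  stopifnot(inherits(qm, "quant_matrix"))
  hit <- qm$area < floor
  qm$area[hit] <- floor
  qm$floored <- qm$floored | hit
  attr(qm$floored, "floor") <- floor
  qm
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix: %d peptides x %d runs; %s; %d floored cells>\n",
              nrow(x$area), ncol(x$area),
              if (is.null(x$normalization)) "raw" else "normalized",
              sum(x$floored)))
  invisible(x)
}

#' Write / read a quantitation matrix as TSV
#'
#' `write_quant_matrix()` emits `<stem>_areas.tsv` (peptide, charge,
#' protein_acc, then one column per run), `<stem>_flags.tsv` (same shape,
#' cell provenance flags with `;floored` appended where censored) and
#' `<stem>_normalization.json`.
#'
#' @param qm a `quant_matrix`.
#' @param stem output path stem.
#' @return `read_quant_matrix()` rebuilds the `quant_matrix` (without warp
#'   functions).
#' @export
write_quant_matrix <- function(qm, stem) {
  meta <- qm$peptides[, c("peptide", "charge", "protein_acc")]
  areas <- cbind(meta, as.data.frame(qm$area, check.names = FALSE))
  write.table(areas, paste0(stem, "_areas.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  fl <- qm$flags
  fl[qm$floored] <- paste0(fl[qm$floored], ";floored")
  flags <- cbind(meta, as.data.frame(fl, check.names = FALSE))
  write.table(flags, paste0(stem, "_flags.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(normalization = qm$normalization %||% list(),
         floor = attr(qm$floored, "floor")),
    paste0(stem, "_normalization.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(stem)
}

#' @rdname write_quant_matrix
#' @export
read_quant_matrix <- function(stem) {
  areas <- read.delim(paste0(stem, "_areas.tsv"), check.names = FALSE)
  flags <- read.delim(paste0(stem, "_flags.tsv"), check.names = FALSE)
  meta_cols <- c("peptide", "charge", "protein_acc")
  run_ids <- setdiff(names(areas), meta_cols)
  a <- as.matrix(areas[, run_ids, drop = FALSE])
  rownames(a) <- areas$peptide
  f <- as.matrix(flags[, run_ids, drop = FALSE])
  rownames(f) <- flags$peptide
  floored <- matrix(grepl(";floored", f), nrow(f), ncol(f),
                    dimnames = dimnames(f))
  f <- sub(";floored", "", f)
  norm <- jsonlite::read_json(paste0(stem, "_normalization.json"),
                              simplifyVector = TRUE)
  if (!is.null(norm$floor)) attr(floored, "floor") <- norm$floor
  peptides <- areas[, meta_cols]
  peptides$mz <- NA_real_
  structure(list(area = a, flags = f, floored = floored,
                 peptides = peptides, run_ids = run_ids, warps = NULL,
                 normalization = if (length(norm$normalization))
                   norm$normalization else NULL),
            class = "quant_matrix")
}
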