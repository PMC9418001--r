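#' Restrict a peak list to an m/z window
#'
#' Keeps peaks with `lo <= mz <= hi` (closed interval, matching the usual
#' 200-900 m/z analysis window for DOM). Dropped peaks are appended to the
#' removal log with reason `"mz_window"`.
#'
#' @param pl a [PeakList-class].
#' @param lo,hi window bounds (Th), `lo < hi`.
#' @return Filtered [PeakList-class]; warns (does not error) if nothing
#'   survives.
#' @examples
#' pl <- PeakList(c(150, 350, 950), c(1, 1, 1))
#' peaks(filterMzWindow(pl))$mz
#' @export
filterMzWindow <- function(pl, lo = 200, hi = 900) {
  stopifnot(is(pl, "PeakList"), lo < hi)
  p <- pl@peaks
  keep <- p$mz >= lo & p$mz <= hi
  if (nrow(p) && !any(keep)) {
    warning("filterMzWindow: no peaks inside [", lo, ", ", hi, "] for sample ",
            pl@sampleId)
  }
  dropped <- p[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "mz_window"
  pl@peaks <- p[keep, , drop = FALSE]
  rownames(pl@peaks) <- NULL
  pl@removed <- rbind(pl@removed, dropped)
  pl
}

#' Remove 13C isotopologue peaks
#'
#' A peak is removed iff a peak one isotopologue spacing below it (within
#' `tolPpm`) is more intense, i.e. it has a more abundant isotopologue
#' partner and is therefore itself the satellite. Decisions are made against
#' the input list, and the operation is idempotent: satellites of removed
#' satellites are caught in the same pass. Removed peaks are logged with
#' reason `"isotopologue"`.
#'
#' @param pl a [PeakList-class] (sorted ascending, enforced by the class).
#' @param spacing satellite spacing in Da (default the 13C-12C mass
#'   difference, 1.0033548).
#' @param tolPpm matching tolerance in ppm of the candidate satellite's m/z.
#' @return Filtered [PeakList-class].
#' @export
removeIsotopologues <- function(pl, spacing = isotopologueSpacing(),
                                tolPpm = 1) {
  stopifnot(is(pl, "PeakList"))
  p <- pl@peaks
  n <- nrow(p)
  if (n < 2) return(pl)
  drop <- logical(n)
  target <- p$mz - spacing
  tolDa <- tolPpm * p$mz * 1e-6
  lo <- findInterval(target - tolDa, p$mz) + 1L
  hi <- findInterval(target + tolDa, p$mz)
  for (i in seq_len(n)) {
    if (lo[i] > hi[i]) next
    if (any(p$intensity[lo[i]:hi[i]] > p$intensity[i])) drop[i] <- TRUE
  }
  dropped <- p[drop, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "isotopologue"
  pl@peaks <- p[!drop, , drop = FALSE]
  rownames(pl@peaks) <- NULL
  pl@removed <- rbind(pl@removed, dropped)
  pl
}

# Auto-detect recalibration anchors: peaks whose neutral mass has exactly one
# CHONSP candidate within `tolPpm`, grouped into CH2 homologous ladders
# (series key: fixed N,O,S,P and fixed H - 2C); ladders with >= 3 members
# qualify. Returns data.frame(mz_obs, mz_theo).
.detectAnchors <- function(pl, cfg, tolPpm = 1) {
  mzs <- pl@peaks$mz
  rows <- vector("list", length(mzs))
  for (i in seq_along(mzs)) {
    cand <- enumerateCandidates(neutralMass(mzs[i]), cfg, tolPpm = tolPpm)
    if (nrow(cand) != 1) next
    rows[[i]] <- data.frame(
      mz_obs = mzs[i],
      mz_theo = formulaMass(cand$C, cand$H, cand$N, cand$O, cand$S, cand$P) -
        .PROTON_MASS,
      key = paste(cand$H - 2L * cand$C, cand$N, cand$O, cand$S, cand$P,
                  sep = "/"))
  }
  a <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(a)) return(data.frame(mz_obs = numeric(), mz_theo = numeric()))
  ladder <- table(a$key)
  a <- a[a$key %in% names(ladder)[ladder >= 3], c("mz_obs", "mz_theo")]
  rownames(a) <- NULL
  a
}

#' Internally recalibrate a peak list
#'
#' Fits the mass-domain error model `ppm_error(mz) = a + b * mz` by least
#' squares over anchor peaks and applies the inverse correction. Anchors are
#' either supplied (`data.frame` with `mz_obs`, `mz_theo`) or auto-detected
#' as confidently assignable peaks (unique CHONSP candidate within
#' `anchorTolPpm`) lying on CH2 homologous ladders of at least 3 members,
#' the classic internal calibrant series for DOM spectra. With fewer than 5
#' anchors the list is returned uncorrected with a warning and an identity
#' [CalibrationModel-class].
#'
#' @param pl a [PeakList-class].
#' @param anchors optional anchor `data.frame` (`mz_obs`, `mz_theo`).
#' @param cfg an [assignmentConfig()] used for anchor auto-detection.
#' @param anchorTolPpm candidate-uniqueness tolerance for auto-detection.
#' @return `list(peakList=, model=)`: the corrected [PeakList-class] and the
#'   fitted [CalibrationModel-class] (with post-correction residual RMS).
#' @export
recalibrate <- function(pl, anchors = NULL, cfg = assignmentConfig(),
                        anchorTolPpm = 1) {
  stopifnot(is(pl, "PeakList"))
  if (is.null(anchors)) anchors <- .detectAnchors(pl, cfg, anchorTolPpm)
  if (nrow(anchors) < 5) {
    warning("recalibrate: only ", nrow(anchors),
            " anchors found (need >= 5); returning identity model")
    model <- new("CalibrationModel", a = 0, b = 0, rmsPpm = NA_real_,
                 nAnchors = nrow(anchors), applied = FALSE,
                 anchors = anchors)
    return(list(peakList = pl, model = model))
  }
  ppm <- (anchors$mz_obs - anchors$mz_theo) / anchors$mz_theo * 1e6
  fit <- stats::lm(ppm ~ mz_obs, data = cbind(anchors, ppm = ppm))
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  corr <- anchors$mz_obs / (1 + (a + b * anchors$mz_obs) * 1e-6)
  res <- (corr - anchors$mz_theo) / anchors$mz_theo * 1e6
  model <- new("CalibrationModel", a = a, b = b,
               rmsPpm = sqrt(mean(res^2)), nAnchors = nrow(anchors),
               applied = TRUE, anchors = anchors)
  pl@peaks$mz <- applyCalibration(model, pl@peaks$mz)
  o <- order(pl@peaks$mz)
  pl@peaks <- pl@peaks[o, , drop = FALSE]
  rownames(pl@peaks) <- NULL
  list(peakList = pl, model = model)
}

#' Align peaks across samples
#'
#' Pools all peaks, sorts ascending by m/z, and clusters greedily: a new
#' cluster opens whenever the next peak is more than `tolPpm` from the
#' running unweighted mean of the current cluster. If a sample contributes
#' two peaks to one cluster, the more intense is kept and the other logged as
#' unresolved. The greedy pass is deterministic and order-invariant (the
#' pooled sort uses m/z with sample id as tie-break).
#'
#' @param pls list of [PeakList-class] objects (>= 1, unique sample ids).
#' @param tolPpm alignment tolerance in ppm (default 0.5).
#' @return An [AlignedPeakTable-class]; `metadata(x)$unresolved` holds the
#'   within-sample duplicate log.
#' @export
alignPeaks <- function(pls, tolPpm = 0.5) {
  stopifnot(length(pls) >= 1, all(vapply(pls, is, TRUE, "PeakList")))
  sids <- vapply(pls, sampleId, "")
  if (anyDuplicated(sids)) stop("alignPeaks: duplicate sample ids")
  pooled <- do.call(rbind, lapply(pls, function(pl) {
    p <- peaks(pl)
    if (!nrow(p)) return(NULL)
    data.frame(mz = p$mz, intensity = p$intensity, sample = sampleId(pl))
  }))
  if (is.null(pooled) || !nrow(pooled)) stop("alignPeaks: no peaks to align")
  pooled <- pooled[order(pooled$mz, pooled$sample), ]
  pooled$cluster <- alignGreedyCpp(pooled$mz, tolPpm)

  # resolve within-sample duplicates: keep the most intense peak
  ord <- order(pooled$cluster, pooled$sample, -pooled$intensity, pooled$mz)
  pooled <- pooled[ord, ]
  key <- paste(pooled$cluster, pooled$sample)
  best <- !duplicated(key)
  unresolved <- pooled[!best, c("sample", "mz", "intensity", "cluster")]
  kept <- pooled[best, ]

  nclust <- max(kept$cluster)
  mzM <- matrix(NA_real_, nclust, length(sids),
                dimnames = list(NULL, sids))
  intM <- mzM
  idx <- cbind(kept$cluster, match(kept$sample, sids))
  mzM[idx] <- kept$mz
  intM[idx] <- kept$intensity
  consensus <- as.numeric(rowsum(kept$mz, kept$cluster) /
                            as.integer(table(kept$cluster)))
  rd <- S4Vectors::DataFrame(
    cluster_id = sprintf("cl%05d", seq_len(nclust)),
    consensus_mz = consensus,
    n_samples = as.integer(rowSums(!is.na(mzM))))
  cd <- S4Vectors::DataFrame(
    sample_id = sids,
    condition = vapply(pls, condition, ""),
    depth = vapply(pls, soilDepth, ""),
    row.names = sids)
  se <- SummarizedExperiment(assays = list(mz = mzM, intensity = intM),
                             rowData = rd, colData = cd)
  out <- new("AlignedPeakTable", se)
  metadata(out)$unresolved <- unresolved
  metadata(out)$tol_ppm <- tolPpm
  out
}

#' Read a peak-list CSV
#'
#' Reads one `mz,intensity` CSV (as written by [writeSyntheticDataset()])
#' into a [PeakList-class].
#'
#' @param path CSV path.
#' @param sampleId,condition,depth sample metadata (default: file stem for
#'   the id).
#' @return A [PeakList-class].
#' @export
readPeakList <- function(path, sampleId = NULL, condition = NA_character_,
                         depth = NA_character_) {
  d <- utils::read.csv(path)
  stopifnot(all(c("mz", "intensity") %in% names(d)))
  if (is.null(sampleId)) sampleId <- tools::file_path_sans_ext(basename(path))
  PeakList(d$mz, d$intensity, sampleId = sampleId, condition = condition,
           depth = depth)
}

#' Read a dataset directory of peak lists plus metadata
#'
#' @param dir directory containing `metadata.csv` and one `<sample_id>.csv`
#'   per sample.
#' @return `list(peakLists=, metadata=)`.
#' @export
readPeakListSet <- function(dir) {
  metaPath <- file.path(dir, "metadata.csv")
  if (!file.exists(metaPath)) stop("metadata file not found: ", metaPath)
  meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "condition") %in% names(meta)))
  if (!"depth" %in% names(meta)) meta$depth <- NA_character_
  pls <- lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(dir, paste0(meta$sample_id[i], ".csv"))
    if (!file.exists(f)) stop("peak-list file not found: ", f)
    readPeakList(f, meta$sample_id[i], meta$condition[i], meta$depth[i])
  })
  names(pls) <- meta$sample_id
  list(peakLists = pls, metadata = meta)
}
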