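#' @import methods
NULL

#' @rdname PeakList-class
#' @param x a `PeakList` (or other pyroDOM object).
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname PeakList-class
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname PeakList-class
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))

#' @rdname PeakList-class
#' @export
setGeneric("soilDepth", function(x) standardGeneric("soilDepth"))

#' @rdname PeakList-class
#' @export
setGeneric("removalLog", function(x) standardGeneric("removalLog"))

#' @rdname AlignedPeakTable-class
#' @param x an `AlignedPeakTable` or `AssignedFormulaTable`.
#' @export
setGeneric("consensusMz", function(x) standardGeneric("consensusMz"))

#' @rdname AssignedFormulaTable-class
#' @export
setGeneric("assignedFormulas", function(x) standardGeneric("assignedFormulas"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @rdname PresenceMatrix-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# SyntheticDesign
# ---------------------------------------------------------------------------

#' Design of a synthetic DOM study
#'
#' Describes the simulated study the synthetic-data generator produces:
#' burn-severity conditions with replicate counts, the size of the shared
#' ("core") formula pool and the per-condition unique strata, the fraction of
#' each stratum drawn from the aromatic (low H/C, AI >= 0.5) population, mass
#' error and calibration drift of the virtual instrument, per-replicate
#' detection probability, log-normal intensity parameters, and the RNG seed.
#'
#' The default design mirrors a burned-soil surface study with four severity
#' conditions (control/low/moderate/high) at 4/6/5/6 replicates and a
#' severity-increasing aromatic fraction in the condition-unique strata.
#'
#' @slot conditions character vector of condition labels.
#' @slot replicates integer vector of replicates per condition (parallel to
#'   `conditions`).
#' @slot nCoreFormulas number of formulas shared by every condition.
#' @slot nUniqueFormulas number of condition-unique formulas per condition.
#' @slot aromaticFraction named numeric, fraction of each condition's unique
#'   stratum drawn from the aromatic population.
#' @slot coreAromaticFraction aromatic fraction of the shared core pool.
#' @slot massErrorSdPpm per-peak Gaussian mass error SD (ppm).
#' @slot calibrationDriftPpm length-2 numeric `(a, b)`: systematic ppm offset
#'   `a + b * mz` applied to every observed m/z.
#' @slot detectionProb probability a pool formula is observed in a replicate.
#' @slot intensityMeanlog,intensitySdlog log-normal intensity parameters.
#' @slot isotopologues logical; emit single-13C satellite peaks.
#' @slot depth depth label stamped on every sample.
#' @slot seed integer RNG seed; identical seed + design gives byte-identical
#'   output.
#' @export
setClass("SyntheticDesign", representation(
  conditions = "character",
  replicates = "integer",
  nCoreFormulas = "integer",
  nUniqueFormulas = "integer",
  aromaticFraction = "numeric",
  coreAromaticFraction = "numeric",
  massErrorSdPpm = "numeric",
  calibrationDriftPpm = "numeric",
  detectionProb = "numeric",
  intensityMeanlog = "numeric",
  intensitySdlog = "numeric",
  isotopologues = "logical",
  depth = "character",
  seed = "integer"
))

setValidity("SyntheticDesign", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
  chk(length(object@conditions) >= 1 && !anyDuplicated(object@conditions),
      "conditions: must be a non-empty set of distinct labels")
  chk(length(object@replicates) == length(object@conditions) &&
        all(object@replicates >= 1L),
      "replicates: one positive integer per condition")
  chk(length(object@nCoreFormulas) == 1 && object@nCoreFormulas >= 1L,
      "nCoreFormulas: must be a positive integer")
  chk(length(object@nUniqueFormulas) == 1 && object@nUniqueFormulas >= 0L,
      "nUniqueFormulas: must be a non-negative integer")
  chk(length(object@aromaticFraction) == length(object@conditions) &&
        all(object@aromaticFraction >= 0 & object@aromaticFraction <= 1),
      "aromaticFraction: one value in [0,1] per condition")
  chk(object@coreAromaticFraction >= 0 && object@coreAromaticFraction <= 1,
      "coreAromaticFraction: must be in [0,1]")
  chk(object@massErrorSdPpm >= 0, "massErrorSdPpm: must be >= 0")
  chk(length(object@calibrationDriftPpm) == 2,
      "calibrationDriftPpm: must be length 2 (offset, slope per m/z)")
  chk(object@detectionProb > 0 && object@detectionProb <= 1,
      "detectionProb: must be in (0,1]")
  chk(object@intensitySdlog >= 0, "intensitySdlog: must be >= 0")
  chk(length(object@seed) == 1 && !is.na(object@seed),
      "seed: must be a single integer")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# PeakList
# ---------------------------------------------------------------------------

#' A per-sample list of detected ions
#'
#' One centroided negative-mode spectrum: observed m/z and intensity pairs in
#' ascending m/z order, with the sample's metadata and a cumulative removal
#' log. Filtering operations ([filterMzWindow()], [removeIsotopologues()])
#' return a new `PeakList` whose `removalLog()` records every dropped peak
#' with the reason, so peak accounting is conserved across the pipeline.
#'
#' @slot sampleId sample identifier, unique within a run.
#' @slot condition burn-severity condition label.
#' @slot depth depth label.
#' @slot peaks `data.frame` with columns `mz`, `intensity`, ascending `mz`.
#' @slot removed `data.frame` with columns `mz`, `intensity`, `reason`.
#' @export
setClass("PeakList", representation(
  sampleId = "character",
  condition = "character",
  depth = "character",
  peaks = "data.frame",
  removed = "data.frame"
))

setValidity("PeakList", function(object) {
  p <- object@peaks
  if (!all(c("mz", "intensity") %in% names(p)))
    return("peaks must have columns mz and intensity")
  if (nrow(p) && any(p$mz <= 0)) return("all mz must be positive")
  if (nrow(p) && any(p$intensity <= 0)) return("all intensities must be positive")
  if (is.unsorted(p$mz)) return("peaks must be sorted ascending by mz")
  TRUE
})

#' Construct a PeakList
#'
#' @param mz,intensity numeric vectors of equal length.
#' @param sampleId,condition,depth sample metadata strings.
#' @return A [PeakList-class] object (peaks sorted ascending by m/z).
#' @examples
#' pl <- PeakList(c(200.1, 350.2), c(1e5, 2e5), "s1", "control")
#' peaks(pl)
#' @export
PeakList <- function(mz, intensity, sampleId = "sample",
                     condition = NA_character_, depth = NA_character_) {
  o <- order(mz)
  new("PeakList", sampleId = sampleId, condition = condition, depth = depth,
      peaks = data.frame(mz = as.numeric(mz[o]),
                         intensity = as.numeric(intensity[o])),
      removed = data.frame(mz = numeric(), intensity = numeric(),
                           reason = character()))
}

#' @rdname PeakList-class
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)

#' @rdname PeakList-class
#' @export
setMethod("sampleId", "PeakList", function(x) x@sampleId)

#' @rdname PeakList-class
#' @export
setMethod("condition", "PeakList", function(x) x@condition)

#' @rdname PeakList-class
#' @export
setMethod("soilDepth", "PeakList", function(x) x@depth)

#' @rdname PeakList-class
#' @export
setMethod("removalLog", "PeakList", function(x) x@removed)

setMethod("show", "PeakList", function(object) {
  cat("PeakList '", object@sampleId, "' (", object@condition, ", ",
      object@depth, "): ", nrow(object@peaks), " peaks",
      if (nrow(object@peaks))
        sprintf(", m/z %.4f-%.4f", min(object@peaks$mz), max(object@peaks$mz)),
      "; ", nrow(object@removed), " removed\n", sep = "")
})

# ---------------------------------------------------------------------------
# CalibrationModel
# ---------------------------------------------------------------------------

#' Linear mass-recalibration model
#'
#' Least-squares fit of `ppm_error(mz) = a + b * mz` over internal anchor
#' peaks (confidently assignable CH2-homologous-series members), applied as
#' the inverse correction `mz / (1 + (a + b*mz) * 1e-6)`.
#'
#' @slot a,b fitted intercept (ppm) and slope (ppm per Th).
#' @slot rmsPpm residual root-mean-square error over anchors after
#'   correction.
#' @slot nAnchors number of anchor peaks used.
#' @slot applied FALSE for the identity model (too few anchors).
#' @slot anchors `data.frame` of the anchors (observed and theoretical m/z).
#' @export
setClass("CalibrationModel", representation(
  a = "numeric", b = "numeric", rmsPpm = "numeric",
  nAnchors = "integer", applied = "logical", anchors = "data.frame"
))

setMethod("show", "CalibrationModel", function(object) {
  if (object@applied) {
    cat(sprintf(
      "CalibrationModel: ppm(mz) = %.4f + %.6f*mz; %d anchors, residual RMS %.4f ppm\n",
      object@a, object@b, object@nAnchors, object@rmsPpm))
  } else {
    cat("CalibrationModel: identity (recalibration skipped,",
        object@nAnchors, "anchors)\n")
  }
})

#' Apply a calibration model to m/z values
#'
#' @param model a [CalibrationModel-class].
#' @param mz numeric vector of observed m/z.
#' @return Corrected m/z vector (unchanged for the identity model).
#' @export
applyCalibration <- function(model, mz) {
  if (!model@applied) return(mz)
  mz / (1 + (model@a + model@b * mz) * 1e-6)
}

# ---------------------------------------------------------------------------
# AlignedPeakTable / AssignedFormulaTable
# ---------------------------------------------------------------------------

#' Cross-sample aligned peak table
#'
#' A [SummarizedExperiment-class] with one row per m/z cluster and one column
#' per sample. Assays `mz` and `intensity` hold the member peak of each
#' sample in each cluster (NA where absent); `rowData` carries `cluster_id`,
#' `consensus_mz` (unweighted mean of member m/z) and `n_samples`; `colData`
#' carries the sample metadata; `metadata(x)$unresolved` logs peaks dropped
#' because their sample already had a more intense peak in the cluster.
#'
#' @export
setClass("AlignedPeakTable", contains = "SummarizedExperiment")

#' @rdname AlignedPeakTable-class
#' @export
setMethod("consensusMz", "AlignedPeakTable",
          function(x) rowData(x)$consensus_mz)

setMethod("show", "AlignedPeakTable", function(object) {
  cat(class(object), ": ", nrow(object), " clusters x ", ncol(object),
      " samples\n", sep = "")
  callNextMethod()
})

#' Aligned table with molecular formula assignments
#'
#' An [AlignedPeakTable-class] whose `rowData` additionally carries the
#' assignment result per cluster: `neutral_mass`, element counts
#' `C,H,N,O,S,P`, `formula` (Hill string, NA if unassigned), `error_ppm`,
#' `n_candidates` and `reason` (`assigned`, `no_candidate`, or
#' `ambiguous_if_strict`). Metric annotation ([annotateFormulas()]) appends
#' `hc`, `oc`, NOSC/AI variants and `vk_class`.
#'
#' @export
setClass("AssignedFormulaTable", contains = "AlignedPeakTable")

#' @rdname AssignedFormulaTable-class
#' @export
setMethod("assignedFormulas", "AssignedFormulaTable", function(x) {
  rd <- rowData(x)
  as.character(rd$formula[!is.na(rd$formula)])
})

# ---------------------------------------------------------------------------
# PresenceMatrix
# ---------------------------------------------------------------------------

#' Formula-by-sample detection matrix
#'
#' Boolean matrix of formula detections (rows = Hill strings, columns =
#' sample ids) with the sample metadata alongside. Rows detected in no sample
#' are dropped at construction and recorded in `droppedFormulas`.
#'
#' @slot mat logical matrix, rownames = Hill formulas, colnames = sample ids.
#' @slot samples `data.frame` with columns `sample_id`, `condition`, `depth`.
#' @slot droppedFormulas character vector of all-absent formulas removed.
#' @export
setClass("PresenceMatrix", representation(
  mat = "matrix", samples = "data.frame", droppedFormulas = "character"
))

setValidity("PresenceMatrix", function(object) {
  if (!is.logical(object@mat)) return("mat must be a logical matrix")
  if (!identical(colnames(object@mat), object@samples$sample_id))
    return("column set must equal the sample metadata exactly (same order)")
  if (nrow(object@mat) && any(rowSums(object@mat) == 0))
    return("all-false rows must be dropped")
  TRUE
})

#' Construct a PresenceMatrix
#'
#' @param mat logical matrix (formulas x samples, dimnames required).
#' @param samples `data.frame` with `sample_id`, `condition`, and optionally
#'   `depth`, matching the matrix columns.
#' @return A [PresenceMatrix-class]. All-absent formulas are dropped with a
#'   message and recorded in the `droppedFormulas` slot.
#' @export
PresenceMatrix <- function(mat, samples) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  mode(mat) <- "logical"
  if (!"depth" %in% names(samples)) samples$depth <- NA_character_
  samples <- samples[match(colnames(mat), samples$sample_id),
                     c("sample_id", "condition", "depth")]
  if (anyNA(samples$sample_id))
    stop("PresenceMatrix: matrix columns missing from sample metadata")
  dead <- rownames(mat)[rowSums(mat) == 0]
  if (length(dead)) {
    message("PresenceMatrix: dropping ", length(dead),
            " formula(s) detected in no sample")
    mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  }
  new("PresenceMatrix", mat = mat, samples = samples, droppedFormulas = dead)
}

#' @rdname PresenceMatrix-class
#' @export
setMethod("detected", "PresenceMatrix", function(x) x@mat)

#' @rdname PresenceMatrix-class
#' @export
setMethod("sampleInfo", "PresenceMatrix", function(x) x@samples)

setMethod("show", "PresenceMatrix", function(object) {
  cat("PresenceMatrix: ", nrow(object@mat), " formulas x ",
      ncol(object@mat), " samples (", length(object@droppedFormulas),
      " dropped)\n", sep = "")
  tab <- table(object@samples$condition)
  cat("  samples per condition:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})
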