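#' Load and validate a pipeline configuration
#'
#' Configuration may be a YAML file or an equivalent named list. Recognised
#' keys (all optional except `paths` for [runPipeline()]):
#' \itemize{
#'   \item `paths`: `dataset` (directory with `metadata.csv` and one
#'     `<sample_id>.csv` per sample) and `outdir`.
#'   \item `mz_window`: `c(lo, hi)`, default `c(200, 900)`.
#'   \item `isotopologue_tol_ppm` (default 1), `recalibrate` (default TRUE),
#'     `alignment_tol_ppm` (default 0.5).
#'   \item `assignment`: `tol_ppm`, `strict` (passed to
#'     [assignmentConfig()] / [assignTable()]).
#'   \item `kendrick`: `base_exact`, `kmd_tolerance`, `nkm_from`,
#'     `require_conditions` (passed to [kendrickConfig()]).
#'   \item `severity_order` (default control/low/moderate/high), `grouping`
#'     (condition to group-label map for unique-formula sets), `seed`.
#' }
#'
#' @param config a YAML path or named list.
#' @param requirePaths check that input paths exist (used by
#'   [runPipeline()] before any compute).
#' @return Normalized configuration list (class `pipelineConfig`).
#' @export
pipelineConfig <- function(config, requirePaths = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dft <- list(mz_window = c(200, 900), isotopologue_tol_ppm = 1,
              recalibrate = TRUE, alignment_tol_ppm = 0.5,
              assignment = list(tol_ppm = 0.5, strict = FALSE),
              kendrick = list(),
              severity_order = c("control", "low", "moderate", "high"),
              grouping = NULL, seed = 1L)
  cfg <- utils::modifyList(dft, config)
  if (requirePaths) {
    if (is.null(cfg$paths$dataset))
      stop("config error: paths$dataset is required")
    meta <- file.path(cfg$paths$dataset, "metadata.csv")
    if (!file.exists(meta))
      stop("config error: metadata file not found: ", meta)
    if (is.null(cfg$paths$outdir))
      stop("config error: paths$outdir is required")
  }
  class(cfg) <- "pipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Simulate a synthetic dataset to disk
#'
#' Thin wrapper over [writeSyntheticDataset()]: builds the design (from a
#' config list of [syntheticDesign()] arguments, or a ready
#' [SyntheticDesign-class]) and writes the peak-list CSVs, metadata and
#' ground truth.
#'
#' @param design a [SyntheticDesign-class] or a named list of
#'   [syntheticDesign()] arguments.
#' @param dir output directory.
#' @param seed optional seed override.
#' @return Invisibly, the generated dataset (see [writeSyntheticDataset()]).
#' @export
simulateDataset <- function(design = list(), dir, seed = NULL) {
  if (!is(design, "SyntheticDesign")) {
    design <- do.call(syntheticDesign, design)
  }
  if (!is.null(seed)) design@seed <- as.integer(seed)
  writeSyntheticDataset(design, dir)
}

#' Run the full DOM characterization pipeline
#'
#' Executes: m/z window filter, isotopologue removal, per-sample internal
#' recalibration, cross-sample alignment, CHONSP formula assignment,
#' molecular descriptor annotation, C4H2 Kendrick series detection with the
#' all-conditions retention rule, and the condition comparison layer
#' (unique-formula sets, one-sided pairwise AI tests, NOSC summaries of
#' unique formulas). Every intermediate artifact is written under
#' `paths$outdir` together with `manifest.json` recording the config hash,
#' seed, per-stage row counts and package versions. The manifest satisfies
#' the conservation identity: input peaks = aligned + window-filtered +
#' isotopologue-removed + alignment-unresolved.
#'
#' @param config a YAML path, named list, or [pipelineConfig()].
#' @return Invisibly, a list with the manifest and the main in-memory
#'   objects (`aligned`, `assigned`, `presence`, `series`, `aiStats`,
#'   `noscSummary`).
#' @export
runPipeline <- function(config) {
  cfg <- if (inherits(config, "pipelineConfig")) config
         else pipelineConfig(config)
  outdir <- cfg$paths$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(cfg$seed))

  ds <- .stage("read", readPeakListSet(cfg$paths$dataset))
  pls <- ds$peakLists
  nInput <- sum(vapply(pls, function(p) nrow(peaks(p)), 0L))

  pls <- .stage("mz_window", lapply(pls, filterMzWindow,
                                    lo = cfg$mz_window[1],
                                    hi = cfg$mz_window[2]))
  pls <- .stage("isotopologues", lapply(pls, removeIsotopologues,
                                        tolPpm = cfg$isotopologue_tol_ppm))
  acfg <- assignmentConfig(tolPpm = cfg$assignment$tol_ppm)
  calib <- NULL
  if (isTRUE(cfg$recalibrate)) {
    rec <- .stage("recalibrate", lapply(pls, recalibrate, cfg = acfg))
    pls <- lapply(rec, `[[`, "peakList")
    calib <- do.call(rbind, lapply(names(rec), function(s) {
      m <- rec[[s]]$model
      data.frame(sample_id = s, a = m@a, b = m@b, rms_ppm = m@rmsPpm,
                 n_anchors = m@nAnchors, applied = m@applied)
    }))
    utils::write.csv(calib, file.path(outdir, "calibration.csv"),
                     row.names = FALSE)
  }
  filterLog <- do.call(rbind, lapply(pls, function(p) {
    r <- removalLog(p)
    if (nrow(r)) cbind(sample_id = sampleId(p), r) else NULL
  }))
  if (!is.null(filterLog))
    utils::write.csv(filterLog, file.path(outdir, "filter_log.csv"),
                     row.names = FALSE)

  apt <- .stage("align", alignPeaks(pls, tolPpm = cfg$alignment_tol_ppm))
  aft <- .stage("assign", assignTable(apt, acfg,
                                      strict = isTRUE(cfg$assignment$strict)))
  aft <- .stage("metrics", annotateFormulas(aft))
  rd <- as.data.frame(rowData(aft))
  utils::write.csv(cbind(rd, as.data.frame(assay(aft, "mz"))),
                   file.path(outdir, "aligned_assigned.csv"),
                   row.names = FALSE)

  kcfg <- do.call(kendrickConfig, c(
    cfg$kendrick[intersect(names(cfg$kendrick),
                           c("baseExact", "kmdTolerance", "nkmFrom",
                             "step", "baseNominal"))],
    if (!is.null(cfg$kendrick$require_conditions))
      list(requireConditions = cfg$kendrick$require_conditions)
    else list(requireConditions =
                intersect(cfg$severity_order,
                          unique(as.character(colData(aft)$condition))))))
  ok <- !is.na(rd$formula)
  krec <- .stage("kendrick", kendrickTransform(rd$consensus_mz[ok], kcfg,
                                               formulas = rd$formula[ok]))
  series <- .stage("kendrick", detectSeries(krec, kcfg))

  pm <- .stage("presence", buildPresence(aft, ds$metadata))
  occ <- formulaOccupancy(pm)
  retained <- .stage("kendrick",
                     filterSeriesByConditions(series, occ, kcfg))
  allSeries <- attr(retained, "all")
  if (!is.null(allSeries) && nrow(allSeries)) {
    utils::write.csv(
      allSeries[, c("series_id", "kmd_key", "n_members", "nkms",
                    "formulas", "conditions_present", "retained")],
      file.path(outdir, "kendrick_series.csv"), row.names = FALSE)
  }

  grouping <- if (!is.null(cfg$grouping)) unlist(cfg$grouping) else NULL
  uniq <- .stage("comparison", uniqueFormulas(pm, grouping))
  utils::write.csv(
    data.frame(group = rep(names(uniq), lengths(uniq)),
               formula = unlist(uniq, use.names = FALSE)),
    file.path(outdir, "unique_formulas.csv"), row.names = FALSE)

  aiVals <- stats::setNames(rd$ai_standard[ok], rd$formula[ok])
  aiVals <- aiVals[!duplicated(names(aiVals))]
  aiStats <- .stage("comparison",
                    compareAI(pm, aiVals,
                              severityOrder = cfg$severity_order))
  utils::write.csv(aiStats$perSample, file.path(outdir, "ai_per_sample.csv"),
                   row.names = FALSE)
  if (!is.null(aiStats$tests))
    utils::write.csv(aiStats$tests, file.path(outdir, "ai_tests.csv"),
                     row.names = FALSE)

  noscVals <- stats::setNames(rd$nosc_standard[ok], rd$formula[ok])
  noscVals <- noscVals[!duplicated(names(noscVals))]
  noscSummary <- .stage("comparison", {
    us <- uniq[lengths(uniq) > 0]
    if (length(us)) summarizeNOSC(us, noscVals,
                                  severityOrder = cfg$severity_order)
    else NULL
  })
  if (!is.null(noscSummary)) {
    utils::write.csv(noscSummary$medians,
                     file.path(outdir, "nosc_medians.csv"),
                     row.names = FALSE)
    utils::write.csv(noscSummary$histogram,
                     file.path(outdir, "nosc_histogram.csv"),
                     row.names = FALSE)
    if (!is.null(noscSummary$tests))
      utils::write.csv(noscSummary$tests,
                       file.path(outdir, "nosc_tests.csv"),
                       row.names = FALSE)
  }

  nKept <- sum(!is.na(assay(aft, "mz")))
  nWin <- if (is.null(filterLog)) 0L else sum(filterLog$reason == "mz_window")
  nIso <- if (is.null(filterLog)) 0L
          else sum(filterLog$reason == "isotopologue")
  nUnres <- nrow(metadata(aft)$unresolved)
  manifest <- list(
    config_hash = .configHash(cfg, outdir),
    seed = as.integer(cfg$seed),
    stages = list(
      input_peaks = nInput, window_filtered = nWin,
      isotopologue_removed = nIso, alignment_unresolved = nUnres,
      aligned_peaks = nKept, clusters = nrow(aft),
      assigned = sum(ok), unassigned = sum(!ok),
      series_detected = nrow(allSeries %||% data.frame()),
      series_retained = nrow(retained)),
    versions = list(r = R.version.string,
                    pyroDOM = as.character(utils::packageVersion("pyroDOM")))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, aligned = apt, assigned = aft,
                 presence = pm, series = retained, allSeries = allSeries,
                 uniqueSets = uniq, aiStats = aiStats,
                 noscSummary = noscSummary, calibration = calib))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hash of the canonicalized config: written to disk, hashed with md5
.configHash <- function(cfg, outdir) {
  cj <- file.path(outdir, "config_used.json")
  jsonlite::write_json(unclass(cfg), cj, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(cj))
}
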