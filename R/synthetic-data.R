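#' Create a synthetic study design
#'
#' Builds and validates a [SyntheticDesign-class]. The defaults emulate a
#' burned-soil surface DOM study: four burn-severity conditions at 4/6/5/6
#' replicates, a shared core pool of 2000 formulas (a conventional DOM
#' spectral richness), 150 condition-unique formulas per condition, and an
#' aromatic fraction of the unique strata that increases with severity. The
#' virtual instrument applies sub-ppm Gaussian mass error, optional
#' systematic calibration drift (constant + linear in m/z), log-normal
#' intensities, and single-13C isotopologue satellites.
#'
#' @param conditions condition labels, in severity order.
#' @param replicates replicates per condition (scalar or one per condition).
#' @param nCoreFormulas size of the shared formula pool.
#' @param nUniqueFormulas condition-unique formulas per condition.
#' @param aromaticFraction fraction of each condition's unique stratum drawn
#'   from the aromatic (AI >= 0.5) population; scalar or named/ordered per
#'   condition.
#' @param coreAromaticFraction aromatic fraction of the shared core pool.
#' @param massErrorSdPpm SD of the per-peak Gaussian mass error, ppm.
#' @param calibrationDriftPpm systematic drift: a scalar constant offset, or
#'   `c(a, b)` for `a + b * mz` ppm.
#' @param detectionProb probability a pool formula appears in a replicate.
#' @param intensityMeanlog,intensitySdlog log-normal intensity parameters.
#' @param isotopologues emit 13C satellite peaks (intensity
#'   `0.011 * C * parent`).
#' @param depth depth label for all samples.
#' @param seed integer RNG seed.
#' @return A validated [SyntheticDesign-class].
#' @examples
#' syntheticDesign(nCoreFormulas = 100, seed = 1)
#' @export
syntheticDesign <- function(conditions = c("control", "low", "moderate", "high"),
                            replicates = c(4L, 6L, 5L, 6L),
                            nCoreFormulas = 2000L,
                            nUniqueFormulas = 150L,
                            aromaticFraction = c(0.05, 0.15, 0.30, 0.40),
                            coreAromaticFraction = 0.10,
                            massErrorSdPpm = 0.15,
                            calibrationDriftPpm = c(0, 0),
                            detectionProb = 0.9,
                            intensityMeanlog = log(1e6),
                            intensitySdlog = 1.2,
                            isotopologues = TRUE,
                            depth = "surface",
                            seed = 1L) {
  reps <- as.integer(rep_len(replicates, length(conditions)))
  af <- rep_len(as.numeric(aromaticFraction), length(conditions))
  if (!is.null(names(aromaticFraction))) {
    if (!setequal(names(aromaticFraction), conditions))
      stop("aromaticFraction: names must match conditions")
    af <- as.numeric(aromaticFraction[conditions])
  }
  names(af) <- conditions
  drift <- as.numeric(calibrationDriftPpm)
  if (length(drift) == 1) drift <- c(drift, 0)
  new("SyntheticDesign",
      conditions = conditions, replicates = reps,
      nCoreFormulas = as.integer(nCoreFormulas),
      nUniqueFormulas = as.integer(nUniqueFormulas),
      aromaticFraction = af,
      coreAromaticFraction = as.numeric(coreAromaticFraction),
      massErrorSdPpm = as.numeric(massErrorSdPpm),
      calibrationDriftPpm = drift,
      detectionProb = as.numeric(detectionProb),
      intensityMeanlog = as.numeric(intensityMeanlog),
      intensitySdlog = as.numeric(intensitySdlog),
      isotopologues = isotopologues, depth = depth,
      seed = as.integer(seed))
}

# Stage-specific seed derivation: all randomness flows from the design seed.
.deriveSeed <- function(seed, stage) {
  as.integer((as.double(seed) + 104729 * stage) %% 2147483646 + 1)
}

# Element-count validity used by the generator; matches the default
# assignment rules so every synthetic formula is assignable.
.validFormula <- function(c, h, n, o, s, p) {
  mass <- formulaMass(c, h, n, o, s, p)
  rdbe <- c - h / 2 + n / 2 + p / 2 + 1
  c >= 1 && c <= 100 && h >= 1 && h <= 200 && o <= 60 &&
    h / c >= 0.2 && h / c <= 3 && o / c <= 1.5 &&
    rdbe >= 0 && (h + n + p) %% 2 == 0 &&
    mass >= 201 && mass <= 899
}

# Draw one homologous ladder (seed formula + repeat-unit extensions) from a
# stratum. Aromatic formulas grow by C4H2 (polyaromatic growth, preserves
# AI >= 0.5); aliphatic formulas grow by CH2. Returns a list of count vectors.
.drawLadder <- function(aromatic) {
  if (aromatic) {
    c0 <- sample(12:30, 1)
    h0 <- max(1L, as.integer(round(stats::runif(1, 0.3, 0.8) * c0)))
    o0 <- as.integer(round(stats::runif(1, 0.02, 0.4) * c0))
    nn <- sample(0:2, 1, prob = c(0.75, 0.20, 0.05))
    ns <- stats::rbinom(1, 1, 0.08)
    np <- stats::rbinom(1, 1, 0.04)
    unit <- c(4L, 2L); len <- sample(1:4, 1)
  } else {
    c0 <- sample(9:32, 1)
    h0 <- max(1L, as.integer(round(stats::runif(1, 1.0, 2.0) * c0)))
    o0 <- as.integer(round(stats::runif(1, 0.2, 0.8) * c0))
    nn <- sample(0:3, 1, prob = c(0.6, 0.25, 0.1, 0.05))
    ns <- stats::rbinom(1, 1, 0.10)
    np <- stats::rbinom(1, 1, 0.05)
    unit <- c(1L, 2L); len <- sample(1:5, 1)
  }
  if ((h0 + nn + np) %% 2 == 1) h0 <- h0 + 1L
  out <- list()
  for (k in seq_len(len) - 1L) {
    cc <- c0 + unit[1] * k; hh <- h0 + unit[2] * k
    if (!.validFormula(cc, hh, nn, o0, ns, np)) next
    ai <- aromaticityIndex(formulaTable(cc, hh, nn, o0, ns, np))
    if (aromatic && ai < 0.5) next
    if (!aromatic && ai >= 0.5) next
    out[[length(out) + 1L]] <- c(C = cc, H = hh, N = nn, O = o0, S = ns, P = np)
  }
  out
}

# Sample nTarget distinct formulas from a stratum, avoiding hill strings in
# `taken` (an environment used as a set).
.sampleStratum <- function(nTarget, aromatic, taken) {
  acc <- vector("list", nTarget)
  got <- 0L
  guard <- 0L
  while (got < nTarget) {
    guard <- guard + 1L
    if (guard > 50000L) stop("formula sampling failed to converge")
    for (f in .drawLadder(aromatic)) {
      if (got >= nTarget) break
      hill <- hillString(f["C"], f["H"], f["N"], f["O"], f["S"], f["P"])
      if (exists(hill, envir = taken, inherits = FALSE)) next
      assign(hill, TRUE, envir = taken)
      got <- got + 1L
      acc[[got]] <- f
    }
  }
  m <- do.call(rbind, acc)
  ft <- formulaTable(C = m[, "C"], H = m[, "H"], N = m[, "N"],
                     O = m[, "O"], S = m[, "S"], P = m[, "P"])
  ft$aromatic <- aromatic
  ft
}

.sampleMixedPool <- function(n, aromaticFraction, taken) {
  nArom <- as.integer(round(n * aromaticFraction))
  parts <- list()
  if (nArom > 0) parts$arom <- .sampleStratum(nArom, TRUE, taken)
  if (n - nArom > 0) parts$ali <- .sampleStratum(n - nArom, FALSE, taken)
  do.call(rbind, unname(parts))
}

#' Generate per-condition formula pools
#'
#' Draws the shared core pool, then a unique stratum per condition (disjoint
#' across conditions and from the core). Each stratum mixes an aromatic
#' population (standard aromaticity index >= 0.5, grown as C4H2 homologous
#' ladders) and an aliphatic population (AI < 0.5, grown as CH2 ladders), so
#' the pools contain the homologous series structure that internal
#' recalibration and Kendrick analysis rely on. Every formula satisfies the
#' default assignment validity rules and has neutral mass in [201, 899] Da.
#'
#' @param design a [SyntheticDesign-class].
#' @return Named list (one element per condition) of formula `data.frame`s
#'   ([formulaTable()] columns plus `aromatic` and `stratum`).
#' @examples
#' pools <- generateFormulaPool(syntheticDesign(
#'   nCoreFormulas = 50, nUniqueFormulas = 10, seed = 1))
#' sapply(pools, nrow)
#' @export
generateFormulaPool <- function(design) {
  validObject(design)
  set.seed(.deriveSeed(design@seed, 1L))
  taken <- new.env(parent = emptyenv())
  core <- .sampleMixedPool(design@nCoreFormulas, design@coreAromaticFraction,
                           taken)
  core$stratum <- "core"
  pools <- list()
  for (cond in design@conditions) {
    if (design@nUniqueFormulas > 0) {
      uni <- .sampleMixedPool(design@nUniqueFormulas,
                              design@aromaticFraction[[cond]], taken)
      uni$stratum <- "unique"
      pools[[cond]] <- rbind(core, uni)
    } else {
      pools[[cond]] <- core
    }
    rownames(pools[[cond]]) <- NULL
  }
  pools
}

#' Synthesize per-sample peak lists from formula pools
#'
#' For each replicate of each condition, every pool formula is detected with
#' probability `detectionProb`; detected formulas appear as singly charged
#' deprotonated ions at
#' `(mass - 1.00727646) * (1 + (drift(mz) + e) * 1e-6)`, `e ~ N(0, sd_ppm)`,
#' with log-normal intensities. When isotopologues are enabled, each detected
#' formula also emits a single-13C satellite 1.0033548 Da above the parent at
#' intensity `0.011 * C * parent` (the leading binomial term), subject to the
#' same mass-error model. A ground-truth table mapping every emitted peak to
#' its formula (and isotopologue status) accompanies the peak lists.
#'
#' @param pools per-condition formula pools from [generateFormulaPool()].
#' @param design the same [SyntheticDesign-class].
#' @return List with elements `peakLists` (list of [PeakList-class]),
#'   `groundTruth` (`data.frame`: `sample_id`, `mz`, `formula`,
#'   `is_isotopologue`), and `metadata` (`data.frame`: `sample_id`,
#'   `condition`, `depth`, `replicate`).
#' @export
synthesizePeakLists <- function(pools, design) {
  validObject(design)
  if (!all(design@conditions %in% names(pools)))
    stop("pools must cover every design condition")
  if (any(vapply(pools, nrow, 0L) == 0)) stop("pools must be non-empty")
  set.seed(.deriveSeed(design@seed, 2L))
  a <- design@calibrationDriftPpm[1]; b <- design@calibrationDriftPpm[2]
  peakLists <- list(); truth <- list(); meta <- list()
  for (ci in seq_along(design@conditions)) {
    cond <- design@conditions[ci]
    pool <- pools[[cond]]
    ionTrue <- pool$mass - .PROTON_MASS
    for (r in seq_len(design@replicates[ci])) {
      sid <- sprintf("%s_%02d", cond, r)
      det <- stats::runif(nrow(pool)) < design@detectionProb
      n <- sum(det)
      if (n == 0) next
      tru <- ionTrue[det]
      eps <- a + b * tru + stats::rnorm(n, 0, design@massErrorSdPpm)
      mz <- tru * (1 + eps * 1e-6)
      int <- stats::rlnorm(n, design@intensityMeanlog, design@intensitySdlog)
      df <- data.frame(mz = mz, intensity = int,
                       formula = pool$hill[det], iso = FALSE)
      if (design@isotopologues) {
        satTrue <- tru + .C13_SPACING
        epsS <- a + b * satTrue + stats::rnorm(n, 0, design@massErrorSdPpm)
        sat <- data.frame(mz = satTrue * (1 + epsS * 1e-6),
                          intensity = 0.011 * pool$C[det] * int,
                          formula = pool$hill[det], iso = TRUE)
        df <- rbind(df, sat)
      }
      df <- df[order(df$mz), ]
      peakLists[[sid]] <- PeakList(df$mz, df$intensity, sampleId = sid,
                                   condition = cond, depth = design@depth)
      truth[[sid]] <- data.frame(sample_id = sid, mz = df$mz,
                                 formula = df$formula,
                                 is_isotopologue = df$iso)
      meta[[sid]] <- data.frame(sample_id = sid, condition = cond,
                                depth = design@depth, replicate = r)
    }
  }
  list(peakLists = peakLists,
       groundTruth = do.call(rbind, c(unname(truth),
                                      list(make.row.names = FALSE))),
       metadata = do.call(rbind, c(unname(meta),
                                   list(make.row.names = FALSE))))
}

#' Write a synthetic dataset to disk
#'
#' Generates pools and peak lists for a design and writes one peak-list CSV
#' per sample (`mz`, `intensity`), a `metadata.csv` (`sample_id`,
#' `condition`, `depth`, `replicate`) and a `ground_truth.csv` (`sample_id`,
#' `mz`, `formula` in Hill order, `is_isotopologue`).
#'
#' @param design a [SyntheticDesign-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the list from [synthesizePeakLists()] plus `pools` and
#'   the written `paths`.
#' @export
writeSyntheticDataset <- function(design, dir) {
  pools <- generateFormulaPool(design)
  ds <- synthesizePeakLists(pools, design)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (pl in ds$peakLists) {
    f <- file.path(dir, paste0(sampleId(pl), ".csv"))
    utils::write.csv(peaks(pl), f, row.names = FALSE)
    paths <- c(paths, f)
  }
  utils::write.csv(ds$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(ds$groundTruth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(c(ds, list(pools = pools,
                       paths = c(paths, file.path(dir, "metadata.csv"),
                                 file.path(dir, "ground_truth.csv")))))
}
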