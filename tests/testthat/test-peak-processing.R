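test_that("m/z window filter keeps the closed interval and logs removals", {
  pl <- PeakList(c(150, 350, 950), c(1, 2, 3), "s1")
  f <- filterMzWindow(pl)
  expect_identical(peaks(f)$mz, 350)
  expect_identical(sort(removalLog(f)$mz), c(150, 950))
  expect_true(all(removalLog(f)$reason == "mz_window"))

  # boundaries are closed
  pl2 <- filterMzWindow(PeakList(c(200, 900), c(1, 1)))
  expect_identical(peaks(pl2)$mz, c(200, 900))

  # empty input passes through; empty output warns, not errors
  expect_identical(nrow(peaks(filterMzWindow(PeakList(numeric(),
                                                      numeric())))), 0L)
  expect_warning(filterMzWindow(PeakList(150, 1)), "no peaks")
})

test_that("isotopologue removal drops satellites with a more abundant parent", {
  sp <- isotopologueSpacing()
  pl <- PeakList(c(400, 400 + sp), c(100, 1.1), "s")
  out <- removeIsotopologues(pl)
  expect_identical(peaks(out)$mz, 400)
  expect_identical(removalLog(out)$reason, "isotopologue")

  # higher-mz peak more intense: it is not "less abundant", neither removed
  pl2 <- PeakList(c(400, 400 + sp), c(1.1, 100), "s")
  expect_identical(nrow(peaks(removeIsotopologues(pl2))), 2L)

  # single peak unchanged
  pl3 <- PeakList(400, 5, "s")
  expect_identical(peaks(removeIsotopologues(pl3)), peaks(pl3))

  # chain parent > sat1 > sat2: both satellites removed in one pass
  pl4 <- PeakList(c(400, 400 + sp, 400 + 2 * sp), c(100, 20, 3), "s")
  expect_identical(peaks(removeIsotopologues(pl4))$mz, 400)
})

test_that("isotopologue removal is idempotent on realistic synthetic lists", {
  d <- syntheticDesign(nCoreFormulas = 120L, nUniqueFormulas = 0L,
                       replicates = 1L, seed = 5L)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  for (pl in ds$peakLists) {
    once <- removeIsotopologues(pl)
    twice <- removeIsotopologues(once)
    expect_identical(peaks(twice), peaks(once))
  }
})

test_that("every input peak ends in exactly one accounting category", {
  d <- syntheticDesign(nCoreFormulas = 100L, nUniqueFormulas = 20L,
                       replicates = 2L, seed = 21L)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  pls <- lapply(ds$peakLists, function(pl)
    removeIsotopologues(filterMzWindow(pl)))
  nInput <- sum(vapply(ds$peakLists, function(p) nrow(peaks(p)), 0L))
  nKept <- sum(vapply(pls, function(p) nrow(peaks(p)), 0L))
  nRemoved <- sum(vapply(pls, function(p) nrow(removalLog(p)), 0L))
  expect_identical(nKept + nRemoved, nInput)

  apt <- alignPeaks(pls)
  nAligned <- sum(!is.na(SummarizedExperiment::assay(apt, "mz")))
  nUnresolved <- nrow(S4Vectors::metadata(apt)$unresolved)
  expect_identical(nAligned + nUnresolved, nKept)
})

test_that("recalibration recovers injected constant and linear drift", {
  d <- syntheticDesign(nCoreFormulas = 250L, nUniqueFormulas = 0L,
                       replicates = 1L, massErrorSdPpm = 0,
                       calibrationDriftPpm = 0.3, isotopologues = FALSE,
                       detectionProb = 1, seed = 8L)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  rec <- recalibrate(ds$peakLists[[1]])
  m <- rec$model
  expect_true(m@applied)
  expect_gte(m@nAnchors, 5L)
  expect_equal(m@a + m@b * 550, 0.3, tolerance = 0.05)
  expect_lt(m@rmsPpm, 0.05)

  # linear drift a + b*mz
  d2 <- syntheticDesign(nCoreFormulas = 250L, nUniqueFormulas = 0L,
                        replicates = 1L, massErrorSdPpm = 0,
                        calibrationDriftPpm = c(0.2, 4e-4),
                        isotopologues = FALSE, detectionProb = 1, seed = 8L)
  ds2 <- synthesizePeakLists(generateFormulaPool(d2), d2)
  rec2 <- recalibrate(ds2$peakLists[[1]])
  expect_equal(rec2$model@a, 0.2, tolerance = 0.05)
  expect_equal(rec2$model@b * 900, 4e-4 * 900, tolerance = 0.05)
  expect_lt(rec2$model@rmsPpm, 0.05)

  # corrected m/z within 0.05 ppm of truth across the mass range
  corr <- peaks(rec2$peakList)$mz
  pool <- generateFormulaPool(d2)[[condition(ds2$peakLists[[1]])]]
  trueIon <- sort(pool$mass - protonMass())
  expect_lt(max(abs((corr - trueIon) / trueIon * 1e6)), 0.05)
})

test_that("zero injected error yields a near-identity calibration", {
  d <- syntheticDesign(nCoreFormulas = 200L, nUniqueFormulas = 0L,
                       replicates = 1L, massErrorSdPpm = 0,
                       isotopologues = FALSE, detectionProb = 1, seed = 9L)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  rec <- recalibrate(ds$peakLists[[1]])
  expect_lt(abs(rec$model@a), 0.01)
  expect_lt(abs(rec$model@b * 900), 0.01)
})

test_that("too few anchors skips recalibration with a warning", {
  pl <- PeakList(c(300.1, 400.2, 500.3), c(1, 1, 1), "s")
  anchors <- data.frame(mz_obs = c(300.1, 400.2), mz_theo = c(300.1, 400.2))
  expect_warning(out <- recalibrate(pl, anchors = anchors), "anchors")
  expect_false(out$model@applied)
  expect_identical(peaks(out$peakList), peaks(pl))
})

test_that("alignment merges identical masses and splits distant ones", {
  mk <- function(mz, id) PeakList(mz, rep(1, length(mz)), id, "control")
  apt <- alignPeaks(list(mk(400.1234, "a"), mk(400.1234, "b"),
                         mk(400.1234, "c")))
  expect_identical(nrow(apt), 1L)
  expect_identical(SummarizedExperiment::rowData(apt)$n_samples, 3L)
  expect_equal(consensusMz(apt), 400.1234)

  # two peaks 2 ppm apart exceed the 0.5 ppm threshold
  apt2 <- alignPeaks(list(mk(400, "a"), mk(400 * (1 + 2e-6), "b")))
  expect_identical(nrow(apt2), 2L)
})

test_that("within-sample duplicates resolve to the more intense peak", {
  pl1 <- PeakList(c(400, 400 * (1 + 1e-7)), c(5, 50), "a", "control")
  pl2 <- PeakList(400, 7, "b", "control")
  apt <- alignPeaks(list(pl1, pl2))
  expect_identical(nrow(apt), 1L)
  mz <- SummarizedExperiment::assay(apt, "mz")
  int <- SummarizedExperiment::assay(apt, "intensity")
  expect_identical(unname(int[1, "a"]), 50)
  unres <- S4Vectors::metadata(apt)$unresolved
  expect_identical(nrow(unres), 1L)
  expect_identical(unres$intensity, 5)
})

test_that("alignment is invariant to sample order and matches the
           single-linkage oracle on separated clusters", {
  set.seed(31)
  centers <- sort(stats::runif(40, 250, 850))
  centers <- centers[c(TRUE, diff(centers) / centers[-1] * 1e6 > 2)]
  mkSample <- function(id) {
    # jitter each center by <= 0.2 ppm: within-cluster spread <= 0.4 ppm,
    # while distinct centers sit > 2 ppm apart
    mz <- centers * (1 + stats::runif(length(centers), -0.2, 0.2) * 1e-6)
    keep <- stats::runif(length(mz)) < 0.8
    PeakList(mz[keep], rep(1, sum(keep)), id, "control")
  }
  pls <- lapply(c("s1", "s2", "s3", "s4"), mkSample)
  apt <- alignPeaks(pls, tolPpm = 0.5)
  aptRev <- alignPeaks(rev(pls), tolPpm = 0.5)
  expect_equal(consensusMz(apt), consensusMz(aptRev))
  expect_identical(
    SummarizedExperiment::assay(apt, "mz")[, c("s1", "s2", "s3", "s4")],
    SummarizedExperiment::assay(aptRev, "mz")[, c("s1", "s2", "s3", "s4")])

  pooled <- sort(unlist(lapply(pls, function(p) peaks(p)$mz)))
  oracle <- oracleAlign(pooled, 0.5)
  production <- rep(seq_len(nrow(apt)),
                    SumEx <- rowSums(!is.na(
                      SummarizedExperiment::assay(apt, "mz"))))
  expect_identical(unname(production), unname(oracle))
})

test_that("a drifting ppm chain splits under the running-consensus rule", {
  # 0 / 0.3 / 0.6 / 0.9 ppm offsets: the 4th peak is 0.6 ppm from the
  # running mean of the first three, so the greedy rule (bounded cluster
  # spread) opens a new cluster even though single linkage would chain all 4
  mz <- 400 * (1 + c(0, 0.3, 0.6, 0.9) * 1e-6)
  pls <- lapply(1:4, function(i) PeakList(mz[i], 1, paste0("s", i)))
  apt <- alignPeaks(pls, tolPpm = 0.5)
  expect_identical(nrow(apt), 2L)
  expect_identical(SummarizedExperiment::rowData(apt)$n_samples, c(3L, 1L))
})
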