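test_that("design validation names the offending field", {
  expect_error(syntheticDesign(detectionProb = 0), "detectionProb")
  expect_error(syntheticDesign(massErrorSdPpm = -1), "massErrorSdPpm")
  expect_error(syntheticDesign(aromaticFraction = c(0.1, 0.2, 0.3, 1.2)),
               "aromaticFraction")
  expect_error(syntheticDesign(nCoreFormulas = 0), "nCoreFormulas")
  expect_error(syntheticDesign(replicates = 0), "replicates")
})

smallDesign <- function(...) {
  args <- utils::modifyList(list(nCoreFormulas = 80L, nUniqueFormulas = 30L,
                                 replicates = 2L, seed = 11L), list(...))
  do.call(syntheticDesign, args)
}

test_that("pools share the core and differ only in the unique strata", {
  d0 <- smallDesign(nUniqueFormulas = 0L)
  pools <- generateFormulaPool(d0)
  expect_identical(unname(lengths(lapply(pools, `[[`, "hill"))),
                   rep(80L, 4))
  for (p in pools[-1]) expect_identical(p$hill, pools[[1]]$hill)

  d1 <- smallDesign()
  pools1 <- generateFormulaPool(d1)
  core <- lapply(pools1, function(p) p$hill[p$stratum == "core"])
  uniq <- lapply(pools1, function(p) p$hill[p$stratum == "unique"])
  for (p in core[-1]) expect_identical(p, core[[1]])
  # unique strata pairwise disjoint and disjoint from the core
  all_uniq <- unlist(uniq)
  expect_false(anyDuplicated(all_uniq) > 0)
  expect_length(intersect(all_uniq, core[[1]]), 0)
})

test_that("pool formulas are valid, in-range, and stratified by AI", {
  pools <- generateFormulaPool(smallDesign(aromaticFraction = rep(0.3, 4)))
  for (p in pools) {
    expect_true(all(p$mass >= 201 & p$mass <= 899))
    expect_true(all(p$rdbe >= 0))
    expect_true(all((p$H + p$N + p$P) %% 2 == 0))
    expect_true(all(p$H / p$C >= 0.2 & p$H / p$C <= 3))
    expect_true(all(p$O / p$C <= 1.5))
    ai <- aromaticityIndex(p)
    expect_true(all(ai[p$aromatic] >= 0.5))
    expect_true(all(ai[!p$aromatic] < 0.5))
  }
})

test_that("aromatic-fraction contrast plants higher mean AI in high pools", {
  d <- smallDesign(aromaticFraction = c(control = 0.05, low = 0.05,
                                        moderate = 0.05, high = 0.40),
                   seed = 1L)
  pools <- generateFormulaPool(d)
  expect_gt(mean(aromaticityIndex(pools$high)),
            mean(aromaticityIndex(pools$control)))
})

test_that("raising one condition's aromatic fraction raises its pool mean AI", {
  fr <- c(0.05, 0.2, 0.4)
  means <- vapply(fr, function(f) {
    pools <- generateFormulaPool(
      smallDesign(aromaticFraction = c(0.05, 0.05, 0.05, f), seed = 3L))
    mean(aromaticityIndex(pools$high))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("identical seed and design give identical pools and peak lists", {
  d <- smallDesign()
  p1 <- generateFormulaPool(d); p2 <- generateFormulaPool(d)
  expect_identical(p1, p2)
  s1 <- synthesizePeakLists(p1, d); s2 <- synthesizePeakLists(p2, d)
  expect_identical(s1, s2)
  d2 <- smallDesign(seed = 99L)
  expect_false(identical(generateFormulaPool(d2), p1))
})

test_that("zero-noise m/z equals neutral mass minus the proton mass exactly", {
  d <- smallDesign(massErrorSdPpm = 0, calibrationDriftPpm = 0,
                   isotopologues = FALSE, detectionProb = 1)
  pools <- generateFormulaPool(d)
  ds <- synthesizePeakLists(pools, d)
  pl <- ds$peakLists[[1]]
  cond <- condition(pl)
  expected <- sort(pools[[cond]]$mass - protonMass())
  expect_identical(peaks(pl)$mz, expected)
})

test_that("injected constant drift is recovered exactly from ground truth", {
  d <- smallDesign(massErrorSdPpm = 0, calibrationDriftPpm = 0.3,
                   isotopologues = FALSE)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  gt <- ds$groundTruth
  trueIon <- parseFormula(gt$formula)$mass - protonMass()
  ppm <- (gt$mz - trueIon) / trueIon * 1e6
  expect_equal(ppm, rep(0.3, nrow(gt)), tolerance = 1e-9)
})

test_that("13C satellites follow the 0.011 * C intensity rule", {
  d <- smallDesign(massErrorSdPpm = 0, isotopologues = TRUE,
                   detectionProb = 1)
  pools <- generateFormulaPool(d)
  ds <- synthesizePeakLists(pools, d)
  gt <- ds$groundTruth
  s1 <- gt[gt$sample_id == gt$sample_id[1], ]
  pk <- peaks(ds$peakLists[[s1$sample_id[1]]])
  parents <- s1[!s1$is_isotopologue, ]
  sats <- s1[s1$is_isotopologue, ]
  expect_identical(nrow(sats), nrow(parents))
  i <- match(sats$formula, parents$formula)
  expect_equal(sats$mz - parents$mz[i],
               rep(isotopologueSpacing(), nrow(sats)), tolerance = 1e-9)
  pint <- pk$intensity[match(parents$mz[i], pk$mz)]
  sint <- pk$intensity[match(sats$mz, pk$mz)]
  Cn <- parseFormula(parents$formula[i])$C
  expect_equal(sint / pint, 0.011 * Cn, tolerance = 1e-9)
  # a C20 formula gives the 0.22 ratio of the single-13C leading term
  expect_equal(unique(round((sint / pint)[Cn == 20], 6)), 0.22)
})

test_that("ground truth covers every emitted peak exactly once", {
  d <- smallDesign()
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  for (pl in ds$peakLists) {
    gt <- ds$groundTruth[ds$groundTruth$sample_id == sampleId(pl), ]
    expect_identical(sort(gt$mz), peaks(pl)$mz)
    expect_identical(nrow(gt), nrow(peaks(pl)))
  }
  expect_true(is.logical(ds$groundTruth$is_isotopologue))
  expect_gt(sum(ds$groundTruth$is_isotopologue), 0)
})
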