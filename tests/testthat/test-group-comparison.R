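toyPresence <- function() {
  mat <- matrix(c(TRUE, TRUE, FALSE, FALSE,   # f1: control only
                  FALSE, FALSE, TRUE, TRUE,   # f2: low only
                  TRUE, FALSE, TRUE, FALSE,   # f3: control + low
                  FALSE, TRUE, TRUE, TRUE),   # f4: everywhere-ish
                nrow = 4, byrow = TRUE,
                dimnames = list(c("C6H6", "C10H8", "C7H8", "C6H12O6"),
                                c("a1", "a2", "b1", "b2")))
  samples <- data.frame(sample_id = c("a1", "a2", "b1", "b2"),
                        condition = c("control", "control", "low", "low"))
  suppressMessages(PresenceMatrix(mat, samples))
}

test_that("presence construction drops empty rows and matches metadata", {
  mat <- rbind(toy = c(TRUE, FALSE), dead = c(FALSE, FALSE))
  colnames(mat) <- c("s1", "s2")
  expect_message(
    pm <- PresenceMatrix(mat, data.frame(sample_id = c("s1", "s2"),
                                         condition = c("control", "high"))),
    "dropping 1")
  expect_identical(rownames(detected(pm)), "toy")
  expect_identical(pm@droppedFormulas, "dead")
})

test_that("presence from an assigned table equals ground-truth occupancy", {
  d <- syntheticDesign(nCoreFormulas = 100L, nUniqueFormulas = 20L,
                       replicates = 2L, massErrorSdPpm = 0,
                       detectionProb = 1, isotopologues = FALSE, seed = 17L)
  pools <- generateFormulaPool(d)
  ds <- synthesizePeakLists(pools, d)
  aft <- assignTable(alignPeaks(ds$peakLists))
  pm <- buildPresence(aft, ds$metadata)
  for (sid in ds$metadata$sample_id) {
    gtF <- sort(ds$groundTruth$formula[ds$groundTruth$sample_id == sid])
    gotF <- sort(rownames(detected(pm))[detected(pm)[, sid]])
    # at zero noise with detection 1, assignment recovers the occupancy
    # exactly wherever the formula was uniquely assignable; require >= 95%
    # agreement and no spurious detections
    expect_true(all(gotF %in% gtF))
    expect_gt(length(intersect(gotF, gtF)) / length(unique(gtF)), 0.95)
  }
})

test_that("unique-formula sets follow the group partition", {
  pm <- toyPresence()
  u <- uniqueFormulas(pm)
  expect_identical(u$control, "C6H6")
  expect_identical(u$low, "C10H8")

  # merging all conditions makes every formula unique to the single group
  uAll <- uniqueFormulas(pm, grouping = c(control = "all", low = "all"))
  expect_identical(sort(uAll$all), sort(rownames(detected(pm))))

  # sets are pairwise disjoint and never exceed the universe
  expect_length(intersect(u$control, u$low), 0)
  expect_lte(sum(lengths(u)), nrow(detected(pm)))

  # formula present in two different groups is unique nowhere
  mat <- matrix(c(TRUE, FALSE, FALSE, TRUE), nrow = 1,
                dimnames = list("C5H10O5", c("a1", "a2", "b1", "b2")))
  pm2 <- PresenceMatrix(mat, sampleInfo(pm))
  u2 <- uniqueFormulas(pm2)
  expect_length(unlist(u2), 0)

  expect_error(uniqueFormulas(pm, grouping = c(control = "x")), "cover")
})

test_that("identical groups give t = 0 and one-sided p = 0.5", {
  # control sample c1 mirrors high sample h1, c2 mirrors h2: the two
  # conditions have identical per-sample mean-AI vectors with nonzero spread
  mat <- matrix(c(TRUE,  TRUE,  FALSE, FALSE,
                  FALSE, FALSE, TRUE,  TRUE,
                  FALSE, FALSE, TRUE,  TRUE),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("C6H10", "C7H10", "C8H10"),
                                c("c1", "h1", "c2", "h2")))
  samples <- data.frame(sample_id = colnames(mat),
                        condition = c("control", "high", "control", "high"))
  pm <- PresenceMatrix(mat, samples)
  ai <- stats::setNames(c(0.1, 0.5, 0.3), rownames(mat))
  res <- compareAI(pm, ai, severityOrder = c("control", "high"))
  expect_equal(res$tests$t, 0)
  expect_equal(res$tests$p, 0.5)
})

test_that("Welch statistics agree with the hand-rolled oracle to 1e-6", {
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5) # fixture group A
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2) # fixture group B
  want <- oracleWelch(y, x, "greater")
  got <- pyroDOM:::.tTest(y, x, alternative = "greater")
  expect_equal(got$t, want$t, tolerance = 1e-6)
  expect_equal(got$df, want$df, tolerance = 1e-6)
  expect_equal(got$p, want$p, tolerance = 1e-6)
})

test_that("a planted aromaticity contrast is detected end to end", {
  d <- syntheticDesign(conditions = c("control", "high"),
                       replicates = 6L, nCoreFormulas = 150L,
                       nUniqueFormulas = 60L,
                       aromaticFraction = c(control = 0.05, high = 0.40),
                       seed = 7L)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  pls <- lapply(ds$peakLists, removeIsotopologues)
  aft <- annotateFormulas(assignTable(alignPeaks(pls)))
  pm <- buildPresence(aft, ds$metadata)
  rd <- SummarizedExperiment::rowData(aft)
  ok <- !is.na(rd$formula)
  ai <- stats::setNames(rd$ai_standard[ok], rd$formula[ok])
  ai <- ai[!duplicated(names(ai))]
  res <- compareAI(pm, ai, severityOrder = c("control", "high"))
  expect_lt(res$tests$p_adj, 0.05)
  expect_gt(res$tests$mean_higher, res$tests$mean_lower)
})

test_that("pairs with too few samples are skipped with a warning", {
  pm <- toyPresence()
  # drop one control sample -> 1 vs 2
  mat <- detected(pm)[, c("a1", "b1", "b2")]
  pm2 <- suppressMessages(
    PresenceMatrix(mat, sampleInfo(pm)[c(1, 3, 4), ]))
  ai <- stats::setNames(c(0.5, 0.2, 0.3, 0.1), rownames(detected(pm)))
  expect_warning(res <- compareAI(pm2, ai,
                                  severityOrder = c("control", "low")),
                 "skipping")
  expect_null(res$tests)
})

test_that("NOSC summaries report medians, histograms, and one-sided tests", {
  us <- list(control = c("C6H6", "C7H8"), high = c("C10H8", "C11H10"))
  noscV <- c(C6H6 = 0, C7H8 = 0.2, C10H8 = 1.0, C11H10 = 1.3)
  s <- summarizeNOSC(us, noscV, severityOrder = c("control", "high"))
  expect_equal(s$medians$median_nosc, c(0.1, 1.15))
  expect_gt(s$tests$median_diff, 0)
  want <- oracleWelch(c(1.0, 1.3), c(0, 0.2), "greater")
  expect_equal(s$tests$p, want$p, tolerance = 1e-9)
  expect_true(all(s$histogram$count >= 0))
  # histogram masses sum to group sizes
  agg <- tapply(s$histogram$count, s$histogram$group, sum)
  expect_identical(as.integer(agg[c("control", "high")]), c(2L, 2L))

  # degenerate zero-variance sets: medians still reported, p by convention
  us2 <- list(a = c("f1", "f2", "f3"), b = c("g1", "g2", "g3"))
  nv2 <- c(f1 = 0, f2 = 0, f3 = 0, g1 = 1, g2 = 1, g3 = 1)
  s2 <- summarizeNOSC(us2, nv2, severityOrder = c("a", "b"))
  expect_equal(s2$medians$median_nosc, c(0, 1))
  expect_equal(s2$tests$p, 0)     # all mass above, one-sided
  expect_equal(s2$tests$t, Inf)

  # identical sets: median difference 0, one-sided p = 0.5
  s3 <- summarizeNOSC(list(a = c("f1", "f2"), b = c("f1", "f2")),
                      c(f1 = 0, f2 = 1), severityOrder = c("a", "b"))
  expect_equal(s3$tests$median_diff, 0)
  expect_equal(s3$tests$p, 0.5)

  expect_warning(summarizeNOSC(list(a = "f1", b = character()),
                               c(f1 = 1), severityOrder = c("a", "b")),
                 "empty")
})

test_that("Holm adjustment is monotone and never below raw p", {
  d <- syntheticDesign(nCoreFormulas = 80L, nUniqueFormulas = 20L,
                       replicates = 3L, seed = 23L)
  ds <- synthesizePeakLists(generateFormulaPool(d), d)
  pls <- lapply(ds$peakLists, removeIsotopologues)
  aft <- annotateFormulas(assignTable(alignPeaks(pls)))
  pm <- buildPresence(aft, ds$metadata)
  rd <- SummarizedExperiment::rowData(aft)
  ok <- !is.na(rd$formula)
  ai <- stats::setNames(rd$ai_standard[ok], rd$formula[ok])
  ai <- ai[!duplicated(names(ai))]
  res <- compareAI(pm, ai)
  expect_true(all(res$tests$p_adj >= res$tests$p))
  o <- order(res$tests$p)
  expect_true(!is.unsorted(res$tests$p_adj[o]))
})
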