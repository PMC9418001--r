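#' Build a formula-by-sample presence matrix
#'
#' A formula is detected in a sample iff it was assigned to a cluster
#' containing a peak from that sample. Clusters sharing a formula (rare, but
#' possible after splitting) are merged by logical OR. Sample metadata is
#' taken from the table's `colData` unless supplied.
#'
#' @param aft an [AssignedFormulaTable-class].
#' @param metadata optional `data.frame` with `sample_id`, `condition`,
#'   `depth`.
#' @return A [PresenceMatrix-class].
#' @export
buildPresence <- function(aft, metadata = NULL) {
  stopifnot(is(aft, "AssignedFormulaTable"))
  rd <- rowData(aft)
  ok <- !is.na(rd$formula)
  if (!any(ok)) stop("buildPresence: no assigned formulas")
  pres <- !is.na(assay(aft, "mz"))[ok, , drop = FALSE]
  hill <- as.character(rd$formula[ok])
  agg <- rowsum(pres + 0L, hill) > 0
  if (is.null(metadata)) {
    metadata <- as.data.frame(colData(aft))
  }
  if (!all(colnames(agg) %in% metadata$sample_id))
    stop("buildPresence: sample ids missing from metadata")
  PresenceMatrix(agg, metadata)
}

#' Per-formula condition occupancy
#'
#' @param pm a [PresenceMatrix-class].
#' @return Named list: for each formula, the conditions in which it was
#'   detected in at least one replicate. Suitable as the `occupancy`
#'   argument of [filterSeriesByConditions()].
#' @export
formulaOccupancy <- function(pm) {
  stopifnot(is(pm, "PresenceMatrix"))
  conds <- pm@samples$condition
  lapply(seq_len(nrow(pm@mat)), function(i)
    sort(unique(conds[pm@mat[i, ]]))) |>
    stats::setNames(rownames(pm@mat))
}

#' Formulas unique to each condition group
#'
#' Under a grouping of conditions into labels, a formula is unique to group
#' g iff it is detected in at least one sample of g and in no sample of any
#' other group. The resulting sets are pairwise disjoint by construction.
#'
#' @param pm a [PresenceMatrix-class].
#' @param grouping named character vector mapping every condition present in
#'   the data to a group label (default: each condition is its own group).
#' @return Named list of character vectors (Hill formulas) per group.
#' @examples
#' \dontrun{
#' uniqueFormulas(pm, grouping = c(control = "unburned", low = "low",
#'                                 moderate = "mod+high", high = "mod+high"))
#' }
#' @export
uniqueFormulas <- function(pm, grouping = NULL) {
  stopifnot(is(pm, "PresenceMatrix"))
  conds <- pm@samples$condition
  if (is.null(grouping)) {
    grouping <- stats::setNames(unique(conds), unique(conds))
  }
  if (!all(conds %in% names(grouping)))
    stop("uniqueFormulas: grouping must cover every condition present")
  sampleGroup <- unname(grouping[conds])
  groups <- unique(grouping[order(match(names(grouping), conds))])
  inGroup <- matrix(
    vapply(groups, function(g)
      rowSums(pm@mat[, sampleGroup == g, drop = FALSE]) > 0,
      logical(nrow(pm@mat))),
    nrow = nrow(pm@mat), dimnames = list(NULL, groups))
  nGroups <- rowSums(inGroup)
  out <- lapply(groups, function(g)
    rownames(pm@mat)[inGroup[, g] & nGroups == 1])
  stats::setNames(out, groups)
}

# Welch (or pooled) t-test with a documented degenerate-variance convention:
# when the standard error is zero, t is 0 or +/-Inf by the sign of the mean
# difference and the p-value follows (one-sided p in {0, 0.5, 1}).
.tTest <- function(x, y, alternative = "greater", pooled = FALSE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    d <- mean(x) - mean(y)
    t <- if (d == 0) 0 else Inf * sign(d)
    p <- switch(alternative,
                greater = if (d > 0) 0 else if (d < 0) 1 else 0.5,
                less = if (d < 0) 0 else if (d > 0) 1 else 0.5,
                two.sided = if (d == 0) 1 else 0)
    return(list(t = t, df = NA_real_, p = p))
  }
  ht <- stats::t.test(x, y, alternative = alternative,
                      var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

.severityPairs <- function(conds, severityOrder) {
  ord <- intersect(severityOrder, conds)
  extra <- setdiff(conds, severityOrder)
  ord <- c(ord, extra)
  if (length(ord) < 2) stop("need at least two conditions to compare")
  do.call(rbind, lapply(utils::combn(length(ord), 2, simplify = FALSE),
                        function(ij) data.frame(lower = ord[ij[1]],
                                                higher = ord[ij[2]])))
}

#' Pairwise one-sided comparison of per-sample aromaticity
#'
#' Summarizes each sample by its (unweighted, or intensity-weighted) mean
#' aromaticity index over detected formulas, then tests each condition pair
#' with a one-sided Welch two-sample t-test in the direction implied by the
#' severity ordering (higher severity expected more aromatic), adjusting
#' across pairs with Holm's method.
#'
#' @param pm a [PresenceMatrix-class].
#' @param ai named numeric vector of per-formula AI values (names = Hill
#'   strings covering the presence matrix rows).
#' @param pairs optional `data.frame(lower, higher)` of condition pairs;
#'   default all pairs under `severityOrder`.
#' @param severityOrder condition labels from least to most severe.
#' @param weights optional intensity matrix (same dimnames as the presence
#'   matrix) for intensity-weighted per-sample means.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return `list(perSample=, tests=)`: per-sample mean AI with metadata, and
#'   per-pair `t`, `df`, `p`, `p_adj`, sample sizes. Pairs where either
#'   condition has fewer than 2 samples are skipped with a warning.
#' @export
compareAI <- function(pm, ai, pairs = NULL,
                      severityOrder = c("control", "low", "moderate", "high"),
                      weights = NULL, pooled = FALSE) {
  stopifnot(is(pm, "PresenceMatrix"))
  miss <- setdiff(rownames(pm@mat), names(ai))
  if (length(miss))
    stop("compareAI: AI values missing for ", length(miss), " formula(s)")
  ai <- ai[rownames(pm@mat)]
  stat <- vapply(seq_len(ncol(pm@mat)), function(j) {
    f <- pm@mat[, j]
    if (!any(f)) return(NA_real_)
    if (is.null(weights)) mean(ai[f])
    else stats::weighted.mean(ai[f], weights[rownames(pm@mat), j][f])
  }, 0)
  perSample <- cbind(pm@samples, mean_ai = stat)
  if (is.null(pairs))
    pairs <- .severityPairs(unique(pm@samples$condition), severityOrder)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    lo <- pairs$lower[k]; hi <- pairs$higher[k]
    x <- stat[pm@samples$condition == hi]
    y <- stat[pm@samples$condition == lo]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) {
      warning("compareAI: skipping ", lo, " vs ", hi,
              " (need >= 2 samples per condition)")
      next
    }
    tt <- .tTest(x, y, alternative = "greater", pooled = pooled)
    rows[[length(rows) + 1L]] <- data.frame(
      lower = lo, higher = hi, n_lower = length(y), n_higher = length(x),
      mean_lower = mean(y), mean_higher = mean(x),
      t = tt$t, df = tt$df, p = tt$p)
  }
  tests <- do.call(rbind, rows)
  if (!is.null(tests)) tests$p_adj <- stats::p.adjust(tests$p, "holm")
  list(perSample = perSample, tests = tests)
}

#' NOSC summary of unique-formula sets
#'
#' For each group's unique formulas: the median NOSC, a fixed-break
#' histogram export (for density-style plotting without a kernel), and
#' pairwise one-sided Welch t-tests on the NOSC values (higher severity
#' expected higher NOSC, i.e. thermodynamically more favourable oxidation),
#' Holm-adjusted.
#'
#' @param uniqueSets named list of formula sets from [uniqueFormulas()].
#' @param noscValues named numeric vector of per-formula NOSC values.
#' @param pairs optional `data.frame(lower, higher)` of group pairs.
#' @param severityOrder group labels from least to most severe.
#' @param binWidth histogram bin width (NOSC units).
#' @return `list(medians=, histogram=, tests=)`. Groups with empty unique
#'   sets are excluded with a warning.
#' @export
summarizeNOSC <- function(uniqueSets, noscValues, pairs = NULL,
                          severityOrder = c("control", "low", "moderate",
                                            "high"),
                          binWidth = 0.25) {
  empty <- names(uniqueSets)[lengths(uniqueSets) == 0]
  if (length(empty)) {
    warning("summarizeNOSC: excluding group(s) with empty unique sets: ",
            paste(empty, collapse = ", "))
    uniqueSets <- uniqueSets[lengths(uniqueSets) > 0]
  }
  if (length(uniqueSets) < 1) stop("summarizeNOSC: no non-empty groups")
  vals <- lapply(uniqueSets, function(fs) {
    miss <- setdiff(fs, names(noscValues))
    if (length(miss)) stop("summarizeNOSC: NOSC missing for ",
                           length(miss), " formula(s)")
    unname(noscValues[fs])
  })
  medians <- data.frame(group = names(vals),
                        n = lengths(vals),
                        median_nosc = vapply(vals, stats::median, 0))
  rng <- range(unlist(vals))
  breaks <- seq(floor(rng[1] / binWidth) * binWidth,
                ceiling(rng[2] / binWidth) * binWidth + binWidth / 2,
                by = binWidth)
  histogram <- do.call(rbind, lapply(names(vals), function(g) {
    h <- graphics::hist(vals[[g]], breaks = breaks, plot = FALSE)
    data.frame(group = g, mid = h$mids, count = h$counts,
               density = h$density)
  }))
  tests <- NULL
  if (length(vals) >= 2) {
    if (is.null(pairs))
      pairs <- .severityPairs(names(vals), severityOrder)
    rows <- list()
    for (k in seq_len(nrow(pairs))) {
      lo <- pairs$lower[k]; hi <- pairs$higher[k]
      if (!lo %in% names(vals) || !hi %in% names(vals)) next
      tt <- .tTest(vals[[hi]], vals[[lo]], alternative = "greater")
      rows[[length(rows) + 1L]] <- data.frame(
        lower = lo, higher = hi,
        median_lower = stats::median(vals[[lo]]),
        median_higher = stats::median(vals[[hi]]),
        median_diff = stats::median(vals[[hi]]) - stats::median(vals[[lo]]),
        t = tt$t, df = tt$df, p = tt$p)
    }
    tests <- do.call(rbind, rows)
    if (!is.null(tests)) tests$p_adj <- stats::p.adjust(tests$p, "holm")
  }
  list(medians = medians, histogram = histogram, tests = tests)
}
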