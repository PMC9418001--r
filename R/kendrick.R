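#' Kendrick mass defect configuration (C4H2 base unit)
#'
#' The C4H2 repeat unit (nominal mass 50 amu) rescales masses so that adding
#' one unit — the growth step of condensed polyaromatics — advances the
#' nominal Kendrick mass (NKM) by exactly 50 while leaving the Kendrick mass
#' defect (KMD) unchanged. `baseExact` defaults to the monoisotopic mass of
#' C4H2 (50.01565006 Da); the alternative `"printed"` value 50.0587 is
#' retained because it appears in print in some KMD applications.
#'
#' `nkmFrom` selects the NKM convention: `"mass"` rounds the input mass M
#' (half away from zero) as some applications define it, while `"kendrick"`
#' rounds the Kendrick mass itself (the classic convention, under which KMD
#' is exactly invariant along a homologous series).
#'
#' @param baseNominal nominal base-unit mass (amu), default 50.
#' @param baseExact exact base-unit mass in Da, or the string
#'   `"chemical"` (50.01565006) or `"printed"` (50.0587).
#' @param kmdTolerance KMD grouping tolerance (dimensionless), default
#'   0.001; measured masses never give exactly equal KMDs.
#' @param step NKM spacing between series members, default 50.
#' @param nkmFrom `"mass"` or `"kendrick"` (see Details).
#' @param requireConditions conditions a series must span to be retained by
#'   [filterSeriesByConditions()].
#' @return A list of class `kendrickConfig`.
#' @export
kendrickConfig <- function(baseNominal = 50,
                           baseExact = c("chemical", "printed"),
                           kmdTolerance = 0.001,
                           step = 50L,
                           nkmFrom = c("mass", "kendrick"),
                           requireConditions = c("control", "low",
                                                 "moderate", "high")) {
  if (is.character(baseExact)) {
    baseExact <- switch(match.arg(baseExact),
                        chemical = .MASS_C4H2,
                        printed = .MASS_C4H2_PRINTED)
  }
  stopifnot(baseExact > 0, kmdTolerance >= 0, baseNominal > 0, step >= 1)
  structure(list(baseNominal = baseNominal, baseExact = baseExact,
                 kmdTolerance = kmdTolerance, step = as.integer(step),
                 nkmFrom = match.arg(nkmFrom),
                 requireConditions = requireConditions),
            class = "kendrickConfig")
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Kendrick transform of masses
#'
#' Computes, per mass M: the Kendrick mass
#' `KM = M * baseNominal / baseExact`, the nominal Kendrick mass `NKM`
#' (rounded half away from zero, from M or KM per the config), and the
#' Kendrick mass defect `KMD = NKM - KM`.
#'
#' @param masses positive masses (ion m/z or neutral, caller's choice; ion
#'   masses are the convention for instrument data).
#' @param cfg a [kendrickConfig()].
#' @param formulas optional character vector of formula labels carried
#'   through to the output.
#' @return `data.frame` with columns `mass`, `km`, `nkm`, `kmd` (and
#'   `formula` if given).
#' @examples
#' kendrickTransform(c(78.04695, 128.06260))
#' @export
kendrickTransform <- function(masses, cfg = kendrickConfig(),
                              formulas = NULL) {
  stopifnot(inherits(cfg, "kendrickConfig"))
  if (any(masses <= 0)) stop("kendrickTransform: masses must be positive")
  km <- masses * cfg$baseNominal / cfg$baseExact
  nkm <- if (cfg$nkmFrom == "mass") .roundHalfAway(masses)
         else .roundHalfAway(km)
  out <- data.frame(mass = masses, km = km, nkm = as.integer(nkm),
                    kmd = nkm - km)
  if (!is.null(formulas)) out$formula <- formulas
  out
}

#' Detect Kendrick homologous series
#'
#' Groups records with matching KMD into homologous series: records are
#' partitioned by NKM residue class modulo `step` (members of a C4H2 series
#' must differ by whole base units), then chained on sorted KMD with an
#' adjacent-gap threshold of `kmdTolerance` — within a residue class this
#' equals single-linkage transitive closure of the pairwise
#' \eqn{|KMD_i - KMD_j| \le tol} relation. Groups with at least 2 members
#' are emitted, ordered by mean KMD then smallest NKM.
#'
#' @param records a [kendrickTransform()] table (optionally with `formula`).
#' @param cfg a [kendrickConfig()].
#' @return `data.frame` with one row per series: `series_id`, `kmd_key`
#'   (mean member KMD), `n_members`, `nkms` and `formulas`
#'   (";"-separated), plus list-columns `member_nkm`, `member_formula`,
#'   `member_idx` (row indices into `records`).
#' @export
detectSeries <- function(records, cfg = kendrickConfig()) {
  stopifnot(inherits(cfg, "kendrickConfig"), nrow(records) >= 1)
  if (is.null(records$formula)) records$formula <- NA_character_
  records$.idx <- seq_len(nrow(records))
  groups <- list()
  for (res in sort(unique(records$nkm %% cfg$step))) {
    sub <- records[records$nkm %% cfg$step == res, , drop = FALSE]
    sub <- sub[order(sub$kmd, sub$nkm), , drop = FALSE]
    brk <- c(0, which(diff(sub$kmd) > cfg$kmdTolerance), nrow(sub))
    for (g in seq_len(length(brk) - 1)) {
      idx <- (brk[g] + 1):brk[g + 1]
      if (length(idx) < 2) next
      groups[[length(groups) + 1L]] <- sub[idx, , drop = FALSE]
    }
  }
  if (!length(groups)) {
    return(data.frame(series_id = character(), kmd_key = numeric(),
                      n_members = integer(), nkms = character(),
                      formulas = character()))
  }
  keys <- vapply(groups, function(g) mean(g$kmd), 0)
  minNkm <- vapply(groups, function(g) min(g$nkm), 0L)
  o <- order(keys, minNkm)
  groups <- groups[o]
  out <- data.frame(
    series_id = sprintf("S%04d", seq_along(groups)),
    kmd_key = keys[o],
    n_members = vapply(groups, nrow, 0L),
    nkms = vapply(groups, function(g)
      paste(sort(g$nkm), collapse = ";"), ""),
    formulas = vapply(groups, function(g)
      paste(g$formula[order(g$nkm)], collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out$member_nkm <- lapply(groups, function(g) sort(g$nkm))
  out$member_formula <- lapply(groups, function(g) g$formula[order(g$nkm)])
  out$member_idx <- lapply(groups, function(g) g$.idx[order(g$nkm)])
  out
}

#' Retain series present across required conditions
#'
#' A series is "present" in a condition when any of its member formulas was
#' detected in at least one replicate of that condition (presence by union
#' of member occupancies). Series whose united condition set covers
#' `cfg$requireConditions` are retained; with an empty requirement the
#' filter is vacuous.
#'
#' @param series output of [detectSeries()] (needs `member_formula`).
#' @param occupancy named list mapping formula (Hill string) to the
#'   character vector of conditions it was detected in.
#' @param cfg a [kendrickConfig()].
#' @return `series` with columns `conditions_present` (";"-separated) and
#'   logical `retained`, filtered to retained rows; the full annotated table
#'   is attached as `attr(, "all")`.
#' @export
filterSeriesByConditions <- function(series, occupancy,
                                     cfg = kendrickConfig()) {
  stopifnot(is.list(occupancy))
  condSets <- lapply(series$member_formula, function(fs) {
    fs <- fs[!is.na(fs)]
    miss <- setdiff(fs, names(occupancy))
    if (length(miss))
      stop("filterSeriesByConditions: occupancy missing for ",
           paste(miss, collapse = ", "))
    sort(unique(unlist(occupancy[fs])))
  })
  series$conditions_present <- vapply(condSets, paste, "", collapse = ";")
  series$retained <- vapply(condSets, function(cs)
    all(cfg$requireConditions %in% cs), TRUE)
  out <- series[series$retained, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all") <- series
  out
}
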