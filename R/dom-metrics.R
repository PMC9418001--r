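.counts <- function(f) {
  if (is.data.frame(f)) {
    stopifnot(all(c("C", "H") %in% names(f)))
    for (el in c("N", "O", "S", "P")) if (is.null(f[[el]])) f[[el]] <- 0L
    f
  } else if (is.character(f)) {
    parseFormula(f)
  } else {
    stop("expected a formula data.frame or Hill strings")
  }
}

#' Nominal oxidation state of carbon
#'
#' The `standard` variant is the LaRowe-Van Briesen form
#' \deqn{NOSC = 4 - (4C + H - 3N - 2O + 5P - 2S - Z)/C}
#' with charge `Z = 0` for neutral formulas. The `as_printed` variant
#' reproduces a typography sometimes seen in print,
#' \eqn{4 - (5C + H - 3N - 2O - 2S)/C}; for P-free neutral formulas it equals
#' the standard value minus 1 exactly. Both are first-class so results can be
#' reported under either convention.
#'
#' @param f a formula `data.frame` ([formulaTable()]) or Hill strings.
#' @param variant `"standard"` or `"as_printed"`.
#' @param z formal charge (standard variant only; default 0).
#' @return Numeric vector of NOSC values (dimensionless).
#' @examples
#' nosc(formulaTable(C = 1, H = 4))        # methane: -4
#' nosc(formulaTable(C = 1, H = 0, O = 2)) # CO2: +4
#' nosc("C6H12O6")                         # glucose: 0
#' @export
nosc <- function(f, variant = c("standard", "as_printed"), z = 0) {
  variant <- match.arg(variant)
  f <- .counts(f)
  if (any(f$C < 1)) stop("nosc: C must be >= 1")
  if (variant == "standard") {
    4 - (4 * f$C + f$H - 3 * f$N - 2 * f$O + 5 * f$P - 2 * f$S - z) / f$C
  } else {
    4 - (5 * f$C + f$H - 3 * f$N - 2 * f$O - 2 * f$S) / f$C
  }
}

#' Aromaticity index
#'
#' The `standard` variant is the Koch-Dittmar aromaticity index
#' \deqn{AI = (1 + C - O - S - 0.5H) / (C - O - S - N - P)}
#' and `modified` (AImod) discounts half the oxygen in both numerator and
#' denominator (carboxyl-corrected). In both, a non-positive numerator or
#' denominator returns 0 (the conventional floor: such formulas carry no
#' aromaticity evidence). The `as_printed` variant reproduces a printed
#' typography `4 - AI_raw` without flooring, and is provided only for
#' comparison with documents using that form.
#'
#' @param f a formula `data.frame` or Hill strings.
#' @param variant `"standard"`, `"modified"`, or `"as_printed"`.
#' @return Numeric vector of AI values; values >= ~0.67 conventionally
#'   indicate condensed aromatic structures.
#' @examples
#' aromaticityIndex("C6H6")   # benzene: 2/3
#' aromaticityIndex("C6H14")  # hexane: 0 (floored)
#' @export
aromaticityIndex <- function(f, variant = c("standard", "modified",
                                            "as_printed")) {
  variant <- match.arg(variant)
  f <- .counts(f)
  if (any(f$C < 1)) stop("aromaticityIndex: C must be >= 1")
  o <- if (variant == "modified") 0.5 * f$O else f$O
  num <- 1 + f$C - o - f$S - 0.5 * f$H
  den <- f$C - o - f$S - f$N - f$P
  if (variant == "as_printed") return(4 - num / den)
  ifelse(num <= 0 | den <= 0, 0, num / den)
}

#' Default Van Krevelen class boundary table
#'
#' Reads the rectangular H/C x O/C compound-class boundaries shipped with the
#' package (`inst/extdata/vk_class_boundaries.csv`). Boundaries are
#' configuration data: edit a copy and pass it to [vkClass()] to use a
#' different convention. Rectangles are half-open (`min <= x < max`) and
#' mutually non-overlapping; points matching no rectangle are `other`.
#'
#' @param path optional path to an alternative boundary CSV with columns
#'   `class`, `hc_min`, `hc_max`, `oc_min`, `oc_max`.
#' @return A `data.frame` of class rectangles.
#' @export
vkBoundaries <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "vk_class_boundaries.csv",
                        package = "pyroDOM", mustWork = TRUE)
  }
  b <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("class", "hc_min", "hc_max", "oc_min", "oc_max") %in%
                  names(b)))
  b
}

#' Van Krevelen compound class of a formula
#'
#' Assigns each (H/C, O/C) point to the first matching half-open rectangle of
#' the boundary table, or `"other"`.
#'
#' @param hc,oc numeric vectors of H/C and O/C atomic ratios, or `hc` may be
#'   a formula `data.frame`/Hill strings (then `oc` is ignored).
#' @param boundaries boundary table from [vkBoundaries()].
#' @return Character vector of class labels.
#' @examples
#' vkClass(1.9, 0.05) # lipid
#' vkClass(0.5, 0.10) # condensed_aromatic
#' @export
vkClass <- function(hc, oc = NULL, boundaries = vkBoundaries()) {
  if (is.data.frame(hc) || is.character(hc)) {
    f <- .counts(hc)
    oc <- f$O / f$C
    hc <- f$H / f$C
  }
  out <- rep("other", length(hc))
  # first match wins; the default table is non-overlapping so order is moot
  for (i in rev(seq_len(nrow(boundaries)))) {
    hit <- hc >= boundaries$hc_min[i] & hc < boundaries$hc_max[i] &
      oc >= boundaries$oc_min[i] & oc < boundaries$oc_max[i]
    out[hit] <- boundaries$class[i]
  }
  out
}

#' Per-formula descriptor table
#'
#' Computes H/C, O/C, both NOSC variants, standard and modified AI, and the
#' Van Krevelen class for a set of formulas.
#'
#' @param f a formula `data.frame` or Hill strings.
#' @param boundaries Van Krevelen boundary table.
#' @return `data.frame` with columns `formula, mass, hc, oc, nosc_standard,
#'   nosc_as_printed, ai_standard, ai_modified, vk_class`.
#' @examples
#' formulaMetrics("C6H12O6")
#' @export
formulaMetrics <- function(f, boundaries = vkBoundaries()) {
  f <- .counts(f)
  hc <- f$H / f$C
  oc <- f$O / f$C
  data.frame(
    formula = if (!is.null(f$hill)) f$hill else
      hillString(f$C, f$H, f$N, f$O, f$S, f$P),
    mass = if (!is.null(f$mass)) f$mass else
      formulaMass(f$C, f$H, f$N, f$O, f$S, f$P),
    hc = hc, oc = oc,
    nosc_standard = nosc(f, "standard"),
    nosc_as_printed = nosc(f, "as_printed"),
    ai_standard = aromaticityIndex(f, "standard"),
    ai_modified = aromaticityIndex(f, "modified"),
    vk_class = vkClass(hc, oc, boundaries),
    stringsAsFactors = FALSE
  )
}

#' Annotate an assigned table with molecular descriptors
#'
#' Joins [formulaMetrics()] onto the `rowData` of an
#' [AssignedFormulaTable-class]. Unassigned clusters are carried through with
#' NA metrics.
#'
#' @param aft an [AssignedFormulaTable-class].
#' @param boundaries Van Krevelen boundary table.
#' @return The input table with metric columns appended to its `rowData`.
#' @export
annotateFormulas <- function(aft, boundaries = vkBoundaries()) {
  stopifnot(is(aft, "AssignedFormulaTable"))
  rd <- rowData(aft)
  if (!any(!is.na(rd$formula))) stop("annotateFormulas: no assigned rows")
  met <- data.frame(hc = NA_real_, oc = NA_real_, nosc_standard = NA_real_,
                    nosc_as_printed = NA_real_, ai_standard = NA_real_,
                    ai_modified = NA_real_, vk_class = NA_character_)[
                      rep(1, nrow(rd)), , drop = FALSE]
  ok <- !is.na(rd$formula)
  f <- data.frame(C = rd$C[ok], H = rd$H[ok], N = rd$N[ok],
                  O = rd$O[ok], S = rd$S[ok], P = rd$P[ok])
  m <- formulaMetrics(f, boundaries)
  met[ok, ] <- m[, c("hc", "oc", "nosc_standard", "nosc_as_printed",
                     "ai_standard", "ai_modified", "vk_class")]
  rowData(aft) <- cbind(rd, S4Vectors::DataFrame(met))
  aft
}
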