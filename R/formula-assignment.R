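#' Neutral mass of a singly charged deprotonated ion
#'
#' Converts an observed m/z to the neutral monoisotopic mass under the
#' \eqn{[M-H]^-} convention: `mass = mz + 1.00727646`. Only `z = -1` (the
#' negative-mode, singly charged case) is supported.
#'
#' @param mz observed m/z (Th).
#' @param z charge; must be -1.
#' @return Neutral mass in Da.
#' @examples
#' neutralMass(179.056105) # glucose [M-H]-: ~180.06338
#' @export
neutralMass <- function(mz, z = -1L) {
  if (!identical(as.integer(z), -1L)) {
    stop("neutralMass: only z = -1 ([M-H]-, negative mode, singly charged) ",
         "is supported")
  }
  mz + .PROTON_MASS
}

#' Configuration for CHONSP formula assignment
#'
#' Element bounds and chemical-validity rules for the bounded exhaustive
#' enumeration. Defaults are conventional DOM assignment windows: C 1-100,
#' H 1-200, O 0-60, N 0-5, S 0-2, P 0-2, H/C in [0.2, 3], O/C in [0, 1.5],
#' ring-and-double-bond equivalents >= 0, and integer-RDBE parity (H+N+P
#' even, as required of neutral even-electron molecules).
#'
#' @param tolPpm assignment tolerance; candidates must satisfy
#'   `|error_ppm| < tolPpm` (strict).
#' @param bounds named list of `c(min, max)` per element.
#' @param hcRange,ocRange closed H/C and O/C validity intervals.
#' @param requireParity require integer RDBE (H+N+P even).
#' @return A list of class `assignmentConfig`.
#' @export
assignmentConfig <- function(tolPpm = 0.5,
                             bounds = list(C = c(1L, 100L), H = c(1L, 200L),
                                           N = c(0L, 5L), O = c(0L, 60L),
                                           S = c(0L, 2L), P = c(0L, 2L)),
                             hcRange = c(0.2, 3.0),
                             ocRange = c(0, 1.5),
                             requireParity = TRUE) {
  stopifnot(tolPpm > 0)
  for (el in c("C", "H", "N", "O", "S", "P")) {
    b <- bounds[[el]]
    if (is.null(b) || length(b) != 2 || b[1] > b[2])
      stop("assignmentConfig: bounds for ", el, " must be c(min, max)")
  }
  structure(list(tolPpm = tolPpm, bounds = bounds, hcRange = hcRange,
                 ocRange = ocRange, requireParity = requireParity),
            class = "assignmentConfig")
}

#' Enumerate candidate formulas for a neutral mass
#'
#' Exhaustively enumerates every CHONSP formula inside the configured element
#' bounds whose computed mass lies strictly within `tolPpm` of `mass` and
#' which passes the validity rules (H/C, O/C, RDBE, parity). Candidates are
#' returned sorted by `|error_ppm|`, ties broken by fewer heteroatoms
#' (N+S+P), then Hill string, making the ranking fully deterministic.
#'
#' @param mass neutral monoisotopic mass (Da).
#' @param cfg an [assignmentConfig()].
#' @param tolPpm optional override of `cfg$tolPpm`.
#' @return `data.frame` with [formulaTable()] columns plus `error_ppm` and
#'   `n_het`; zero rows when nothing matches.
#' @examples
#' enumerateCandidates(180.063388)[1, c("hill", "error_ppm")]
#' @export
enumerateCandidates <- function(mass, cfg = assignmentConfig(),
                                tolPpm = NULL) {
  stopifnot(inherits(cfg, "assignmentConfig"), mass > 0)
  tol <- if (is.null(tolPpm)) cfg$tolPpm else tolPpm
  b <- cfg$bounds
  raw <- enumerateCandidatesCpp(
    mass, tol,
    b$C[1], b$C[2], b$H[1], b$H[2], b$N[1], b$N[2], b$O[1], b$O[2],
    b$S[1], b$S[2], b$P[1], b$P[2],
    cfg$hcRange[1], cfg$hcRange[2], cfg$ocRange[1], cfg$ocRange[2],
    cfg$requireParity)
  if (!nrow(raw)) {
    out <- formulaTable(C = 1L, H = 2L)[0, ]
    out$error_ppm <- numeric()
    out$n_het <- integer()
    return(out)
  }
  ft <- formulaTable(C = raw$C, H = raw$H, N = raw$N, O = raw$O,
                     S = raw$S, P = raw$P)
  ft$error_ppm <- raw$error_ppm
  ft$n_het <- raw$N + raw$S + raw$P
  ft <- ft[order(abs(ft$error_ppm), ft$n_het, ft$hill), ]
  rownames(ft) <- NULL
  ft
}

#' Assign formulas to an aligned peak table
#'
#' Converts each cluster's consensus m/z to a neutral mass, enumerates
#' candidates, and records the top-ranked formula. A cluster is left
#' unassigned with reason `no_candidate` when nothing matches; in strict
#' mode, clusters whose top two candidates differ by less than
#' `ambiguityPpm` are left unassigned with reason `ambiguous_if_strict`.
#'
#' @param apt an [AlignedPeakTable-class].
#' @param cfg an [assignmentConfig()].
#' @param strict reject near-degenerate top candidates.
#' @param ambiguityPpm strict-mode separation threshold (ppm).
#' @return An [AssignedFormulaTable-class].
#' @export
assignTable <- function(apt, cfg = assignmentConfig(), strict = FALSE,
                        ambiguityPpm = 0.05) {
  stopifnot(is(apt, "AlignedPeakTable"), nrow(apt) >= 1)
  mz <- consensusMz(apt)
  nm <- neutralMass(mz)
  n <- length(nm)
  res <- data.frame(
    neutral_mass = nm, formula = NA_character_,
    C = NA_integer_, H = NA_integer_, N = NA_integer_, O = NA_integer_,
    S = NA_integer_, P = NA_integer_,
    error_ppm = NA_real_, n_candidates = 0L, reason = "no_candidate")
  for (i in seq_len(n)) {
    cand <- enumerateCandidates(nm[i], cfg)
    res$n_candidates[i] <- nrow(cand)
    if (!nrow(cand)) next
    if (strict && nrow(cand) >= 2 &&
        abs(abs(cand$error_ppm[1]) - abs(cand$error_ppm[2])) < ambiguityPpm) {
      res$reason[i] <- "ambiguous_if_strict"
      next
    }
    res$formula[i] <- cand$hill[1]
    res[i, c("C", "H", "N", "O", "S", "P")] <-
      cand[1, c("C", "H", "N", "O", "S", "P")]
    res$error_ppm[i] <- cand$error_ppm[1]
    res$reason[i] <- "assigned"
  }
  rowData(apt) <- cbind(rowData(apt), S4Vectors::DataFrame(res))
  new("AssignedFormulaTable", apt)
}
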