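#' Construct a table of CHONSP molecular formulas
#'
#' The package represents molecular formulas as a plain `data.frame` with one
#' row per formula and integer columns `C`, `H`, `N`, `O`, `S`, `P`, plus the
#' derived monoisotopic neutral `mass` (Da), the canonical Hill-notation
#' string `hill`, and the ring-and-double-bond equivalents `rdbe`
#' (\eqn{C - H/2 + N/2 + P/2 + 1}).
#'
#' @param C,H,N,O,S,P integer vectors of element counts (recycled to a common
#'   length). `C >= 1` and all counts non-negative.
#' @return A `data.frame` with columns `C,H,N,O,S,P,mass,hill,rdbe`.
#' @examples
#' formulaTable(C = 6, H = 12, O = 6)
#' @export
formulaTable <- function(C, H, N = 0L, O = 0L, S = 0L, P = 0L) {
  n <- max(length(C), length(H), length(N), length(O), length(S), length(P))
  C <- as.integer(rep_len(C, n)); H <- as.integer(rep_len(H, n))
  N <- as.integer(rep_len(N, n)); O <- as.integer(rep_len(O, n))
  S <- as.integer(rep_len(S, n)); P <- as.integer(rep_len(P, n))
  if (any(C < 1L)) stop("formulaTable: C must be >= 1 for every formula")
  if (any(c(H, N, O, S, P) < 0L)) {
    stop("formulaTable: element counts must be non-negative")
  }
  data.frame(
    C = C, H = H, N = N, O = O, S = S, P = P,
    mass = formulaMass(C, H, N, O, S, P),
    hill = hillString(C, H, N, O, S, P),
    rdbe = C - H / 2 + N / 2 + P / 2 + 1,
    stringsAsFactors = FALSE
  )
}

#' Monoisotopic neutral mass of CHONSP formulas
#'
#' @param C,H,N,O,S,P element count vectors.
#' @return Numeric vector of monoisotopic masses (Da).
#' @examples
#' formulaMass(6, 12, 0, 6) # glucose, 180.06339
#' @export
formulaMass <- function(C, H, N = 0, O = 0, S = 0, P = 0) {
  m <- .ELEMENT_MASS
  C * m[["C"]] + H * m[["H"]] + N * m[["N"]] +
    O * m[["O"]] + S * m[["S"]] + P * m[["P"]]
}

#' Hill-notation formula strings
#'
#' Carbon first, hydrogen second, remaining elements alphabetically
#' (N, O, P, S); a count of 1 is omitted, a count of 0 omits the element.
#'
#' @param C,H,N,O,S,P element count vectors.
#' @return Character vector of Hill strings.
#' @examples
#' hillString(6, 12, O = 6) # "C6H12O6"
#' @export
hillString <- function(C, H, N = 0L, O = 0L, S = 0L, P = 0L) {
  piece <- function(sym, k) {
    ifelse(k == 0L, "", ifelse(k == 1L, sym, paste0(sym, k)))
  }
  paste0(piece("C", C), piece("H", H), piece("N", N),
         piece("O", O), piece("P", P), piece("S", S))
}

#' Parse Hill-notation CHONSP strings
#'
#' Inverse of [hillString()]; accepts any order of the six supported element
#' symbols.
#'
#' @param x character vector of formula strings, e.g. `"C6H12O6"`.
#' @return A formula `data.frame` as returned by [formulaTable()].
#' @examples
#' parseFormula("C6H12O6")$mass
#' @export
parseFormula <- function(x) {
  counts <- matrix(0L, nrow = length(x), ncol = 6,
                   dimnames = list(NULL, c("C", "H", "N", "O", "S", "P")))
  rx <- gregexpr("([CHNOSP])([0-9]*)", x)
  toks <- regmatches(x, rx)
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) stop("parseFormula: empty formula string")
    flat <- paste(toks[[i]], collapse = "")
    if (!identical(flat, x[i])) {
      stop("parseFormula: unsupported element or malformed formula: ", x[i])
    }
    for (tk in toks[[i]]) {
      sym <- substr(tk, 1, 1)
      num <- substring(tk, 2)
      counts[i, sym] <- counts[i, sym] + if (nzchar(num)) as.integer(num) else 1L
    }
  }
  formulaTable(C = counts[, "C"], H = counts[, "H"], N = counts[, "N"],
               O = counts[, "O"], S = counts[, "S"], P = counts[, "P"])
}
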