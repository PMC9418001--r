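# Independent brute-force oracles. These deliberately share no code with the
# package implementation paths they check.

# --- naive exhaustive-grid CHONSP enumeration ------------------------------
# Full grid over (N, S, P, O, C) within the default bounds; for each cell the
# hydrogen count is scanned over every integer whose mass lands within the
# tolerance window (the window is << 1 H mass at sub-ppm tolerances, scanning
# round(rem/mH) +/- 2 covers it for any tolerance used in the tests).
.oracleGridEnv <- new.env()

oracleGrid <- function() {
  if (is.null(.oracleGridEnv$g)) {
    m <- elementMasses()
    g <- expand.grid(N = 0:5, S = 0:2, P = 0:2, O = 0:60, C = 1:100,
                     KEEP.OUT.ATTRS = FALSE)
    g$base <- g$N * m[["N"]] + g$S * m[["S"]] + g$P * m[["P"]] +
      g$O * m[["O"]] + g$C * m[["C"]]
    .oracleGridEnv$g <- g
  }
  .oracleGridEnv$g
}

oracleEnumerate <- function(mass, tolPpm = 0.5) {
  g <- oracleGrid()
  mH <- elementMasses()[["H"]]
  rem <- mass - g$base
  h0 <- round(rem / mH)
  tolDa <- tolPpm * mass * 1e-6
  dmax <- max(1, ceiling(tolDa / mH))
  out <- list()
  for (dh in -dmax:dmax) {
    h <- h0 + dh
    ppm <- (mass - (g$base + h * mH)) / mass * 1e6
    ix <- which(abs(ppm) < tolPpm & h >= 1)
    if (!length(ix)) next
    h <- h[ix]
    keep <- h <= 200 &
      h / g$C[ix] >= 0.2 & h / g$C[ix] <= 3 & g$O[ix] / g$C[ix] <= 1.5 &
      (g$C[ix] - h / 2 + g$N[ix] / 2 + g$P[ix] / 2 + 1) >= 0 &
      (h + g$N[ix] + g$P[ix]) %% 2 == 0
    ix <- ix[keep]; h <- h[keep]
    if (length(ix)) {
      out[[length(out) + 1L]] <- data.frame(
        C = g$C[ix], H = h, N = g$N[ix], O = g$O[ix],
        S = g$S[ix], P = g$P[ix])
    }
  }
  if (!length(out)) {
    return(data.frame(C = integer(), H = integer(), N = integer(),
                      O = integer(), S = integer(), P = integer()))
  }
  unique(do.call(rbind, out))
}

oracleHillSet <- function(mass, tolPpm = 0.5) {
  o <- oracleEnumerate(mass, tolPpm)
  sort(hillString(o$C, o$H, o$N, o$O, o$S, o$P))
}

# --- union-find transitive closure -----------------------------------------
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

closureComponents <- function(n, edges) {
  parent <- seq_len(n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- .ufFind(parent, edges[k, 1]); rj <- .ufFind(parent, edges[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), function(i) .ufFind(parent, i), 1L)
}

# all-pairs single-linkage clustering of m/z values at a ppm tolerance
oracleAlign <- function(mz, tolPpm) {
  n <- length(mz)
  pairs <- which(outer(mz, mz, function(a, b)
    abs(a - b) / pmin(a, b) * 1e6) <= tolPpm & upper.tri(matrix(0, n, n)),
    arr.ind = TRUE)
  comp <- closureComponents(n, pairs)
  match(comp, unique(comp[order(mz)]))
}

# transitive closure grouping of Kendrick records: records are linked iff
# |KMD_i - KMD_j| <= tol and NKM_i = NKM_j (mod step); series = components
# with >= 2 members
oracleSeries <- function(kmd, nkm, tol, step = 50L) {
  n <- length(kmd)
  ok <- outer(kmd, kmd, function(a, b) abs(a - b)) <= tol &
    outer(nkm, nkm, function(a, b) (a - b) %% step) == 0
  pairs <- which(ok & upper.tri(ok), arr.ind = TRUE)
  comp <- closureComponents(n, pairs)
  keep <- table(comp)
  members <- split(seq_len(n), comp)
  members <- members[lengths(members) >= 2]
  # canonical form: sorted member index sets, ordered by mean kmd, min nkm
  members <- lapply(members, sort)
  key <- vapply(members, function(ix) mean(kmd[ix]), 0)
  mn <- vapply(members, function(ix) min(nkm[ix]), 0L)
  unname(members[order(key, mn)])
}

# --- hand-rolled Welch test -------------------------------------------------
# Same degenerate-variance convention as the package (see compareAI docs).
oracleWelch <- function(x, y, alternative = "greater") {
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    d <- mean(x) - mean(y)
    t <- if (d == 0) 0 else Inf * sign(d)
    p <- switch(alternative,
                greater = if (d > 0) 0 else if (d < 0) 1 else 0.5,
                less = if (d < 0) 0 else if (d > 0) 1 else 0.5,
                two.sided = if (d == 0) 1 else 0)
    return(list(t = t, df = NA_real_, p = p))
  }
  nx <- length(x); ny <- length(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- switch(alternative,
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  list(t = t, df = df, p = p)
}

# --- random valid formulas for property tests -------------------------------
# Independent of the package generator: plain rejection sampling over the
# default element bounds with parity and RDBE validity.
randomFormulas <- function(n, seed) {
  set.seed(seed)
  acc <- list()
  while (length(acc) < n) {
    c0 <- sample(4:60, 1)
    h0 <- sample(seq(max(1, ceiling(0.2 * c0)), min(200, 3 * c0)), 1)
    n0 <- sample(0:5, 1); s0 <- sample(0:2, 1); p0 <- sample(0:2, 1)
    o0 <- sample(0:min(60, floor(1.5 * c0)), 1)
    if ((h0 + n0 + p0) %% 2 != 0) next
    if (c0 - h0 / 2 + n0 / 2 + p0 / 2 + 1 < 0) next
    acc[[length(acc) + 1L]] <- c(C = c0, H = h0, N = n0, O = o0, S = s0,
                                 P = p0)
  }
  m <- do.call(rbind, acc)
  formulaTable(C = m[, "C"], H = m[, "H"], N = m[, "N"], O = m[, "O"],
               S = m[, "S"], P = m[, "P"])
}
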