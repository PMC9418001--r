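---
title: "Methods: molecular characterization of pyrogenic DOM from FTICR-MS peak lists"
author: "pyroDOM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: molecular characterization of pyrogenic DOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyroDOM)
```

## The problem

Wildfire transforms soil organic matter toward condensed aromatic
("pyrogenic") structures. Ultrahigh-resolution mass spectrometry (FTICR-MS)
of water-extractable dissolved organic matter (DOM) resolves thousands of
ions whose exact masses admit unique CHONSP molecular formulas, so the
molecular-level response of DOM to burn severity can be read from peak lists
alone: how aromatic the assigned formulas are, which formulas are unique to
each severity condition, whether unique formulas differ in their nominal
oxidation state of carbon (NOSC), and whether homologous series built from
the C4H2 unit — the growth step of condensed polyaromatics — run across all
severity conditions.

pyroDOM implements that analysis as a tested pipeline operating on
centroided peak lists (`mz`, `intensity` CSVs) plus a sample metadata table.
It deliberately starts after vendor peak picking and ends before any
thermodynamic modelling: NOSC is reported as a descriptor, not converted to
an oxidation free energy.

## Pipeline stages and their parameters

1. **m/z window** (`filterMzWindow`): peaks outside the closed interval
   [200, 900] m/z are removed. The bounds are closed because a peak sitting
   exactly on the nominal boundary carries no evidence for exclusion; the
   choice only matters for measure-zero inputs.
2. **Isotopologue removal** (`removeIsotopologues`): a peak is removed iff a
   peak one ¹³C–¹²C spacing (1.0033548 Da) below it, within 1 ppm, is more
   intense. The rule is evaluated against the input list, which makes the
   operation idempotent and lets a whole ¹³C chain fall in one pass.
3. **Internal recalibration** (`recalibrate`): the classic DOM calibrant
   structure — CH2 homologous series — is auto-detected: peaks with a
   *unique* CHONSP candidate within 1 ppm whose assignments form CH2 ladders
   (constant N, O, S, P and constant H − 2C) of ≥ 3 members become anchors.
   The ppm error model `a + b·m/z` is fitted by least squares and inverted.
   A linear model captures constant and mass-proportional miscalibration,
   the two leading instrumental effects, and is fully testable by injecting
   known drift. Fewer than 5 anchors ⇒ identity model with a warning.
4. **Alignment** (`alignPeaks`): all samples' peaks are pooled, sorted, and
   clustered greedily at 0.5 ppm against the running cluster mean. The
   running-mean criterion bounds how far a cluster can drift, unlike
   single-linkage chaining which can join arbitrarily long ppm chains; on
   realistic data (within-cluster spread well under the tolerance,
   between-cluster gaps above it) the two coincide, and the test suite
   verifies that equivalence against a brute-force single-linkage oracle on
   such inputs. Ties in the pooled sort are broken by sample id, which makes
   the output invariant to the order samples are supplied.
5. **Formula assignment** (`assignTable` / `enumerateCandidates`): cluster
   consensus m/z is converted to neutral mass under the singly charged
   [M−H]⁻ convention (+1.00727646 Da; positive mode is rejected, not
   guessed). Candidates are enumerated exhaustively within element bounds
   C 1–100, H 1–200, N 0–5, O 0–60, S 0–2, P 0–2 — conventional DOM
   assignment windows — subject to |error| < 0.5 ppm (strict), H/C ∈
   [0.2, 3], O/C ∈ [0, 1.5], RDBE ≥ 0 and integer-RDBE parity (H+N+P even).
   The enumeration loops over the heteroatom/oxygen/carbon grid in compiled
   code and solves the hydrogen count from the mass residual; a naive
   unpruned grid oracle in the test suite certifies that nothing is lost.
   Ranking is by |ppm|, then fewest heteroatoms, then Hill string — a
   deterministic tie-break. Strict mode withholds assignments whose top two
   candidates are separated by < 0.05 ppm.
6. **Descriptors** (`annotateFormulas`): per formula, H/C, O/C, NOSC,
   aromaticity index, and a Van Krevelen class from an editable rectangle
   table (`inst/extdata/vk_class_boundaries.csv`, half-open rectangles, no
   overlaps, remainder = "other").
7. **Kendrick series** (`kendrickTransform`, `detectSeries`,
   `filterSeriesByConditions`): C4H2-based Kendrick mass defect analysis on
   cluster ion masses; series = ≥ 2 records with matching KMD (tolerance
   0.001) and nominal Kendrick masses congruent modulo 50; retained iff the
   union of member-formula occupancies covers all four severity conditions.
8. **Comparison layer** (`buildPresence`, `uniqueFormulas`, `compareAI`,
   `summarizeNOSC`): presence/absence (not intensity) drives condition
   comparisons. Per sample, the summary statistic is the unweighted mean AI
   over detected formulas (an intensity-weighted variant is available);
   condition pairs are tested with one-sided Welch t-tests oriented by the
   severity ordering control < low < moderate < high, Holm-adjusted. Unique
   formulas per group feed median-NOSC summaries with the same testing
   scheme.

## Equation variants

Two published quantities circulate with typographical variants, and the
package makes both first-class rather than silently choosing:

* **NOSC.** The default is the standard electron-balance form
  `4 − (4C + H − 3N − 2O + 5P − 2S − Z)/C` with charge Z = 0 for neutral
  formulas. An `as_printed` variant `4 − (5C + H − 3N − 2O − 2S)/C`
  reproduces a typography seen in print; for P-free neutral formulas it
  equals the standard value minus exactly 1 (tested as an identity), so
  distributional comparisons are unaffected by the choice and medians shift
  by a constant.
* **Aromaticity index.** The default is the Koch–Dittmar form
  `(1 + C − O − S − 0.5H)/(C − O − S − N − P)` with the conventional
  zero-floor for non-positive numerator or denominator (such formulas carry
  no aromaticity evidence; the alternative of returning NA is a
  configuration away, but the floor keeps per-sample means defined). The
  carboxyl-discounted modified form (0.5·O) and an `as_printed`
  `4 − ratio` variant are also computed.
* **Kendrick base.** The exact mass of C4H2 is 50.01565006 Da, and that is
  the default `baseExact`; the value 50.0587 also appears in print and is
  available as `baseExact = "printed"`. The nominal Kendrick mass
  defaults to the ion mass rounded half away from zero (`nkmFrom =
  "mass"`); the classic convention of rounding the Kendrick mass itself
  (`nkmFrom = "kendrick"`) is the one under which KMD is *exactly*
  invariant along a C4H2 series (rounding the raw mass can cross an integer
  boundary as the 0.0157 Da per-unit surplus accumulates), and the exact
  invariance test uses it.

Series "presence" in a condition is by union of member occupancies (a
series counts as present wherever any member was detected); a per-member
reading is available by filtering occupancies upstream. The union reading
is the weaker (more retentive) of the two natural interpretations.

## The synthetic study generator

Because real FTICR-MS archives are instrument-scale, every stage is
exercised on synthetic studies whose statistical structure matches what the
analysis assumes:

* **Design**: four severity conditions at 4/6/5/6 surface replicates by
  default, a shared core pool of 2000 formulas (conventional DOM spectral
  richness; per-sample peak counts in the low thousands) plus 150
  condition-unique formulas per condition.
* **Formula populations**: an aromatic stratum (standard AI ≥ 0.5) grown as
  C4H2 ladders and an aliphatic stratum (AI < 0.5) grown as CH2 ladders.
  Ladder growth is deliberate: CH2 series are what internal recalibration
  anchors on, and C4H2 series are what the Kendrick stage must find. The
  aromatic fraction of the unique strata rises with severity
  (0.05/0.15/0.30/0.40 by default; the core pool holds at 0.10), planting
  the severity-dependent aromaticity effect the comparison layer is meant
  to recover. Because the aromatic stratum pairs low H/C with comparable
  O/C, its NOSC runs higher than the aliphatic stratum's, so the planted
  effect also carries the expected NOSC signature of severe burning.
* **Instrument model**: [M−H]⁻ ions only; Gaussian mass error (0.15 ppm SD
  by default, typical of a well-tuned 12 T instrument), optional systematic
  drift `a + b·m/z`, log-normal intensities (meanlog log(1e6), sdlog 1.2),
  and single-¹³C satellites at +1.0033548 Da with intensity 0.011·C×parent
  (the leading binomial term — enough to exercise the isotopologue filter,
  not a full isotope-pattern simulation).
* **Determinism**: every stage derives its RNG stream from the single
  design seed; identical seed + design gives byte-identical CSVs. A
  ground-truth table maps every emitted peak (satellites flagged) to its
  formula.

What the generator does *not* emulate: peak shape, resolution and S/N
behaviour, transient co-addition, adducts other than [M−H]⁻, multiply
charged ions, matrix effects, or intensity-dependent detection. Passing
tests therefore certify the computational pipeline — filtering rules,
enumeration correctness, calibration recovery, series logic, statistical
wiring — on spectra with the assumed structure; they do not certify
robustness to instrumental artifacts absent from the model.

## Numerical and degenerate-case choices

* Assignment tolerance is strict (`|ppm| < 0.5`), matching the convention
  that a reported threshold is an open bound.
* With both group variances zero, the Welch statistic is undefined; the
  package reports t = 0 or ±Inf by the sign of the mean difference and a
  one-sided p of 0.5 / 0 / 1 accordingly, so degenerate toy inputs fail
  loudly in magnitude rather than erroring.
* Alignment resolves two same-sample peaks in one cluster by intensity
  (ties by lower m/z) and logs the loser as unresolved, preserving the
  peak-accounting identity: input = aligned + window-filtered +
  isotopologue-removed + unresolved, checked on every run via the manifest.
* Kendrick grouping partitions records by NKM residue class modulo 50 and
  then chains sorted KMDs with an adjacent-gap threshold; within a residue
  class this is exactly the transitive closure of the pairwise tolerance
  relation, so the greedy implementation is certified against a
  closure oracle rather than assumed equivalent.
* KMD equality is taken at a tolerance of 0.001 (exact equality is a
  measure-zero event for measured masses).

## Problem sizes used in the test suite

Test designs are scaled to keep the suite fast while preserving the
structure under test: pools of 80–250 formulas for unit tests, a
200+40-formula zero-noise study for exact assignment checks, 1000 random
masses for enumeration–oracle equivalence, 10,000 random formulas for the
metric and Kendrick identities, three seeds of a 150+60-formula two-condition
study for planted-effect recovery, and 500 simulated identical-pool datasets
(80 formulas, 6+6 replicates) for the null calibration of the one-sided
test, which is expected to reject at the nominal 5% rate. The acceptance
script (`scripts/acceptance.R`) runs the full default design.

## Known limitations

* Exact replication of third-party assignment software is not claimed: its
  internal validity filters and tie-breaks are not public, so counts of
  assigned formulas from real archives will differ in detail even at the
  same tolerance.
* Assignment ambiguity grows with mass (tested and reported per 100 Da
  bin); above ~700 Da a meaningful fraction of clusters has multiple
  sub-0.5-ppm candidates, and the heteroatom-parsimony tie-break is a
  heuristic, not evidence.
* Only singly charged deprotonated ions are modelled and assigned.
* The comparison layer treats replicates as independent samples; spatial or
  temporal correlation structure among field replicates is out of scope.
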