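---
title: "Methods: media-panel coverage, group statistics and the identification cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: media-panel coverage, group statistics and the identification cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycopanel)
```

## The problem

Surveys of yeast biodiversity in drinking water isolate colonies from
membrane-filtered samples plated on several culture media in parallel.
Media differ in selectivity (chromogenic differentiation, dichloran
suppression of fast-growing moulds, nutrient richness), so the species
inventory recovered depends on the panel of media deployed. The practical
question is how much biodiversity a cheaper sub-panel would have missed,
relative to the full panel — and which sub-panel is the best compromise.

`mycopanel` implements that evaluation as a reusable pipeline: isolate
tables in, an exhaustive subset-coverage analysis out, with panel-size
group statistics, an explicit model of the laboratory identification
cascade and of reference-database coverage, overgrowth kinetics, and a
synthetic campaign generator so every stage can be tested without any
external data.

## Coverage model

The substrate of the analysis is the **incidence matrix**: taxa × media
presence, built from identified isolates only, plus per-medium isolate
counts over *all* analysed isolates. Two conventions matter and are fixed
throughout:

* **Species denominator.** The full panel is *defined* to recover 100% of
  the observable taxa; every panel's species percentage is relative to the
  full-panel taxon count. This is an operational best-achievable baseline,
  not a claim that the full panel recovers every cultivable species.
  Genus-rank labels (e.g. `"Geotrichum sp."`) each count as one taxon, so
  the reference study's 142 species + 10 genera give a 152-taxon axis.
* **Isolate denominator.** Isolate percentages default to all analysed
  isolates, including strains lost before identification and strains that
  resisted identification: each physically belongs to exactly one medium,
  so panel isolate counts are additive over members. An identified-only
  denominator is available (`isolate_denominator = "identified"`); the
  full-panel row of the packaged count fixture is identified-only, which is
  why it reads 2389 of 2479 (96.4%) rather than 100%.

Panel species coverage is a set union over presence columns, enumerated
exhaustively over all `2^k − 1` non-empty subsets (k ≤ 12, ordered by size
then canonically CH, DG, DR, SY, then alphabetical). Two structural
identities follow and are property-tested: coverage is monotone under
subset inclusion, and because every medium sits in the same number of
size-k panels, the mean isolate count of the size-k group is exactly
`k/|media| ×` the isolate total — which is why the printed mean isolate
coverages of the reference table are exactly 25.0, 50.0 and 75.0%.

**Minimal panels** (`minimal_panel()`) are found by exhaustive search up to
6 media (63 subsets; guaranteed optimum with deterministic tie-breaks:
smallest size, then higher species count, then lexicographic label) and by
greedy set cover beyond, where the greedy answer may exceed the optimum
size; the method used is reported in the result.

**Rounding.** All percentages and ratios are rounded half-up (never
half-even) to one decimal, via `round_half_up()`. This single convention
reproduces all thirty printed percentage cells of the reference coverage
table and the 9.2 strains-per-sample ratio; group means are kept at two
decimals and their percentages computed from the unrounded means so the
k/4 symmetry survives rounding.

## Group statistics

Panel-size groups (species or isolate counts of all size-1, size-2, …
panels) are compared with a classical one-way ANOVA and Tukey-Kramer
all-pairs comparisons. Three design points:

* The decomposition is computed directly from sums of squares because the
  single full panel forms a legitimate singleton group: it contributes
  zero within-group SS and zero within degrees of freedom, which standard
  "ordinary ANOVA" handles without special-casing. `stats::aov` serves as
  an independent cross-check in the test suite, to 1e-8 on random
  instances.
* The **studentized range distribution** needed for Tukey-Kramer p-values
  is computed from first principles by nested quadrature. Conditional on
  the pooled scale `s`, `P(range ≤ q s)` for k iid standard normals is a
  one-dimensional integral with integrand `k φ(z) [Φ(z) − Φ(z − q s)]^(k−1)`;
  because `φ(z)` bounds the integrand, a fixed 240-point Gauss-Legendre
  rule on \[−9, 9\] is exact far below the 1e-7 target. The scale is then
  integrated out between extreme chi quantiles (1e-13 tails) with adaptive
  quadrature at 1e-10 relative tolerance. The suite checks the k = 2
  closed form (`√2·|t|`), base R's `ptukey`, the df → ∞ normal-range
  limit, and a 10^6-draw Monte-Carlo simulation; observed agreement with
  `ptukey` is ~1e-9, and the implementation also covers df = 1, where
  `ptukey` returns `NaN`.
* Unequal group sizes use the Tukey-Kramer standard error
  `√(MSE/2 · (1/nᵢ + 1/nⱼ))`; the k = 2 case collapses to the pooled
  two-sided t-test, which is asserted to 1e-6.

The package prints its own adjusted p-values. The pairwise p-values quoted
in the motivating study could not be reconciled with textbook Tukey-Kramer
applied to the printed group values, so they are deliberately not encoded
as expectations anywhere; the F statistic on the printed species groups
(30.857 on 3 and 11 df) was verified by an independent hand decomposition
before implementation and is the frozen oracle.

## The identification cascade

Isolates are identified by up to two rapid MALDI-TOF MS protocols, up to
two long (protein-extraction) protocols, then ITS sequencing, then the
D1/D2 (26S, "NL") region — in that order, stopping at the first success.
`accept_ms()` encodes the acceptance rule: species-level acceptance if the
Bruker LogScore criterion (≥ 1.7) *or* the MSI-2 score criterion (closed
interval \[20, 100\]) is met, with a discordance override — if the two
libraries disagree, the strain is referred to sequencing even when a score
criterion is met. That is the only reading consistent with both the
"and/or" rule and the mismatch rule of the laboratory protocol. Barcode
identities are classified species/genus/none with inclusive thresholds
98.41/96.31 (ITS) and 99.51/97.11 (NL); boundary behaviour is tested at
one-ulp perturbations.

For simulation, stage outcomes are Bernoulli draws with exogenous
per-stage probabilities — the package never simulates spectra or
alignments. One structural constraint is enforced: an MS stage can only
succeed when the true taxon is present in the union of the active
database catalogs. Catalogs are plain label sets (`db_catalog()`), and
`db_coverage()` / `supplementation_delta()` do the set arithmetic for
coverage accounting: identifiable-taxon counts, the percentage of
isolates whose taxon a catalog contains (denominator: all supplied
records), union coverage, and gains from database supplementation. The
packaged summary counts give the reference study's 65 → 95 identifiable
species (+30) for the MSI-2 snapshots. The study's "88% of isolates
identifiable by the supplemented MSI-2" cannot be recomputed without the
unpublished per-isolate breakdown and is therefore only mentioned, never
reported as a computed value.

## Overgrowth kinetics

Filamentous fungi progressively overgrow the membrane and censor new
colony detection. Membranes start clean and are eventually fully
overgrown, so invasion is modelled as a logistic with asymptotes fixed at
0 and 100 — two free parameters, midpoint `t50` (hours) and rate (per
hour). `fit_logistic()` minimizes least squares by multi-start (15 × 6
grid over `t50` and log-rate) followed by Nelder-Mead at 1e-14 relative
tolerance; a fit is declared non-converged when it explains less than
half the variance about the mean, and constant series are flagged
degenerate rather than fitted. `time_to_threshold()` inverts either the
observations (linear interpolation, first crossing, left-censoring
flagged) or the model (`t = t50 − log(100/thr − 1)/rate`);
`usable_window()` clips to the 168-h incubation horizon. Noiseless
recovery is exact to 1e-6; at 3-percentage-point noise on the standard
twice-daily observation grid the median midpoint error is about half an
hour over 100 replicates.

## The synthetic campaign generator

The generator's defaults are the study conditions of the motivating
campaign, and they are fixed once:

* **Community.** 152 taxa with a quantile-based lognormal rank-abundance
  (`a_i ∝ exp(σ z_i)`); σ is calibrated by `calibrate_skew()` so the top 3
  taxa hold 25% of strains and the top 30 hold 75%. The geometric family
  provably cannot satisfy both targets (its best fit misses by ~0.10,
  and the calibration flags it), which is why lognormal is the default.
  The calibration achieves the targets within 0.015; those two cumulative
  shares were reported as approximate in the source material, so the
  residual is acceptable and flagged only beyond 0.02. For pools too
  small to express the rank-30 target the calibrated reference shape
  (σ = 1.52) is reused.
* **Design.** 6 sites × 29 sessions, four media, Poisson(10) strain
  deposits per filtered sample. Detection is per-taxon × medium: each
  medium draws a baseline detectability in \[0.45, 0.75\] with ±0.25
  per-taxon jitter, seeded and deterministic. Colony emergence times are
  per-strain lognormal (median 40 h, σ_log = 0.5), medium-independent:
  censoring differentiates media only through their usable windows, the
  simplest mechanism that makes slow media lose late-emerging species.
* **Censoring.** Per-medium logistic invasion parameters are matched to
  the reported overgrowth percentages at 40 h and 66 h (CH/SY: t50 45.7 h,
  rate 0.108; DR: 59.6 h, 0.097; DG: 67.6 h, 0.126 — all near-saturated
  by 96 h), and colonies are countable until 95% membrane overgrowth.
* **Identification.** Cascade probabilities (0.7 rapid, 0.6 long, 0.8
  ITS, 0.75 NL, genus fraction 0.025) give a realistically high MS
  identification rate; a default reference catalog holds the top 75% of
  taxon ranks, emulating databases biased towards common species. A
  per-strain loss probability of 0.04 (≈ 65 lost strains of ~1575)
  produces the `lost` status class, which the cascade itself cannot.
* **Reproducibility.** One isolate at most per (strain, medium). The
  physical campaign (deposits, emergence, detection, loss) runs at
  `seed`, the cascade at `seed + 1`: identification settings can change
  without disturbing which isolates exist, and raising the countable
  threshold is monotone pathwise per seed. Communities take their own
  seed so a fixed community can be re-campaigned.

What the generator deliberately does not emulate: seasonal or hydrological
forcing of composition, spatial structure within a membrane, repeat picks
of one strain from one plate, cross-contamination, or misidentification
(stages succeed or fail, they never return a wrong taxon). Tests passing
on synthetic campaigns therefore validate the *bookkeeping and inference*
of the pipeline — set unions, denominators, cascade accounting,
statistics — not the ecological realism of any particular water system.

## Problem sizes and tolerances used by the test suite

The suite freezes derived oracle values rather than recomputing them from
the implementation under test: brute-force set unions on 200 random
incidence instances (≤ 12 taxa × ≤ 5 media), exhaustive minimal-panel
search against an independent subset scan, ANOVA against `stats::aov` on
200 random instances (1e-8), the studentized range against `ptukey`
(1e-4 at worst, typically 1e-9) and against 10^6-draw Monte-Carlo within
three standard errors, Tukey-Kramer against `TukeyHSD` (1e-4) and the
pooled t-test (1e-6), logistic midpoint recovery over 100 noisy
replicates, and coverage symmetry over 25 seeded campaigns of 2 sites ×
2–3 sessions. These sizes keep the default suite near half a minute while
leaving every numerical claim above directly exercised.

## Known limitations

* The full 152-taxon inventory of the motivating study is not published
  as machine-readable data; everything incidence-dependent beyond the
  printed per-panel counts is validated by oracles on generated data, not
  by comparison to the study.
* Greedy minimal panels beyond six media may be larger than optimal (the
  classical set-cover gap); the exhaustive cutoff is deliberate.
* `coverage_from_counts()` trusts its inputs' internal consistency except
  for the species ≤ total check; it cannot detect transcription errors in
  count fixtures.
* The membership flags of the packaged 30-taxon table reconstruct
  ambiguous printed dot columns by a documented convention (see the file
  header); analyses that need authoritative catalog membership should
  supply their own catalog files.
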