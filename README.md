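# mycopanel

Evaluation of culture-media panels for recovering yeast biodiversity from
water samples.

Environmental mycology surveys filter water through cellulose membranes
and plate them on several culture media in parallel — typically a
chromogenic medium (CHROMagar Candida, `CH`), the dichloran-based
selective media DG18 (`DG`) and DRBC (`DR`), and a nutrient-rich medium
(SYMPHONY, `SY`). Because media select for different species, the panel
you deploy determines the biodiversity you see. `mycopanel` is for
microbiologists and water-quality scientists who need to answer, with
numbers: *how much of the recoverable species inventory does each media
subset capture, is the difference between panel sizes statistically
real, and which minimal panel is good enough?*

## What it computes

**Subset coverage.** From a long-format isolate table (one row per picked
colony), the package builds the taxon × medium incidence matrix and
scores every non-empty media subset *P* against the full panel *M*:

    species coverage(P) = | ∪_{m ∈ P} taxa(m) | / | ∪_{m ∈ M} taxa(m) |
    isolate coverage(P) = Σ_{m ∈ P} isolates(m) / total isolates

The full panel defines 100% species coverage (a best-achievable baseline,
not truth). Species axes use identified isolates only; isolate
denominators include lost/unidentified isolates. Ranking, group
summaries by panel size, and minimal-panel selection (exhaustive ≤ 6
media, greedy set cover beyond) sit on top.

**Group statistics.** One-way ANOVA over panel-size groups followed by
Tukey–Kramer all-pairs comparisons, q = |x̄ᵢ − x̄ⱼ| / √(MSE/2 (1/nᵢ + 1/nⱼ)),
with the studentized range distribution computed from scratch by nested
numerical quadrature (singleton groups — the lone full panel — are
handled as ordinary ANOVA prescribes).

**Identification cascade and database coverage.** The MALDI-TOF MS
acceptance rule (Bruker LogScore ≥ 1.7 and/or MSI-2 score in [20, 100],
discordance referred to sequencing), inclusive ITS/NL barcode identity
thresholds (98.41/96.31 and 99.51/97.11), the two-short–two-long–ITS–NL
attempt cascade, and set-arithmetic accounting of what reference spectral
libraries can identify, including supplementation gains.

**Overgrowth kinetics.** Logistic fits of membrane-invasion time series
(asymptotes fixed at 0/100) and usable-window computation — how long a
medium stays readable before moulds overgrow it.

**Synthetic campaigns.** A seeded generator (skewed lognormal
rank-abundance, per-medium detection, overgrowth censoring, cascade) that
produces isolate tables for every stage; see the methods vignette
(`vignettes/mycopanel-methods.Rmd`) for the model and its defaults.

## Worked example

Score all 15 panels of the reference four-medium study from its packaged
per-panel counts, then test whether panel size matters:

```r
library(mycopanel)

tab <- coverage_from_counts(load_table2_counts())
head(tab[order(-tab$species_count), ], 4)
#>              panel size species_count species_pct isolate_count isolate_pct
#>  CH + DG + DR + SY    4           152       100.0          2389        96.4
#>       CH + DR + SY    3           144        94.7          1923        77.6
#>       DG + DR + SY    3           138        90.8          1820        73.4
#>       CH + DG + DR    3           136        89.5          1914        77.2

group_summary(tab)[, c(1:4, 7, 8)]
#>  panel_size n_panels mean_species mean_species_pct mean_isolates mean_isolate_pct
#>           1        4        89.50             58.9        619.75             25.0
#>           2        6       118.67             78.1       1239.50             50.0
#>           3        4       137.75             90.6       1859.25             75.0
#>           4        1       152.00            100.0       2389.00             96.4

one_way_anova(split(tab$species_count, tab$size))
#> One-way ANOVA: F = 30.8570 on (3, 11) df, p = 0.0000

tukey_kramer(split(tab$species_count, tab$size))
#>  group_i group_j mean_diff standard_error q_stat  p_adj
#>        1       2    -29.17          3.665  7.959 0.0008
#>        1       3    -48.25          4.014 12.019 0.0000
#>        1       4    -62.50          6.347  9.847 0.0001
#>        2       3    -19.08          3.665  5.207 0.0162
#>        2       4    -33.33          6.132  5.436 0.0124
#>        3       4    -14.25          6.347  2.245 0.4238
```

Reading: a single medium recovers on average 58.9% of the species the
full panel does (the best single media, DR and SY, reach 63.8%), two
media reach 78.1%, three 90.6%. Panel size has a strong effect on
species recovery (F = 30.86); the four-media panel beats one- and
two-media panels decisively (adjusted p ≤ 0.0008) but its advantage over
three media is not significant at α = 0.05 (p = 0.42 here) — the case for
stopping at a well-chosen three-media panel. The best two-media panel is
`CH + DR` (126 species, 82.9%): `rank_panels(tab, 2, "species")`.

The same pipeline runs end to end on any isolate table, simulated or
real:

```r
model   <- build_community(152, seed = 1)        # skew-calibrated community
records <- simulate_campaign(model, campaign_config(seed = 1))
coverage_table(build_incidence(records))
```

A command-line wrapper with the same surface ships in
`inst/exec/mycopanel` (`simulate`, `evaluate`, `stats`, `dbcoverage`,
`invasion`, `report`).

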