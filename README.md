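# sealforage

Do anthropogenic sea-floor structures — pipelines, cable routes, oil and
gas wells, shipwrecks — shape where a central-place benthic marine
predator forages? `sealforage` implements the full analysis chain for that
question, developed around GPS- and time–depth-recorder-tracked adult
female Australian fur seals foraging over the near-featureless floor of
Bass Strait, where such structures act as *de facto* artificial reefs.

The pipeline runs, per individual:

1. **Dive processing** — zero-offset correction of the depth trace, dive
   detection (5 m minimum depth), and benthic/pelagic classification by
   the score *bottom-time proportion × maximum depth*: a kernel density
   estimate of the scores is bimodal for a benthic forager, and the nadir
   between the two modes is the class threshold.
2. **Track processing** — iterative speed filtering (3 m/s), linear
   regularisation to 10-min intervals, and time-interpolated dive
   locations.
3. **First-passage diving (FPD)** — a first-passage-time variant that
   accumulates time spent *underwater* within a circle of radius r around
   each track point. The operational scale is the radius maximising the
   variance of log FPD; points above the per-trip 75th percentile at that
   scale mark intensive foraging, and benthic dives there collapse to one
   foraging event per 250 m grid cell.
4. **Habitat model** — a presence-background maximum-entropy (Gibbs)
   model over a seven-layer 250 m covariate stack (depth, terrain
   complexity, and Euclidean distances to colony, coast, pipelines/cables,
   wells, shipwrecks), maximising the L1-regularised gain
   `G(w) = mean_pres(w·f) − log mean_bg exp(w·f) − Σ λ_f|w_f|`
   with linear + quadratic features, a 70/30 train/test split, AUC
   evaluation, and per-variable percent contributions from training-gain
   attribution.
5. **Association statistics** — time within a 250 m buffer of each
   structure type, cohort visitation summaries, Kruskal–Wallis comparison
   of structure-type contributions, and AICc model comparison with Akaike
   weights and model averaging for morphometric predictors (e.g. the
   flipper-length/standard-length manoeuvrability ratio).

A synthetic-data generator (`generate_seascape()`, `generate_trip()`,
`simulate_cohort()`) produces Bass-Strait-like seascapes, structures,
central-place trips and depth traces with known ground truth — including a
tunable attraction of foraging patches to structures — so every stage is
testable without field data.

## Worked example

The per-seal study table (morphometrics, habitat-model contributions,
foraging-cell counts, AUC for 36 individuals) ships with the package:

```r
library(sealforage)

seals <- seal_morphometrics()
modelled <- subset(seals, !is.na(pipes_cables))

kruskal_wallis(list(modelled$pipes_cables, modelled$wells,
                    modelled$shipwrecks))
#> $H  10.46114
#> $df 2
#> $p  0.005350465

combined <- with(modelled, pipes_cables + wells + shipwrecks)
sum(combined > 30)                     # 20 of 34 individuals above 30%
round(colMeans(modelled[, c("pipes_cables", "wells", "shipwrecks")]), 1)
#> pipes_cables        wells   shipwrecks
#>         17.6         13.2          8.1
```

The three structure types differ significantly in their mean contribution
to where seals forage intensively (H = 10.46, df = 2, p < 0.01), with
pipelines/cables highest (17.6%), then wells (13.2%) and shipwrecks
(8.1%); for 20 of the 34 modelled individuals the combined structure
layers explain more than 30% of the model.

An end-to-end synthetic run:

```r
dir <- tempfile()
cfg <- simulate_cohort(dir, n_seals = 2, seed = 42,
                       seascape_args = list(n_rows = 160, n_cols = 160),
                       trip_args = list(duration_d = 4,
                                        attraction_strength = 3))
cfg$background_n <- 4000
res <- run_pipeline(cfg)
#> [sealforage] seal 1: 1085 fixes -> 543 regular, 534 dives (391 benthic),
#>              scale 342 m, 74 foraging cells
#> [sealforage] seal 2: 1123 fixes -> 562 regular, 554 dives (401 benthic),
#>              scale 342 m, 61 foraging cells

round(res$seal_table[, c("seal", "foraging_cells", "d_pipes_cables",
                         "d_wells", "d_shipwrecks", "auc",
                         "prop_any_structure")], 3)
#>   seal foraging_cells d_pipes_cables d_wells d_shipwrecks   auc prop_any_structure
#> 1    1             74         14.494   7.234        5.602 0.949              0.100
#> 2    2             61         32.092   7.082       13.354 0.968              0.014
```

Both simulated seals — generated with their foraging patches attracted to
structures — yield models with AUC > 0.9 whose structure-distance layers
carry substantial contributions, and the occupancy column gives the
fraction of each trip spent within 250 m of any structure.

A thin command-line wrapper with `simulate` and `run` subcommands is in
`inst/cli/sealforage.R`; the methods vignette
(`vignettes/methods.Rmd`) documents every stage, parameter and design
choice in detail.

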