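---
title: "Methods: from depth traces to structure-association statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from depth traces to structure-association statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sealforage` implements an analysis chain for asking whether anthropogenic
sea-floor structures (pipelines, cable routes, wells, shipwrecks) shape
where a central-place benthic forager — the motivating system is the adult
female Australian fur seal, diving to the sea floor of Bass Strait —
concentrates its foraging. This vignette explains each stage, the
assumptions behind it, the parameters that matter, and the choices made
where the design was genuinely open.

## Dive processing

A time–depth-recorder trace is first zero-offset corrected: pressure
sensors drift, so the surface baseline is estimated as a rolling low
quantile of depth (default: the 5% quantile over 1800 s windows, evaluated
on a half-window grid and interpolated) and subtracted, with corrected
depths clipped at zero. The window must span several surfacings; with the
dive rates modelled here (~6 dives/h) the default is comfortable. This
assumes the animal surfaces regularly — true for an air-breathing diver —
and that drift is slow relative to the window.

Dives are maximal submergence intervals (depth above a 0.5 m surface
threshold, a delimiter the data demand but that has no biological weight)
whose maximum depth reaches the 5 m minimum dive threshold. Each dive is
summarised by duration, maximum depth, and the proportion of its duration
spent at or below 80% of its maximum depth — the conventional
time-depth-recorder "bottom phase". The 80% fraction is exposed as a
parameter (`bottom_fraction`).

The benthic/pelagic classifier scores each dive as bottom-time proportion
× maximum depth (metres). Flat-bottomed benthic dives to the sea floor
score high; V-shaped pelagic dives score low, so a benthic forager's score
distribution is bimodal. A Gaussian kernel density estimate
(Silverman's rule-of-thumb bandwidth, 512-point grid spanning [0, max
score]) is fitted; the two highest local maxima are found, and the nadir —
the density minimum between them, ties broken towards the lower score —
becomes the threshold: below it pelagic, at or above it benthic. A
unimodal density is signalled rather than guessed at; the caller may
supply a fallback threshold (the pipeline treats an unclassifiable
individual's dives as benthic, logged, since the modelled species forages
benthically almost exclusively). Bandwidth choice is the one genuinely
arbitrary element; a rule-based bandwidth keeps the nadir reproducible.

## Track processing

GPS fixes are projected to planar metres with an equirectangular
projection centred on the colony before any filtering, because every
distance in the analysis (250 m cells, 250 m buffers, speed limits) is
metric. Over a study region spanning a few degrees this distorts
distances by well under 1%.

The speed filter iteratively deletes the fix with the worst implied speed
to a neighbour until no consecutive pair exceeds `vmax` (default 3 m/s, a
standard sustained-speed ceiling for otariids; the choice is exposed).
Ties are broken towards the fix that is over-speed on both sides, so an
isolated spike is removed rather than its neighbours. Endpoints are always
kept; the filter only deletes, never edits, and is idempotent.

The filtered track is regularised by linear interpolation at 600 s
intervals starting from the first fix, with no extrapolation. Dives are
then located by time-linear interpolation at their start times; dives
outside the track span beyond a tolerance (default one interval) are
dropped and counted. Locating at the dive start (rather than snapping to
the nearest regular fix) was an open choice; interpolation is consistent
with how the track itself is built.

## First-passage diving

Classic first-passage time asks how long an animal takes to cross a circle
of radius r centred on each track point; area-restricted search shows up
as long passages. First-passage *diving* substitutes time spent underwater
for elapsed time: each inter-fix interval carries the summed durations of
dives starting in it, and the passage (first entry to first exit of the
circle containing the focal fix) accumulates those seconds, partial
boundary intervals pro-rated linearly in distance. Underwater time counts
all dives — a continuously diving animal accrues it while transiting too —
but only benthic dives later become foraging events; both behaviours sit
behind an explicit switch.

The operational scale is the radius maximising the variance of log
first-passage values across track points (zeros excluded), over 15
log-spaced radii from the 250 m cell size to 20 km (a typical trip
extent). If no radius shows variance the smallest is returned with a
warning. Track points above the per-trip 75th percentile of the
first-passage value at that scale are flagged as intensive foraging; the
quantile is a documented, configurable stand-in for peak-extraction rules
that vary across the first-passage literature. Benthic dives at flagged
points are snapped to 250 m grid cells and duplicate cells collapse into a
single foraging event, avoiding pseudo-replication in the habitat model.

## The covariate stack

Seven layers share one 250 m grid: depth; terrain complexity; and
Euclidean distances to the colony, the coast, pipelines and cables
(merged, as they are modelled as one variable), wells, and shipwrecks.
Distances are exact planar point-to-segment distances from cell centres —
cells are half-open so no point belongs to two cells, and values are
sampled at centres (cell-centre vs edge was an open choice; centres are
simplest and 1-Lipschitz continuity across neighbours makes the error
bounded by the cell diagonal). Complexity is the rate of change of slope:
the Horn 3×3 finite-difference slope operator applied twice, with mirrored
edge padding — zero on constant or planar bathymetry, invariant to datum
offset and sign convention. Collinearity is screened by variance inflation
factors (ordinary least squares of each variable on the rest, flag at
VIF > 3). Note that synthetic seascapes routinely flag variables —
smooth distance surfaces over a small domain correlate — whereas the
motivating study reported none; the screen reports, it does not silently
drop.

## The habitat model

The model is a presence-background maximum-entropy (Gibbs) model: over the
background cells it estimates q(x) ∝ exp(w·f(x)) maximising the
L1-regularised training gain

G(w) = mean over presences of w·f(x) − log( mean over background of
exp(w·f(x)) ) − Σ λ_f |w_f|,

the penalised log-likelihood improvement over a uniform use of the
background. Features are linear and quadratic terms of each covariate,
min–max scaled to [0, 1] by the background range (presences clamped).
The per-feature penalty is λ_f = r·0.05·s_f/√m with r the regularisation
multiplier (default 1), s_f the presence standard deviation of the
feature and m the presence count. Feature classes stop at quadratic:
hinge/product/threshold classes of the original maximum-entropy software
are out of scope here, and with presence sets this small (the floor is 5
cells; individuals below it are refused and reported, not modelled) richer
classes would mostly fit noise.

Optimisation is cyclic coordinate ascent: each feature takes a
soft-thresholded Newton step with backtracking, so the penalised gain
never decreases and every accepted step moves exactly one feature. That
last property is why coordinate ascent was chosen over a full proximal
gradient: "percent contribution" is defined as the per-variable sum of
positive gain increments (linear and quadratic features pooled),
normalised to 100, and single-feature steps make that attribution exact
rather than apportioned. The attribution is still path-dependent —
relabelling variables changes the cycling order and can move contributions
by a fraction of a percentage point — and permutation importance (drop in
presence-vs-background AUC when a variable's values are permuted) is
provided as an independent cross-check. Convergence is declared when a
full cycle improves the gain by less than 1e-5, up to 1000 cycles; small
presence sets often run to the iteration cap with the gain still creeping,
and the model is returned with its convergence flag rather than an error.

Evaluation uses a seeded disjoint 70/30 presence split and rank-based AUC
of held-out presences against the background, midranks for ties (a
constant score gives 0.5; the statistic equals Mann–Whitney U divided by
n₁n₂). Background size defaults to 10000 uniform cells.

## Structure association statistics

Buffer occupancy accrues, over the regularised track, the seconds whose
10-min interval midpoint lies within 250 m of each structure type (and of
the union). Midpoints are the simplest unbiased accrual rule on a
linearly interpolated track; the radius absorbs locational error in the
structure data and is monotone by construction. Cohort summaries count
individuals visiting at all (union time > 0), type shares among visitors,
and multi-type visitors.

Structure-type contributions are compared with the tie-corrected
Kruskal–Wallis rank-sum test (chi-square p; H defined as 0 when all values
are identical). Morphometric hypotheses are compared as ordinary linear
models under AICc = AIC + 2k(k+1)/(n−k−1), with Akaike weights and full
model averaging (absent terms as zeros). All candidate models share one
complete-case sample so likelihoods are comparable — pairwise deletion
would silently change n between rows of the model table. The response for
"reliance on structures" is the arcsine-square-root of the summed
structure-layer contribution as a proportion; plain arcsine is available
by flag, since the variance-stabilising √ convention is assumed rather
than stated in the motivating analysis.

## The synthetic world

The generator exists so every stage has testable ground truth. A seascape
is a 400×400 cell (100 km) planar world: near-uniform bathymetry around a
60 m mean (a dozen smooth Gaussian bumps, amplitude ±5 m, widths 5–20% of
the domain; zero amplitude gives a constant field), a straight northern
coastline, a colony on an offshore island 12% of the domain south of it
(an island colony also keeps distance-to-colony and distance-to-coast from
being collinear), shore-normal pipeline and cable polylines, and scattered
wells and shipwrecks.

A trip is a state-switching correlated random walk: directed transit
(≈1.2 m/s) between the colony and 2–4 foraging patch centres, slow
tortuous movement (≈0.35 m/s, high turning) inside patches, and a broad
searching state (≈0.7 m/s) around each focal region between bouts. Bouts
occupy `forage_frac` (default 0.2) of the trip — focal foraging areas
connected by travel, not a trip spent mostly inside bouts; with bouts
dominating the trip the upper-quartile first-passage flag could not, even
in principle, contain them. Trips last 3–7 days, start and end at the
colony, and with attraction strength a > 0 each patch centre is drawn near
a structure with probability a/(1+a) (500 m jitter), giving a planted
effect for recovery tests. Dives occur at ~6/h (matching the reported
~855 dives over ~6 days): square-ish benthic dives to the local
bathymetric depth during bouts, and a benthic/pelagic mixture elsewhere
(35% pelagic V-dives to a fraction of the water column), so the score
distribution is genuinely bimodal. Depth is sampled at 10 s; optional
linear sensor drift exercises the zero-offset correction.

What the generator does *not* emulate: tides and currents, haul-outs,
GPS gaps and real fix noise beyond what the speed filter sees, prey
dynamics, individual heterogeneity in diving style, and the real geometry
of Bass Strait's structures. Passing recovery tests therefore shows the
chain is internally correct and sensitive to planted effects of realistic
size — not that field data would behave this gently. In particular the
published per-individual contribution values depend on unreleased
structure geometries and are reproduced only through their printed
summary statistics, which ship with the package as a data table.

## Numerical choices and degenerate inputs

Seeds control every stochastic step (splits, background, the generator)
via isolated RNG scopes, so pipeline runs are byte-identical under a fixed
seed. Degenerate paths are explicit: empty depth series, single-fix
tracks, radius ≤ 0, unimodal score densities, zero-variance first-passage
profiles, all-identical rank data, singular model designs and
sub-threshold presence sets each produce a defined signal (error, warning
flag, or refusal) rather than a numeric accident. Exact collinearity in
the VIF screen reports Inf. The backtracking line search caps at 30
halvings; logsumexp guards the Gibbs normaliser.

Test and example problem sizes are deliberate downscales — 160×160 grids
(40 km), 3–5 day trips, 4000 background points in the heavier loops —
chosen so the full suite runs in a couple of minutes while keeping every
effect size comfortably detectable; defaults remain at the study scale
(400×400, 10000 background, full iteration caps).

## Known limitations

The optimiser's contribution attribution is order-dependent (documented
above); the quantile rule for intensive areas is a stand-in for
literature-specific peak extraction; the movement model has no behavioural
memory beyond its patch plan; occupancy uses interval midpoints rather
than exact buffer crossing times (quantisation is bounded by one
interval); and the habitat model omits the original software's richer
feature classes and output transforms, so absolute contribution values are
comparable within this implementation, not across implementations.
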