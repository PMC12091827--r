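---
title: "Methods: binned ancestral niche reconstruction with accessible areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned ancestral niche reconstruction with accessible areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barniche)
```

This vignette documents the models, parameters, numerical conventions
and design decisions behind `barniche`, and what the synthetic
validation can and cannot show about real data.

## 1. Accessible areas (M)

Niche estimates from occurrences alone are truncated: absence from an
environment is only informative if the species could have reached it.
`barniche` delimits accessibility by simulation.

**Suitability surface.** The pipeline needs a suitability value in
[0, 1] per cell to drive dispersal. We use a truncated
Mahalanobis-ellipsoid envelope: with occurrence environments
$x_1,\dots,x_k$ (one row per record over the analysis variables),
centroid $\mu$ and sample covariance $S$, a cell with environment $v$
gets

$$ s(v) = \max\!\left(0,\; 1 - \frac{(v-\mu)^\top S^{-1}(v-\mu)}{\chi^2_{p,q}}\right), $$

rescaled so the best data cell scores 1. The chi-square quantile
truncation (`truncation_q`, default 0.95, $p$ = number of variables)
bounds the envelope; outside it suitability is exactly 0 and dispersal
can never colonize. A singular covariance (e.g. all records in one
raster row) falls back to the diagonal covariance with a warning;
species with fewer than `min_records` records (default 5) skip the
simulation entirely and are characterized from occurrences only.

**Dispersal.** Starting from the occupied cells, each of `n_events`
(default 35) rounds lets every colonized cell with $s>0$ emit
dispersers. The suitability range is split into `max_dispersers`
(default 2) equal upper-closed intervals and a cell emits as many
dispersers as the index of its interval — with the defaults, two when
$s > 0.5$, one when $0 < s \le 0.5$. Each disperser travels a
log-normal distance (median 1 cell width; `kernel_sd` is the sdlog,
default 0.50 with screened alternatives 0.25 and 0.75) in a uniform
direction; the landing cell is the rounded displacement, displacements
off the grid are discarded, and a landing cell with $s>0$ joins the
colonized set. Colonization is monotone and the whole simulation is a
pure function of inputs and seed. Kernel distances are in cell widths,
not kilometres: dispersal operates on the lattice and the kernel SD is
the single spread knob.

## 2. Spatial preparation

Occurrences are validated against the shared raster frame (points
outside the extent or on nodata cells are dropped with reasons) and
then thinned so that all pairwise great-circle distances (haversine,
Earth radius 6371.0088 km) are at least `thin_km` (default 5.2 km, one
point per 2.5-arcmin pixel; points are additionally de-duplicated per
cell first when a frame is supplied). Thinning retains a
**maximum-size** subset: points closer than the threshold form a
conflict graph, and each connected component is solved exactly by
branch-and-bound (deterministic, lexicographically smallest optimum)
for components up to 24 points, with a greedy most-neighbours-removed
fallback above that. We chose exact maximization over the common greedy
heuristic because greedy removal is not optimal on all configurations
(e.g. chains), while typical occurrence clusters are small enough for
the exact solver; the procedure is deterministic and idempotent.

The four bioclim variables mixing temperature and precipitation (bio8,
bio9, bio18, bio19) are excluded up front; the analysis itself runs on
one temperature and one precipitation variable.

## 3. BR coding

Per variable, the clade-wide range is the min/max of the raster over
the union of all Ms. With a target width $w$ (defaults 1 °C, 100 mm)
the range is cut into $\max(1,\mathrm{round}(\text{range}/w))$ bins of
exactly equal width, half-open $[e_i, e_{i+1})$ with the last bin
closed — "equal-sized" bins whose width only approximates the target,
which is the only way both properties can hold simultaneously.

Coding rules per species: bins overlapping the **closed** occupied
interval $[\min, \max]$ of occurrence values are present (`1`); bins
overlapping the **open** accessible interval $(\min M, \max M)$ but not
the occupied interval are absent (`0`); all other bins are uncertain
(`?`). The open-interval convention for M makes a bin merely touched by
the M boundary uncertain rather than absent, which also covers the
boundary-coincidence case (occupied limit meeting the M limit) without
a separate rule. Occurrence-only species have no absent bins: outside
their occupied range everything is `?`. Every row of the resulting
matrix is a contiguous run of `1`s surrounded by `0`/`?` — interval
niches at the tips by construction.

## 4. Ancestral reconstruction

Each bin is an independent binary character on the dated ultrametric
tree (branch lengths in Myr; zero-length branches floored at
$10^{-8}$ Myr). The model is the single-rate symmetric 2-state CTMC
(ER) with stationary root prior $(\tfrac12,\tfrac12)$ — the minimal
defensible family for presence/absence bins and the default of the
character-based ancestral-niche tools this package follows. The
transition probability is $P(\text{stay}) = \tfrac12 + \tfrac12
e^{-2rt}$. Ambiguous tips (`?`) contribute the partial likelihood
$(1,1)$.

The rate is fitted per bin by golden-section search on the log scale
over $[10^{-8}, 10^{3}]$ /Myr (tolerance $10^{-8}$). Bins whose certain
tips are invariant bypass optimization: the shared state is fixed
clade-wide. Marginal ancestral probabilities use the standard two-pass
inside/outside computation with per-node rescaling; both the
likelihood and the marginals are verified in the test suite against
exhaustive enumeration over all internal-state assignments on every
rooted binary shape with up to six tips ($10^{-10}$ tolerance).

States are discretized at θ (default 0.8): present when
$P(\text{present}) \ge \theta$, absent when $\le 1-\theta$, else
uncertain. Ancestral present bins need not form a contiguous run;
contiguity is asserted only at the tips.

## 5. Change typology

Per bin: retraction (ancestor `1`, descendant `0`), expansion (`0` →
`1`), stasis (identical certain states), indeterminate (any `?`).
Branch events anchor to the ancestor's certain-present run: expansions
strictly above/below it are `expansion_high`/`expansion_low`;
retraction runs containing the run's top/bottom bin are
`retraction_high`/`retraction_low`; changes strictly inside are
`interior_*`, reported separately because the limit-based typology
does not cover them. When the descendant shares no certain-present bin
with the ancestor, the change is `complete_retraction`, which replaces
the per-limit retraction labels (a total loss is not a limit shift);
when the descendant's present bins sit on uncertain ancestral bins the
record is flagged, and the clade summary therefore carries both a
strict count (certain changed bins only) and an inclusive count that
adds such complete non-utilization cases. Terminal branches compare
the reconstructed parent with the observed tip vector; internal
branches compare two reconstructions.

## 6. The synthetic-data generator

`simulate_study()` builds: two orthogonal gradients (temperature
north–south over 0–30 °C, precipitation west–east over 0–3000 mm) on
one 100×100 frame, optionally with seeded moving-average-smoothed
Gaussian noise rescaled to an exact SD; a Yule tree rescaled to a
6.12 Myr crown age with 40 tips by default (the scale of the target
clade); true interval niches evolved along the tree with at most one
event per branch and variable (type uniform over the four limit
classes, magnitude $|N(0,\sigma)|$, floors/caps recorded, retractions
capped to keep at least two bin widths of niche); and occurrences
sampled uniformly without replacement from the jointly suitable cells
(counts 2–54 as in the mirrored design, or exhaustively under
`records = "dense"`). Defaults mirror the study conditions this
package targets, including eight occurrence-only species out of 40.

What the generator does **not** emulate: real spatial sampling bias
(roads, collectors), non-rectangular niche geometry, interactions
between variables, past-climate dynamics, and tree-wide heterogeneity
of niche positions. Passing tests therefore demonstrate the
correctness and internal consistency of the machinery and its
behaviour under known truth — not that any real clade's niches evolved
as reconstructed.

## 7. Identifiability and the validation fixtures

Recovery experiments revealed three structural limits, which the
validation design works within rather than papering over:

1. **Colliding events.** Two species changing state in the same bin
   inflate that bin's fitted rate and erode ancestral certainty. The
   recovery fixture plants one event per class per variable, making
   the four changed spectral zones disjoint.
2. **Unpolarizable branches.** A change on a branch off the root, or
   within a cherry with a long stem, cannot be attributed to that
   branch: the parent's state is honestly uncertain.
   `identifiable_tips()` makes this operational — a tip is eligible
   for event planting only if reconstructing the single-deviant
   character (that tip different from everyone) still calls its parent
   with certainty. This probe is a deterministic function of the tree
   alone.
3. **Truncation of expansions.** Under realistic accessible areas, an
   expansion into environments outside most species' M lands on `?`
   ancestors — the niche-truncation caveat the method is designed to
   expose. The 40-species mirror therefore plants retractions (zones
   inside the clade's shared range, where ancestors stay certain);
   expansions are validated under the full-accessibility baseline
   (`m_mode = "full"`), where they are exactly recoverable.

Events below one bin width sit under the method's resolution floor and
are verified to produce no reported changes (root interval limits are
placed at bin centers so sub-bin events cannot straddle an edge).

## 8. Numerical conventions and problem sizes

Quantiles are type-7 (linear interpolation); SDs are sample SDs
(n−1). Grids are WGS84 lon/lat, lower-left registered, cells half-open
with the top/right boundary mapped into the last cell. The ESRI ASCII
dialect is written at full precision and round-trips bit-exactly.
Manifest hashes (MD5 of every written artifact) verify that a config
plus seeds reproduces every output byte.

The shipped validation runs use 12-species clades on 100×100 grids for
event recovery, a 40-species clade with dispersal-simulated Ms for the
design mirror, 200-replicate Monte Carlo comparisons for the
dispersal-kernel screening, and exhaustive enumeration oracles at ≤6
tips, ≤12 thinning points and ≤4 bins — sizes chosen so each property
is checked exhaustively where exhaustive checking is feasible and by
seeded simulation where it is not.

## 9. Known limitations

* The suitability model behind M is an ellipsoid envelope; other
  choices (e.g. presence-background models) would change M shapes and
  hence the `0`/`?` split.
* The ER model shares one rate per bin and cannot express asymmetric
  gain/loss; rates are not pooled across bins.
* High/low event anchoring can re-classify (e.g. to `interior_*`) when
  uncertainty masks a run endpoint; species-level change counts are
  insensitive to this, event-class labels are not.
* The expert visual choice among kernel-SD candidates in the mirrored
  design is replaced by a configuration value (default 0.50); all
  candidates can be simulated for comparison.
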