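---
title: "Methods: cowshed microclimate, heat-stress indices and housing typologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cowshed microclimate, heat-stress indices and housing typologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shedclim)
```

## The problem this package addresses

Smallholder dairy farms in the tropics typically house fewer than twenty
lactating cows in sheds built from local materials, with design driven by
accumulated experience rather than thermal engineering. The microclimate
inside those sheds — air temperature, humidity, radiant load and air
movement — determines how much heat the cows accumulate through the day,
and therefore feed intake, milk yield and welfare. `shedclim` implements a
complete analysis chain for this setting, patterned on a field design of
four climatically contrasting regions (south/north crossed with
lowland/highland, labelled SL, SH, NL, NH) with eight farms per region,
microclimate readings at seven clock times through one day per farm
(06:00, 08:00, 10:00, 11:00, 14:00, 16:00, 18:00), and twelve housing
variables per farm (seven quantitative: mat area and floor area per cow,
ridge and eave roof heights, percent of shed sides open, fans per cow,
hosing frequency; five qualitative: housing type, roof material, roof
vents, sprinklers, roof soakers).

Because field data of this kind are rarely deposited, the package ships a
synthetic-data generator that emulates the design's statistical structure,
so every downstream stage — indices, comparisons, clustering, regression —
is exercised and tested end-to-end without any download.

## Thermal indices

Four indices are computed from spot readings of dry-bulb temperature (AT,
degC), relative humidity (RH, %), air speed (AS, m/s) and black-globe
temperature (GT, degC).

**Dew point** inverts the Magnus saturation-vapour-pressure approximation
with the classical coefficients 17.27 and 237.3 degC:

$$b = \frac{\ln(RH/100) + 17.27\,AT/(237.3+AT)}{17.27}, \qquad
T_{dp} = \frac{237.3\,b}{1-b}.$$

The natural logarithm makes saturation exact: `dew_point(25, 100)$Tdp` is
exactly 25. `RH = 0` is a domain error (log of zero), rejected as invalid
humidity.

**THI** (temperature-humidity index, Yousef form) is the affine
combination `THI = AT + 0.36 Tdp + 41.2`.

**HLI** (heat load index) is piecewise in globe temperature with the
branch switch at GT = 25 degC, boundary inclusive to the high branch:

- GT &ge; 25: `HLI = 8.62 + 0.38 RH + 1.55 GT - 0.5 AS + exp(2.4 - AS)`
- GT &lt; 25: `HLI = 10.66 + 0.28 RH + 1.3 GT - AS`

The low-branch humidity coefficient is 0.28 by default. A coefficient of
2.8 circulates in some secondary write-ups of this index; it makes
humidity alone contribute over two hundred index units at RH = 80% and is
physically implausible, so it is only available as an explicit override
(`low_rh_coeff`), which triggers a warning.

**AHLU** (accumulated heat load units) integrates the excess of HLI over
a thermoneutral band [77, 86]: the increment is `HLI - 77` below the
band (heat discharge), zero inside, `HLI - 86` above (heat gain). The
first value of a farm-day is the first increment itself (no interval
weighting — the day starts fresh, with no overnight carry-over), each
subsequent value adds `increment x interval` in hours, and the running
total is clamped at zero after *every* update: a cow in thermal balance
cannot bank "negative heat". Irregular intervals are supported; the
11:00 to 14:00 gap is an ordinary 3 h interval. On a fine uniform grid
the series converges to the integral of the increment function, which
the tests verify against a closed form.

**Bands.** All four categorisations use half-open intervals
`[lower, upper)`: AT {20, 27}, THI {68, 72, 80}, HLI {70, 77, 86}, AHLU
{10, 25, 50}. So HLI = 86 is already "very hot" and THI = 72 already
"mild-moderate heat stress". Bands are total and mutually exclusive over
the real line, which the tests check on a dense grid including every
boundary.

A practical caution verified by the acceptance checks: the *daily mean*
HLI of a region is not the HLI of the daily mean inputs. Lowland sheds
sit on the high branch all day, and there the two agree within about one
unit; highland sheds cross the branch boundary in the early morning, and
the daily mean HLI runs some 7 units below the index evaluated at the
daily mean GT/RH/AS. Summaries of HLI should therefore always average
the per-reading index, never plug averaged inputs into the formula.

## The synthetic-data generator

The generator defines the study conditions; its defaults are not tuning
knobs. Two modes exist because they answer different questions:

- **model mode** draws each response (AT, AS, HLI, THI) directly from the
  final fitted-model effect structure: an intercept (33.86 degC for AT,
  0.02 m/s for AS, 107.1 for HLI, 88.01 for THI) plus altitude (-0.004
  degC/m for AT, -0.013 for HLI, -0.008 for THI), a south-latitude
  indicator (-1.43, -2.46, -1.57), eave roof height (-0.87 degC/m, +0.14
  m/s per m for AS, -3.31, -1.42) and floor-area / sides-open terms
  (-0.12 degC per m2/cow for AT; -0.05 per % for HLI), plus a diurnal
  offset and Gaussian noise (sd 0.8 degC, 0.12 m/s, 2.0, 1.2). This is
  the mode for coefficient- and dip-recovery: physically consistent raw
  readings cannot simultaneously reproduce four separately fitted index
  models, since HLI and THI are deterministic functions of the raw
  variables.
- **physical mode** generates raw AT/RH/AS/GT series (GT = AT + 0.4
  degC, matching the observed offset between globe and dry-bulb daily
  means) so the index pipeline can be exercised end-to-end on readings.

The diurnal offset curve is zero across the 11:00–14:00 plateau (the
observed daily maximum is flat between those times), rises from a cool
06:00 and falls slightly by 18:00. The roof-soaker/fan dip — active by
default for NL farms that have a roof soaker — subtracts 1.3 degC from
AT, 3.2 units from HLI and 2.5 from THI at in-window readings. The
default window is {14:00, 16:00} rather than the full 10:00–16:00
operating period: the systems switch on around 10:00 and reach full
effect by early afternoon, and anchoring the window after the plateau
makes the expected paired 11:00-minus-14:00 contrast equal the
configured amplitudes exactly, which is how the effect is quantified.

**Within-farm structure.** The five qualitative variables and fans per
cow are drawn comonotonically from a single farm-level latent (marginal
frequencies unchanged): in the field, the same NL farms carry the
asbestos roof, the roof vents, the soaker system, the fan bank and
tie-up stalls — a "cooling package". This coupling is what makes the
equipment block mutually near-collinear with region, so the VIF screen
confronts the same multicollinearity the real data presents.

**Spreads.** Regional medians and frequencies anchor the centres.
Within-region sds of the quantitative housing variables are calibrated
so the implied study-wide dispersion matches the published overall
standard deviations (within² = overall² − between-median variance),
giving MatCow 0.92, FloorCow 3.24, RidgeHei 0.66, EaveHei 0.46,
SideOpen 18.9, FanCow 0.08 and hosing 0.6. A generic
fraction-of-the-median rule was rejected because it contradicts those
printed dispersions (mat area is far more variable than its medians
suggest; fans per cow are almost deterministic given the region).
Within-region altitude spread is unobserved; it defaults to 15% of the
regional mean (floor 8 m), reflecting rolling highland plateaus versus
delta flats. These are declared assumptions, chosen once.

**What the generator does not emulate.** Farm-level unmodelled
heterogeneity (management quirks, shed orientation, roof colour) is
absent, so synthetic regressions run at higher R² than field data; mat
area in regions where most farms have none is generated as a truncated
normal rather than a zero-inflated mixture; all farms share one
measurement day with no weather drift. Passing recovery tests therefore
demonstrates correctness of the estimators under the declared model, not
robustness to everything real sheds do.

## Housing typology: FAMD, Ward, k-means, V-tests

The mixed housing table is encoded FAMD-style: quantitative columns
centred and scaled by the population (1/n) standard deviation;
each category indicator divided by the square root of its proportion and
centred, the MCA weighting, so a quantitative variable and a
two-category qualitative variable contribute comparable inertia. The
encoded matrix is decomposed by SVD; eigenvalues are squared singular
values over n, and retaining all components reconstructs the matrix to
numerical precision. Components are retained up to 70% cumulative
explained variance by default.

Ward linkage (`ward.D2`) on Euclidean distances of the retained scores
produces the dendrogram. The suggested number of clusters maximises the
relative inertia gain between successive cuts,
`(W(k-1) - W(k)) / (W(k) - W(k+1))` over k in 2..10 — a large ratio
marks the cut after which further splitting buys little. This rule is a
package choice (the elbow criterion is not uniquely defined in the
literature); it is deterministic and is validated on constructed
fixtures with known cluster counts. The k-means consolidation runs Lloyd
iterations from the hierarchical-cut centroids — no random restarts, so
the whole stage is reproducible; an emptied cluster is re-seeded at the
point farthest from its assigned centroid.

Cluster characterisation uses V-tests. For a quantitative variable,

$$v = \frac{\bar x_k - \bar x}{\sqrt{\frac{N-n_k}{N-1}\,\frac{s^2}{n_k}}},$$

with s the population sd over all N farms — the exact sd of a mean of
n_k draws without replacement — and a two-sided normal p. For a
category, the count inside the cluster is hypergeometric under random
assignment; p is twice the tail in the direction of the deviation and v
is the signed normal quantile of that tail, positive when
over-represented. V-test p-values are reported unadjusted, as is
conventional for descriptive cluster profiling. For the fixture used in
validation — seven housing archetypes with membership sizes
4, 10, 9, 1, 2, 1, 5 and centre separation at least ten times the
within-archetype spread — the pipeline recovers the archetypes exactly
across seeds.

## Regression: VIF screen, backward elimination, diagnostics

Candidate predictors are altitude, latitude (treatment contrast, north
reference) and the twelve housing variables (qualitative ones as
indicator contrasts, alphabetical reference). `VIF_j = 1/(1 - R²_j)`
from regressing column j on the others; the screen removes the single
highest-VIF column at a time (ties broken by column order, every removal
logged) until all VIFs are below 5. Iterative single-column removal is a
package choice where only the removed set is conventionally reported; on
generated data the screen removes members of the equipment block
(housing type, roof type, fans per cow, roof soakers, roof vents) and
retains altitude, latitude, eave height, floor area and sides open.

The initial model is ordinary least squares with classical standard
errors and t-based two-sided p-values. Backward elimination removes the
single worst term per step — the largest p above the retention threshold
0.1, multi-level qualitative terms judged and removed as a block on
their largest level p — and refits until all terms are at or below the
threshold; an intercept-only outcome (as happens for RH) is reported,
not an error. Diagnostics are internally standardised residuals and hat
diagonals, flagged at |r| &gt; 3 and leverage above twice the mean p/n.

One statistical consequence of the 0.1 threshold worth stating plainly:
a pure-noise predictor survives elimination with probability roughly
0.1, so "noise is always removed" is not a property any implementation
can have; the tests assert a ~90% removal rate.

## Comparison battery

Quantitative variables are routed by a Shapiro-Wilk gate at alpha 0.05
on the pooled within-group residuals (a per-variable decision on
residuals, not per raw group): normal goes to one-way ANOVA with
Tukey-Kramer pairwise letters, non-normal to Kruskal-Wallis
(tie-corrected) with Dunn z post hoc tests. The Dunn adjustment is Holm
by default — a deliberate choice where the convention is split —
configurable. Qualitative variables get Fisher's exact test on the
region-by-category table (network algorithm; beyond its limits a fixed
seed Monte-Carlo with 1e5 draws, and the output records which method
ran), with pairwise two-row Fisher tests Bonferroni-multiplied by the
number of pairs. Compact letter displays are built by insert-and-absorb
from the pairwise p matrix and are invariant to label permutation.

The cluster-vs-microclimate question uses a two-way ANOVA: response on
the cluster factor plus altitude and latitude, Type-II sums of squares
(clusters are unbalanced), restricted to clusters with more than three
members. Constant covariates (latitude within a single region) are
dropped with a message.

## Validation scale and determinism

Everything is deterministic given seeds. Validation sizes were chosen to
make Monte-Carlo error small relative to the tolerances while keeping
the default suite fast: coefficient and dip recovery use 20 replicates
of 100 farms per region and 8 dip-active farms respectively; archetype
recovery uses 20 seeds of the 32-farm fixture; the size of each overall
test is estimated from 2,000 null simulations and required to lie in
[0.03, 0.07] at nominal 0.05 (Fisher's exact test is conservative on
discrete 4x2 tables and sits near the bottom of that band). The
2x2 Fisher p is checked against full hypergeometric enumeration across
all tables with margins up to 12.

## Known limitations

- The generator's model mode produces responses from linear effect
  structures; interactions and non-linear altitude effects are out of
  scope.
- Single-day, seven-reading series; no seasonal scenarios beyond scaling
  the configuration.
- The FAMD implementation covers the standard weighting only (no
  supplementary variables or rotations).
- Robust/mixed-effects alternatives to OLS, and effect-size measures for
  the comparison battery, are deliberately not provided.
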