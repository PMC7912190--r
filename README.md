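# shedclim

Heat stress is the central constraint on smallholder dairy farming in the
tropics. `shedclim` is an R package plus a scripted analysis workflow for
studying the microclimate inside smallholder cowsheds: it turns spot
readings of dry-bulb temperature (AT), relative humidity (RH), air speed
(AS) and black-globe temperature (GT) into the standard cattle
heat-stress indices, classifies cowshed designs into typologies from
mixed quantitative/qualitative housing data, and identifies which housing
and geographic parameters drive the shed microclimate. It is aimed at
animal-science and veterinary-epidemiology researchers working with
multi-region shed-survey designs (here: south/north crossed with
lowland/highland, eight farms per region, seven readings per farm-day).

## The indices at the core

* Dew point by Magnus inversion:
  `b = [ln(RH/100) + 17.27·AT/(237.3+AT)]/17.27`, `Tdp = 237.3·b/(1−b)`.
* Temperature-humidity index (Yousef): `THI = AT + 0.36·Tdp + 41.2`.
* Heat load index, piecewise at GT = 25 °C (boundary on the high branch):
  `HLI = 8.62 + 0.38·RH + 1.55·GT − 0.5·AS + e^(2.4−AS)` for GT ≥ 25,
  `HLI = 10.66 + 0.28·RH + 1.3·GT − AS` below.
* Accumulated heat load units: time integral of the excess of HLI over
  the [77, 86] thermoneutral band, clamped at zero after every update,
  restarted each farm-day.

Each index carries its ordinal heat-stress banding (half-open
`[lower, upper)` intervals: AT 20/27; THI 68/72/80; HLI 70/77/86;
AHLU 10/25/50).

Around the index engine sit four more stages, each exposed as package
functions and driven by the numbered scripts in `analysis/`:

1. a seeded synthetic-data generator for farm housing tables and diurnal
   microclimate series (model mode draws AT/AS/HLI/THI from fitted-model
   effect structures, physical mode produces raw readings), including a
   configurable midday roof-soaker/fan dip;
2. a region-comparison battery (Shapiro-Wilk gate, ANOVA/Tukey-Kramer or
   Kruskal-Wallis/Dunn, Fisher's exact with Bonferroni pairwise letters);
3. housing typologies by factor analysis of mixed data, Ward clustering
   of the retained components, deterministic k-means consolidation and
   V-test cluster characterisation;
4. VIF-screened multivariable regression (iterative screen at VIF < 5,
   backward elimination to p ≤ 0.1) with residual/leverage diagnostics.

See `vignettes/cowshed-microclimate-methods.Rmd` for the full
methodological account.

## Worked example

One hot lowland farm-day, from raw readings to indices:

```r
library(shedclim)
day <- data.frame(
  farm_id = "SL01",
  clock_time = c("06:00","08:00","10:00","11:00","14:00","16:00","18:00"),
  AT = c(24.9, 26.8, 29.6, 30.8, 31.5, 30.9, 29.2),
  RH = c(88, 87, 80, 77, 74, 76, 79),
  AS = c(0.2, 0.3, 0.5, 0.5, 0.6, 0.5, 0.4),
  GT = c(25.3, 27.2, 30.0, 31.2, 31.9, 31.3, 29.6))
idx <- compute_indices(day)
idx[, c("clock_time","AT","Tdp","THI","HLI","AHLU","hli_category")]
```

```
  clock_time   AT   Tdp   THI   HLI  AHLU hli_category
1      06:00 24.9 22.77 74.30 90.20  4.20     very hot
2      08:00 26.8 24.45 76.80 91.86 15.91     very hot
3      10:00 29.6 25.78 80.08 91.96 27.82     very hot
4      11:00 30.8 26.29 81.47 92.68 34.50     very hot
5      14:00 31.5 26.29 82.17 91.93 52.30     very hot
6      16:00 30.9 26.17 81.52 92.45 65.21     very hot
7      18:00 29.2 25.18 79.46 91.71 76.62     very hot
```

Reading: HLI exceeds the upper threshold (86) from 06:00 on, so heat
accumulates all day; AHLU crosses the "very high heat load" line (50) by
14:00 and reaches ≈77 units by 18:00 — a cow in this shed cannot return
to thermal balance during daylight and must shed the load overnight.

The full workflow runs as a sequence of thin drivers that write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # farms.csv, readings.csv
Rscript analysis/02_indices.R             # indices.csv, daily summaries
Rscript analysis/03_compare_regions.R     # region comparison tables
Rscript analysis/04_cluster_housing.R     # clusters, V-tests, cluster ANOVA
Rscript analysis/05_regress_microclimate.R# coefficient/VIF tables, dip
```

or end-to-end via `run_pipeline("results", generator_config())`.

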