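Package: shedclim
Title: Cowshed Microclimate and Heat-Stress Analysis for Smallholder Dairy Farms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing the microclimate inside smallholder dairy
    cowsheds in relation to housing design. Computes dew point, the
    temperature-humidity index (THI), the heat load index (HLI) and
    accumulated heat load units (AHLU) with their heat-stress bands from
    spot microclimate readings; generates synthetic farm housing tables and
    diurnal microclimate series with a configurable midday soaker/fan dip;
    classifies housing designs by factor analysis of mixed data followed by
    Ward clustering with k-means consolidation and V-test cluster
    characterisation; and links housing and geography to microclimate
    through variance-inflation-factor screened multivariable regression
    with backward elimination and residual/leverage diagnostics. A battery
    of region-comparison tests (ANOVA/Tukey-Kramer, Kruskal-Wallis/Dunn,
    Fisher's exact with Bonferroni pairwise) completes the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
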