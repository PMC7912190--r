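#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort — 4 regions x 8 farms with
# housing tables, plus diurnal microclimate readings at the seven
# measurement clock times (physical mode, so the index engine can be
# exercised on raw AT/RH/AS/GT readings).

suppressMessages(library(shedclim))
dir.create("results", showWarnings = FALSE)

cfg <- generator_config()  # default seed 20170824, 8 farms/region
farms <- generate_farms(cfg)
readings <- generate_microclimate(farms, mode = "physical", config = cfg)

write.csv(farms, "results/farms.csv", row.names = FALSE)
write.csv(readings, "results/readings.csv", row.names = FALSE)

cat(sprintf("simulated %d farms in %d regions; %d microclimate readings\n",
            nrow(farms), length(unique(farms$region)), nrow(readings)))
cat("regional altitude means (m):\n")
print(round(tapply(farms$altitude, farms$region, mean)))
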