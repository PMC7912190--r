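#!/usr/bin/env Rscript
# Stage 2: thermal indices. Computes dew point, THI, HLI, AHLU and their
# heat-stress bands for every reading, then summarises per region
# (daily means) and per clock time.

suppressMessages(library(shedclim))

readings <- read_readings("results/readings.csv")
farms <- read_farms("results/farms.csv")

idx <- compute_indices(readings)
write.csv(idx, "results/indices.csv", row.names = FALSE)

s <- summarize_daily(idx, variables = c("AT", "RH", "AS", "GT", "Tdp",
                                        "THI", "HLI", "AHLU"))
write.csv(s$region, "results/summary_region.csv", row.names = FALSE)
write.csv(s$by_time, "results/summary_by_time.csv", row.names = FALSE)

daily <- s$region
cat("regional daily means (06:00-18:00):\n")
for (v in c("AT", "THI", "HLI", "AHLU")) {
  sub <- daily[daily$variable == v, ]
  cat(sprintf("  %-5s %s\n", v,
              paste(sprintf("%s=%.1f", sub$region, sub$mean), collapse = "  ")))
}
end_ahlu <- idx[idx$clock_time == "18:00", ]
cat("AHLU at 18:00, regional means:\n")
print(round(tapply(end_ahlu$AHLU, end_ahlu$region, mean), 1))
cat("heat-stress banding of daily mean HLI per region:\n")
hli_means <- tapply(idx$HLI, idx$region, mean)
print(data.frame(region = names(hli_means), HLI = round(hli_means, 1),
                 band = as.character(categorize("HLI", hli_means)),
                 row.names = NULL))
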