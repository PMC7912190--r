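#!/usr/bin/env Rscript
# Stage 3: region comparisons. Housing variables are compared across the
# four regions with the test family chosen by a Shapiro-Wilk gate
# (ANOVA/Tukey-Kramer or Kruskal-Wallis/Dunn); qualitative variables get
# Fisher's exact tests with Bonferroni-corrected pairwise letters.

suppressMessages(library(shedclim))

farms <- read_farms("results/farms.csv")

vars <- c("altitude", "MatCow", "FloorCow", "RidgeHei", "EaveHei",
          "SideOpen", "FanCow", "HoseCoFlo", "Housing", "RoofType",
          "RoofVent", "Sprinkler", "RoofCooler")
rows <- list()
for (v in vars) {
  cp <- tryCatch(suppressWarnings(compare_regions(farms, v)),
                 error = function(e) NULL)
  if (is.null(cp)) {
    cat(sprintf("  %-10s skipped (degenerate)\n", v))
    next
  }
  rows[[v]] <- data.frame(
    variable = v, test = cp$test, p = cp$p,
    letters = paste(names(cp$letters), cp$letters, sep = ":", collapse = ";"))
  cat(sprintf("  %-10s %-28s p = %.4g  %s\n", v, cp$test, cp$p,
              rows[[v]]$letters))
}
out <- do.call(rbind, rows)
write.csv(out, "results/region_comparisons.csv", row.names = FALSE)

# overall housing summaries: mean of regional medians with SEM
quant <- c("MatCow", "FloorCow", "RidgeHei", "EaveHei", "SideOpen",
           "FanCow", "HoseCoFlo")
overall <- do.call(rbind, lapply(quant, function(v) {
  mm <- mean_of_medians(farms[[v]], farms$region)
  data.frame(variable = v, mean_of_medians = round(mm$mean, 1),
             sem = round(mm$sem, 1))
}))
write.csv(overall, "results/housing_overall.csv", row.names = FALSE)
cat("overall housing summaries (mean of regional medians +/- SEM):\n")
print(overall, row.names = FALSE)
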