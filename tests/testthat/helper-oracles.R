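# Independent oracles used across the suite. These deliberately avoid
# the package's code paths: direct arithmetic, enumeration, dense
# eigendecompositions and sum-of-squares formulas.

# Dew point + THI in one brute-force expression.
oracle_thi <- function(AT, RH) {
  b <- (log(RH / 100) + (17.27 * AT) / (237.3 + AT)) / 17.27
  tdp <- (237.3 * b) / (1 - b)
  AT + 0.36 * tdp + 41.2
}

oracle_hli <- function(GT, RH, AS, low_coeff = 0.28) {
  if (GT >= 25) 8.62 + 0.38 * RH + 1.55 * GT - 0.5 * AS + exp(2.4 - AS)
  else 10.66 + low_coeff * RH + 1.3 * GT - AS
}

# One-way ANOVA F from raw sums of squares.
oracle_anova_F <- function(values, groups) {
  groups <- as.factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(tapply(values, groups, function(x) sum((x - mean(x))^2)))
  k <- nlevels(groups); n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Tie-corrected Kruskal-Wallis H from rank sums.
oracle_kw_H <- function(values, groups) {
  groups <- as.factor(groups)
  n <- length(values)
  rk <- rank(values)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, groups, function(r) sum(r)^2 / length(r))) - 3 * (n + 1)
  ties <- table(rk)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration (sum of probabilities of tables at most as probable).
oracle_fisher_2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper hypergeometric tail P(X >= x) by enumeration.
oracle_hyper_upper <- function(x, K, N, n) {
  xs <- x:min(K, n)
  sum(vapply(xs, function(v)
    exp(lchoose(K, v) + lchoose(N - K, n - v) - lchoose(N, n)), numeric(1)))
}

# Adjusted Rand index from the contingency table.
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Farms table with all predictors at reference zero except as supplied.
zero_farm <- function(n = 1, altitude = 0, latitude = "north", EaveHei = 0,
                      FloorCow = 0, SideOpen = 0, region = "NH",
                      RoofCooler = "no") {
  data.frame(farm_id = sprintf("Z%02d", seq_len(n)), region = region,
             altitude = altitude, latitude_class = latitude,
             MatCow = 0, FloorCow = FloorCow, EaveHei = EaveHei,
             RidgeHei = EaveHei + 1, SideOpen = SideOpen, FanCow = 0,
             HoseCoFlo = 2, Housing = "loose", RoofType = "metal",
             RoofVent = "no", Sprinkler = "no", RoofCooler = RoofCooler,
             stringsAsFactors = FALSE)
}

# Generator config with all noise switched off.
noiseless_config <- function(seed = 1, ...) {
  cfg <- generator_config(seed = seed, ...)
  cfg$noise_sd[] <- 0
  cfg
}
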