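# Synthetic study generator: 4 regions x 8 farms, housing tables and
# diurnal microclimate with the study's linear effect structure.

#' Default region specifications
#'
#' One row per study region (SL/SH south lowland/highland, NL/NH north
#' lowland/highland): regional mean altitude with its generator sd,
#' latitude class, and whether the midday roof-soaker/fan dip is active
#' by default (NL, where farms run soakers and fans from about 10:00 h).
#' Within-region altitude spread is not an observed quantity; the default
#' sd is 15% of the regional mean with an 8 m floor, reflecting that the
#' highland study districts are rolling plateaus while the lowland ones
#' are river-delta flats.
#'
#' @return Data.frame with columns `region`, `altitude_mean`,
#'   `altitude_sd`, `latitude_class`, `dip_region`.
#' @export
region_specs <- function() {
  data.frame(
    region = c("SL", "SH", "NL", "NH"),
    altitude_mean = c(47, 967, 31, 937),
    altitude_sd = pmax(0.15 * c(47, 967, 31, 937), 8),
    latitude_class = c("south", "south", "north", "north"),
    dip_region = c(FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Regional medians of the seven quantitative housing variables and
# regional frequencies (out of 8 farms) of the five qualitative ones.
.housing_medians <- data.frame(
  region = c("SL", "SH", "NL", "NH"),
  MatCow = c(0.6, 0.0, 1.4, 1.4),
  FloorCow = c(5.2, 7.5, 6.7, 12.5),
  RidgeHei = c(3.3, 3.3, 4.1, 3.6),
  EaveHei = c(2.6, 2.3, 3.4, 2.8),
  SideOpen = c(75, 87, 75, 90),
  FanCow = c(0.1, 0.0, 0.8, 0.0),
  HoseCoFlo = c(2, 2, 2, 2),
  stringsAsFactors = FALSE
)

.housing_freqs <- data.frame(
  region = c("SL", "SH", "NL", "NH"),
  loose = c(0, 8, 3, 8) / 8,
  asbestos = c(0, 1, 7, 3) / 8,
  roofvent = c(0, 1, 8, 3) / 8,
  sprinkler = c(0, 0, 2, 0) / 8,
  roofcooler = c(0, 0, 7, 0) / 8,
  stringsAsFactors = FALSE
)

#' Default generator configuration
#'
#' Model-mode responses are generated directly from the final fitted
#' linear models of the study: for each response (AT degC, AS m/s, HLI
#' and THI index units) an intercept plus altitude (per m), south
#' latitude indicator, eave roof height (per m), floor area per cow
#' (per m2/cow) and shed-sides-open (per %) terms, a diurnal offset
#' (zero across the 11:00-14:00 plateau) and Gaussian noise. The
#' roof-soaker/fan dip (active for NL farms with a roof soaker) subtracts
#' 1.3 degC from AT, 3.2 units from HLI and 2.5 units from THI at
#' afternoon in-window readings (default window 14:00 and 16:00, the
#' readings taken with the systems fully in action).
#'
#' @param n_farms_per_region Farms per region (study: 8).
#' @param seed Integer seed; the seed fully determines the output.
#' @return Named list of generator parameters; any element may be
#'   overridden before passing to [generate_farms()] /
#'   [generate_microclimate()].
#' @export
generator_config <- function(n_farms_per_region = 8, seed = 20170824) {
  list(
    n_farms_per_region = n_farms_per_region,
    seed = seed,
    clock_times = c("06:00", "08:00", "10:00", "11:00", "14:00", "16:00", "18:00"),
    coefficients = list(
      #        intercept altitude latitude_south EaveHei FloorCow SideOpen
      AT = c(intercept = 33.86, altitude = -0.004, latitude_south = -1.43,
             EaveHei = -0.87, FloorCow = -0.12, SideOpen = 0),
      AS = c(intercept = 0.02, altitude = 0, latitude_south = 0,
             EaveHei = 0.14, FloorCow = 0, SideOpen = 0),
      HLI = c(intercept = 107.1, altitude = -0.013, latitude_south = -2.46,
              EaveHei = -3.31, FloorCow = 0, SideOpen = -0.05),
      THI = c(intercept = 88.01, altitude = -0.008, latitude_south = -1.57,
              EaveHei = -1.42, FloorCow = 0, SideOpen = 0)
    ),
    noise_sd = c(AT = 0.8, AS = 0.12, HLI = 2.0, THI = 1.2),
    # diurnal offsets relative to the 11:00-14:00 plateau, per clock time
    diurnal = list(
      AT = c(-5.5, -3.5, -1.0, 0, 0, -0.5, -1.5),
      AS = c(-0.15, -0.1, 0, 0, 0, 0, -0.05),
      HLI = c(-9.0, -5.5, -1.5, 0, 0, -1.0, -2.5),
      THI = c(-4.5, -3.0, -0.8, 0, 0, -0.4, -1.2)
    ),
    soaker_dip = list(
      active = TRUE,
      window = c("14:00", "16:00"),
      amount = c(AT = 1.3, AS = 0, HLI = 3.2, THI = 2.5)
    ),
    # physical mode: RH diurnal structure and globe-temperature offset
    physical = list(
      RH_base = c(SL = 81.8, SH = 80.5, NL = 82.0, NH = 80.6),
      RH_diurnal = c(6, 6, 0, -3, -4, -3, 0),
      RH_sd = 3,
      GT_offset = 0.4
    ),
    # within-region sds of the quantitative housing variables, calibrated
    # so the implied overall dispersion matches the printed study-wide
    # standard deviations (within^2 = overall^2 - between-median^2)
    housing_sd = c(MatCow = 0.92, FloorCow = 3.24, RidgeHei = 0.66,
                   EaveHei = 0.46, SideOpen = 18.9, FanCow = 0.08,
                   HoseCoFlo = 0.6)
  )
}

# Truncated-normal draws by inverse-CDF, deterministic under set.seed().
rtnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  qtnorm(stats::runif(n), mean, sd, lower, upper)
}

# Truncated-normal quantile function (u in [0,1]).
qtnorm <- function(u, mean, sd, lower = 0, upper = Inf) {
  pl <- stats::pnorm((lower - mean) / sd)
  pu <- stats::pnorm((upper - mean) / sd)
  stats::qnorm(pl + u * (pu - pl)) * sd + mean
}

#' Generate a synthetic farm housing table
#'
#' Draws the seven quantitative housing variables from truncated normals
#' centred on the regional medians, with within-region sds calibrated so
#' the implied study-wide dispersion matches the printed overall
#' standard deviations; qualitative variables come from the regional
#' frequencies, and altitude from the regional altitude distribution.
#' Ridge height is floored at eave height plus 0.1 m so
#' `RidgeHei >= EaveHei` always holds; shed-sides-open is capped at 100%.
#'
#' @param config List from [generator_config()].
#' @param regions Regions to generate (default all four).
#' @return Data.frame with one row per farm: `farm_id`, `region`,
#'   `altitude`, `latitude_class`, the seven quantitative and five
#'   qualitative housing variables.
#' @export
generate_farms <- function(config = generator_config(),
                           regions = c("SL", "SH", "NL", "NH")) {
  if (config$n_farms_per_region < 1) stop("n_farms_per_region must be >= 1")
  bad <- setdiff(regions, region_specs()$region)
  if (length(bad)) stop("invalid region name: ", paste(bad, collapse = ", "))
  set.seed(config$seed)
  specs <- region_specs()
  med <- .housing_medians
  frq <- .housing_freqs
  n <- config$n_farms_per_region
  sds <- config$housing_sd
  out <- lapply(regions, function(r) {
    sp <- specs[specs$region == r, ]
    m <- med[med$region == r, ]
    f <- frq[frq$region == r, ]
    eave <- rtnorm(n, m$EaveHei, sds[["EaveHei"]], lower = 1.2)
    # cooling-equipment package: in the field the same farms carry the
    # asbestos roof, the roof vents, the soakers, the fans and tie-up
    # stalls, so all equipment marks are driven by one farm-level latent
    # (comonotone coupling); marginals still match the regional
    # frequencies.
    u <- stats::runif(n)
    data.frame(
      farm_id = sprintf("%s%02d", r, seq_len(n)),
      region = r,
      altitude = rtnorm(n, sp$altitude_mean, sp$altitude_sd, lower = 0),
      latitude_class = sp$latitude_class,
      MatCow = rtnorm(n, m$MatCow, sds[["MatCow"]]),
      FloorCow = rtnorm(n, m$FloorCow, sds[["FloorCow"]], lower = 1),
      EaveHei = eave,
      RidgeHei = pmax(rtnorm(n, m$RidgeHei, sds[["RidgeHei"]], lower = 1.2),
                      eave + 0.1),
      SideOpen = rtnorm(n, m$SideOpen, sds[["SideOpen"]], upper = 100),
      FanCow = qtnorm(1 - u, m$FanCow, sds[["FanCow"]]),
      HoseCoFlo = rtnorm(n, m$HoseCoFlo, sds[["HoseCoFlo"]]),
      Housing = ifelse(u < 1 - f$loose, "tie-up", "loose"),
      RoofType = ifelse(u < f$asbestos, "asbestos", "metal"),
      RoofVent = ifelse(u < f$roofvent, "yes", "no"),
      Sprinkler = ifelse(u < f$sprinkler, "yes", "no"),
      RoofCooler = ifelse(u < f$roofcooler, "yes", "no"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

.linear_predictor <- function(farms, coefs) {
  coefs[["intercept"]] +
    coefs[["altitude"]] * farms$altitude +
    coefs[["latitude_south"]] * (farms$latitude_class == "south") +
    coefs[["EaveHei"]] * farms$EaveHei +
    coefs[["FloorCow"]] * farms$FloorCow +
    coefs[["SideOpen"]] * farms$SideOpen
}

.dip_active <- function(farms, config) {
  if (!isTRUE(config$soaker_dip$active)) return(rep(FALSE, nrow(farms)))
  specs <- region_specs()
  dip_regions <- specs$region[specs$dip_region]
  farms$region %in% dip_regions & farms$RoofCooler == "yes"
}

#' Generate diurnal microclimate series for a farm table
#'
#' Two modes. In `"model"` mode each response (AT, AS, HLI, THI) is drawn
#' directly from its fitted-model linear predictor plus a diurnal offset,
#' the soaker/fan dip at in-window times for dip-active farms, and
#' Gaussian noise; this is the mode used for coefficient- and
#' dip-recovery, since physically consistent raw readings cannot
#' simultaneously reproduce four separately fitted index models. In
#' `"physical"` mode raw readings (AT, RH, AS, GT = AT + 0.4 degC) are
#' generated from the diurnal curves so the whole index pipeline can be
#' exercised end-to-end.
#'
#' @param farms Farm table from [generate_farms()].
#' @param mode `"model"` or `"physical"`.
#' @param config Generator configuration; `config$seed` is consumed here
#'   independently of farm generation.
#' @param dip_active Optional logical vector (one per farm) overriding
#'   the default rule (dip-region farms with a roof soaker).
#' @return Long data.frame with one row per farm and clock time; in model
#'   mode columns `AT`, `AS`, `HLI`, `THI`, in physical mode `AT`, `RH`,
#'   `AS`, `GT`.
#' @export
generate_microclimate <- function(farms, mode = c("model", "physical"),
                                  config = generator_config(),
                                  dip_active = NULL) {
  mode <- match.arg(mode)
  if (nrow(farms) == 0) stop("farms must be non-empty")
  if (is.null(dip_active)) dip_active <- .dip_active(farms, config)
  stopifnot(length(dip_active) == nrow(farms))
  set.seed(config$seed + 1L)
  times <- config$clock_times
  nt <- length(times)
  nf <- nrow(farms)
  grid <- data.frame(
    farm_id = rep(farms$farm_id, each = nt),
    region = rep(farms$region, each = nt),
    clock_time = rep(times, nf),
    stringsAsFactors = FALSE
  )
  in_window <- grid$clock_time %in% config$soaker_dip$window &
    rep(dip_active, each = nt)
  if (mode == "model") {
    for (resp in c("AT", "AS", "HLI", "THI")) {
      lp <- .linear_predictor(farms, config$coefficients[[resp]])
      val <- rep(lp, each = nt) +
        rep(config$diurnal[[resp]], nf) -
        config$soaker_dip$amount[[resp]] * in_window +
        stats::rnorm(nt * nf, 0, config$noise_sd[[resp]])
      if (resp == "AS") val <- pmax(val, 0)
      grid[[resp]] <- val
    }
  } else {
    ph <- config$physical
    at <- rep(.linear_predictor(farms, config$coefficients$AT), each = nt) +
      rep(config$diurnal$AT, nf) -
      config$soaker_dip$amount[["AT"]] * in_window +
      stats::rnorm(nt * nf, 0, config$noise_sd[["AT"]])
    rh <- rep(ph$RH_base[farms$region], each = nt) +
      rep(ph$RH_diurnal, nf) + stats::rnorm(nt * nf, 0, ph$RH_sd)
    as_ <- rep(.linear_predictor(farms, config$coefficients$AS), each = nt) +
      rep(config$diurnal$AS, nf) +
      stats::rnorm(nt * nf, 0, config$noise_sd[["AS"]])
    grid$AT <- at
    grid$RH <- pmin(pmax(rh, 0), 100)
    grid$AS <- pmax(as_, 0)
    grid$GT <- at + ph$GT_offset
  }
  grid
}

#' Per-farm daily mean responses merged with housing predictors
#'
#' Averages each response over the day's clock times for each farm and
#' joins the result to the housing table, producing the merged
#' farm-by-response table the regression stage consumes.
#'
#' @param farms Farm housing table.
#' @param microclimate Long table from [generate_microclimate()] (model
#'   mode) or index series from [compute_indices()].
#' @param responses Response columns to average.
#' @return One row per farm: housing predictors plus daily mean responses.
#' @export
merge_farm_responses <- function(farms, microclimate,
                                 responses = intersect(c("AT", "RH", "AS", "HLI", "THI"),
                                                       names(microclimate))) {
  means <- stats::aggregate(microclimate[responses],
                            by = list(farm_id = microclimate$farm_id), FUN = mean)
  merge(farms, means, by = "farm_id", sort = TRUE)
}

# Seven housing archetypes for cluster-recovery fixtures, loosely shaped
# like the study's seven cowshed types (membership sizes 4,10,9,1,2,1,5).
.archetypes <- data.frame(
  archetype = 1:7,
  size = c(4, 10, 9, 1, 2, 1, 5),
  MatCow = c(2.9, 0.6, 1.0, 0.5, 1.2, 0.8, 1.4),
  FloorCow = c(9.0, 8.7, 5.3, 21.3, 7.0, 10.0, 6.7),
  RidgeHei = c(3.0, 3.6, 3.5, 4.0, 4.2, 6.0, 4.1),
  EaveHei = c(2.4, 2.5, 2.6, 3.0, 3.3, 3.8, 3.6),
  SideOpen = c(80, 88, 75, 90, 70, 60, 75),
  FanCow = c(0.0, 0.0, 0.1, 0.0, 0.5, 1.0, 0.8),
  HoseCoFlo = c(2, 2, 2, 2, 3, 5, 2),
  Housing = c("loose", "loose", "tie-up", "loose", "tie-up", "tie-up", "tie-up"),
  RoofType = c("metal", "metal", "metal", "metal", "asbestos", "metal", "asbestos"),
  RoofVent = c("no", "no", "no", "no", "yes", "no", "yes"),
  Sprinkler = c("no", "no", "no", "no", "yes", "no", "no"),
  RoofCooler = c("no", "no", "no", "no", "yes", "no", "yes"),
  stringsAsFactors = FALSE
)

#' Archetype fixture for cluster recovery
#'
#' Generates farms from seven housing archetypes with fixed membership
#' sizes (4, 10, 9, 1, 2, 1, 5; 32 farms at scale 1). Quantitative
#' variables get Gaussian noise whose sd is `noise_frac` of each
#' variable's between-archetype sd; at the default 0.04 the minimum
#' centre-to-centre separation in the encoded factor space is at least
#' 10 times the within-archetype spread, so the archetypes are cleanly
#' recoverable. Qualitative variables are fixed per archetype. The true
#' membership is returned in the `archetype` column.
#'
#' @param seed Integer seed.
#' @param noise_frac Within-archetype noise as a fraction of each
#'   variable's between-archetype sd.
#' @param size_scale Multiplier on the membership sizes.
#' @return Farm-style housing table with an extra `archetype` column.
#' @export
archetype_farms <- function(seed = 1, noise_frac = 0.04, size_scale = 1) {
  set.seed(seed)
  arch <- .archetypes
  sizes <- round(arch$size * size_scale)
  idx <- rep(seq_len(nrow(arch)), sizes)
  quant <- c("MatCow", "FloorCow", "RidgeHei", "EaveHei",
             "SideOpen", "FanCow", "HoseCoFlo")
  out <- arch[idx, c("archetype", quant, "Housing", "RoofType",
                     "RoofVent", "Sprinkler", "RoofCooler")]
  for (v in quant) {
    between_sd <- stats::sd(arch[[v]])
    out[[v]] <- pmax(out[[v]] + stats::rnorm(nrow(out), 0, noise_frac * between_sd), 0)
  }
  out$farm_id <- sprintf("A%02d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("farm_id", "archetype", quant, "Housing", "RoofType",
          "RoofVent", "Sprinkler", "RoofCooler")]
}
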