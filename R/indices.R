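#' Dew-point temperature from dry-bulb temperature and relative humidity
#'
#' Inverts the Magnus saturation-vapour-pressure approximation
#' (coefficients 17.27 and 237.3 degC) to obtain the dew point from the
#' dry-bulb temperature and relative humidity:
#' \deqn{b = [\ln(RH/100) + 17.27\,AT/(237.3 + AT)] / 17.27}
#' \deqn{T_{dp} = 237.3\,b / (1 - b)}
#' The natural logarithm is used, so saturation (`RH = 100`) returns the
#' dry-bulb temperature exactly.
#'
#' @param AT Dry-bulb air temperature, degC. Vectorised.
#' @param RH Relative humidity, percent, in (0, 100]. Vectorised.
#' @return A data.frame with columns `b` (dimensionless intermediate,
#'   always < 1) and `Tdp` (dew point, degC, never above `AT`).
#' @examples
#' dew_point(25, 100)        # Tdp == 25 at saturation
#' dew_point(29.5, 81.8)$Tdp # about 26.06
#' @export
dew_point <- function(AT, RH) {
  stopifnot(is.numeric(AT), is.numeric(RH))
  if (any(!is.finite(AT)) || any(!is.finite(RH)))
    stop("AT and RH must be finite")
  if (any(RH <= 0))
    stop("invalid-humidity: RH must be strictly positive (log of zero)")
  if (any(RH > 100))
    stop("invalid-humidity: RH must not exceed 100%")
  b <- (log(RH / 100) + 17.27 * AT / (237.3 + AT)) / 17.27
  data.frame(b = b, Tdp = 237.3 * b / (1 - b))
}

#' Temperature-humidity index (Yousef form)
#'
#' `THI = AT + 0.36 * Tdp + 41.2`, the affine dry-bulb/dew-point
#' combination classically used to band heat-stress risk in cattle.
#'
#' @param AT Dry-bulb temperature, degC.
#' @param Tdp Dew-point temperature, degC (measured or from [dew_point()]).
#' @return THI in index units; monotone increasing in both arguments.
#' @export
thi_yousef <- function(AT, Tdp) {
  stopifnot(is.numeric(AT), is.numeric(Tdp))
  AT + 0.36 * Tdp + 41.2
}

#' Heat load index
#'
#' Piecewise function of black-globe temperature, relative humidity and
#' air speed with a branch switch at `GT = 25` degC (the high branch is
#' used at the boundary):
#' \itemize{
#'   \item `GT >= 25`: `HLI = 8.62 + 0.38 RH + 1.55 GT - 0.5 AS + exp(2.4 - AS)`
#'   \item `GT <  25`: `HLI = 10.66 + low_rh_coeff * RH + 1.3 GT - AS`
#' }
#' The low-branch humidity coefficient defaults to 0.28 (the value of the
#' original index). Some secondary sources print 2.8 for this coefficient;
#' that value makes humidity alone contribute hundreds of index units and
#' is physically implausible, so it is not the default, but it can be
#' supplied via `low_rh_coeff` for comparison.
#'
#' @param GT Black-globe temperature, degC.
#' @param RH Relative humidity, percent.
#' @param AS Air speed, m/s (non-negative).
#' @param low_rh_coeff Humidity coefficient of the `GT < 25` branch.
#' @return HLI in index units.
#' @export
hli <- function(GT, RH, AS, low_rh_coeff = 0.28) {
  stopifnot(is.numeric(GT), is.numeric(RH), is.numeric(AS))
  if (any(AS < 0)) stop("AS must be non-negative")
  if (!identical(low_rh_coeff, 0.28))
    warning("non-default low-branch RH coefficient: ", low_rh_coeff)
  high <- 8.62 + 0.38 * RH + 1.55 * GT - 0.5 * AS + exp(2.4 - AS)
  low <- 10.66 + low_rh_coeff * RH + 1.3 * GT - AS
  ifelse(GT >= 25, high, low)
}

#' Per-time-point accumulated heat load increment
#'
#' Excess of HLI over the upper threshold when hot, deficit below the
#' lower threshold when cool, zero inside the thermoneutral band.
#'
#' @param hli_values HLI values.
#' @param lower,upper Thermoneutral band limits in HLI units (77 and 86).
#' @return Increment in AHLU units per hour.
#' @export
ahlu_increment <- function(hli_values, lower = 77, upper = 86) {
  stopifnot(lower <= upper)
  ifelse(hli_values < lower, hli_values - lower,
         ifelse(hli_values > upper, hli_values - upper, 0))
}

#' Accumulated heat load units over a farm-day
#'
#' Integrates the heat-load increment through the day. The first value is
#' the increment at the first time point; each later value adds
#' `increment * interval` (hours since the previous reading). The running
#' total is clamped at zero after every update, so a cow discharging heat
#' below the lower threshold never goes into "negative" heat load. Each
#' farm-day starts fresh (no overnight carry-over).
#'
#' @param hli_values HLI per time point.
#' @param clock_times Measurement times in decimal hours, strictly
#'   increasing; irregular intervals are supported.
#' @param lower,upper Thermoneutral band limits in HLI units.
#' @return A data.frame with `increment` (AHLU units/h) and `AHLU`.
#' @examples
#' ahlu_series(c(90, 90), c(6, 8))$AHLU   # 4 then 4 + 4*2 = 12
#' ahlu_series(c(90, 70), c(6, 8))$AHLU   # 4 then clamped to 0
#' @export
ahlu_series <- function(hli_values, clock_times, lower = 77, upper = 86) {
  n <- length(hli_values)
  if (n < 1L) stop("at least one time point is required")
  if (length(clock_times) != n)
    stop("hli_values and clock_times must have equal length")
  if (n > 1L && any(diff(clock_times) <= 0))
    stop("clock_times must be strictly increasing")
  inc <- ahlu_increment(hli_values, lower, upper)
  ahlu <- numeric(n)
  ahlu[1L] <- max(inc[1L], 0)
  if (n > 1L) {
    for (i in 2:n) {
      ahlu[i] <- max(ahlu[i - 1L] + inc[i] * (clock_times[i] - clock_times[i - 1L]), 0)
    }
  }
  data.frame(increment = inc, AHLU = ahlu)
}

# Band definitions: half-open [lower, upper) throughout.
.heat_bands <- list(
  AT = list(breaks = c(-Inf, 20, 27, Inf),
            labels = c("normal", "heat stress threshold", "mid-severe heat stress")),
  THI = list(breaks = c(-Inf, 68, 72, 80, Inf),
             labels = c("normal", "heat stress threshold",
                        "mild-moderate heat stress", "moderate-severe heat stress")),
  HLI = list(breaks = c(-Inf, 70, 77, 86, Inf),
             labels = c("cool", "moderate", "hot", "very hot")),
  AHLU = list(breaks = c(-Inf, 10, 25, 50, Inf),
              labels = c("low heat load", "moderate heat load",
                         "high heat load", "very high heat load"))
)

#' Ordinal heat-stress band for an index value
#'
#' Bands are total and mutually exclusive over the real line, half-open
#' on the right: e.g. `HLI = 86` is already "very hot", `THI = 72` is
#' already "mild-moderate heat stress".
#'
#' @param index_name One of `"AT"`, `"THI"`, `"HLI"`, `"AHLU"`.
#' @param value Numeric vector of index values.
#' @return An ordered factor of band labels.
#' @export
categorize <- function(index_name, value) {
  if (!index_name %in% names(.heat_bands))
    stop("unknown index name: ", index_name)
  band <- .heat_bands[[index_name]]
  cut(value, breaks = band$breaks, labels = band$labels,
      right = FALSE, ordered_result = TRUE)
}

#' Parse "HH:MM" clock times to decimal hours
#'
#' @param x Character vector like `"06:00"`, or numeric (returned as-is).
#' @return Numeric hours since midnight.
#' @export
parse_clock <- function(x) {
  if (is.numeric(x)) return(x)
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) != 2L || anyNA(suppressWarnings(as.numeric(p))))
      stop("clock_time must be numeric hours or 'HH:MM': ", paste(p, collapse = ":"))
    as.numeric(p[1L]) + as.numeric(p[2L]) / 60
  }, numeric(1))
}

.check_readings <- function(readings) {
  required <- c("farm_id", "clock_time", "AT", "RH", "AS", "GT")
  missing <- setdiff(required, names(readings))
  if (length(missing))
    stop("missing reading columns: ", paste(missing, collapse = ", "))
  with(readings, {
    if (any(RH < 0 | RH > 100)) stop("RH must lie in [0, 100]")
    if (any(AS < 0)) stop("AS must be non-negative")
    if (any(AT <= -40 | AT >= 60) || any(GT <= -40 | GT >= 60))
      stop("AT and GT must lie within (-40, 60) degC")
  })
  invisible(readings)
}

#' Thermal index series for a table of microclimate readings
#'
#' Takes long-format readings (one row per farm and clock time, columns
#' `farm_id`, `clock_time`, `AT`, `RH`, `AS`, `GT`; a measured `Tdp`
#' column, if present, is carried through untouched and a computed dew
#' point is added alongside) and appends `Tdp` (computed), `THI`, `HLI`,
#' `AHLU_increment`, `AHLU` and the four heat-stress band columns. AHLU
#' is accumulated per farm in clock-time order.
#'
#' @param readings Data.frame of microclimate readings.
#' @param low_rh_coeff Low-branch HLI humidity coefficient, see [hli()].
#' @param lower,upper AHLU thermoneutral band limits in HLI units.
#' @return The input with index and category columns appended, ordered by
#'   farm and clock time.
#' @export
compute_indices <- function(readings, low_rh_coeff = 0.28,
                            lower = 77, upper = 86) {
  .check_readings(readings)
  readings$.hours <- parse_clock(readings$clock_time)
  readings <- readings[order(readings$farm_id, readings$.hours), , drop = FALSE]
  measured_tdp <- if ("Tdp" %in% names(readings)) readings$Tdp else NULL
  readings$Tdp <- dew_point(readings$AT, readings$RH)$Tdp
  if (!is.null(measured_tdp)) readings$Tdp_measured <- measured_tdp
  readings$THI <- thi_yousef(readings$AT, readings$Tdp)
  readings$HLI <- hli(readings$GT, readings$RH, readings$AS, low_rh_coeff)
  pieces <- split(readings, readings$farm_id)
  pieces <- lapply(pieces, function(df) {
    if (anyDuplicated(df$.hours))
      stop("clock times must be strictly increasing within a farm: ",
           df$farm_id[1L])
    acc <- ahlu_series(df$HLI, df$.hours, lower, upper)
    df$AHLU_increment <- acc$increment
    df$AHLU <- acc$AHLU
    df
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$at_category <- categorize("AT", out$AT)
  out$thi_category <- categorize("THI", out$THI)
  out$hli_category <- categorize("HLI", out$HLI)
  out$ahlu_category <- categorize("AHLU", out$AHLU)
  out$.hours <- NULL
  out
}
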