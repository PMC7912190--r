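# Orchestration and shared I/O: CSV readers/writers with schema checks,
# daily summaries, and the end-to-end pipeline driver used by the
# analysis scripts.

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a microclimate readings CSV with schema validation
#'
#' Long format, UTF-8, '.' decimal; required columns `farm_id`,
#' `clock_time`, `AT`, `RH`, `AS`, `GT` (a `region` column and measured
#' temperature columns are carried through).
#'
#' @param path CSV path.
#' @return Data.frame of readings.
#' @export
read_readings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("farm_id", "clock_time", "AT", "RH", "AS", "GT")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error, missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Read a farm housing CSV with schema validation
#'
#' @param path CSV path.
#' @return Data.frame of farm housing records.
#' @export
read_farms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("farm_id", "region", "altitude", "latitude_class",
                "MatCow", "FloorCow", "RidgeHei", "EaveHei", "SideOpen",
                "FanCow", "HoseCoFlo", "Housing", "RoofType", "RoofVent",
                "Sprinkler", "RoofCooler")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("schema error, missing columns: ", paste(missing, collapse = ", "))
  if (any(df$RidgeHei < df$EaveHei))
    stop("invalid housing record: RidgeHei below EaveHei")
  df
}

#' Mean of group medians with its standard error
#'
#' The "overall" summary convention used for skewed housing variables:
#' the median per group, then the mean and SEM of those medians.
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @return List: `medians` (per group), `mean`, `sem`.
#' @export
mean_of_medians <- function(values, groups) {
  med <- tapply(values, groups, stats::median)
  list(medians = med, mean = mean(med),
       sem = stats::sd(med) / sqrt(length(med)))
}

#' Daily and per-time summaries of microclimate/index series
#'
#' Per-region means and SEMs of each numeric variable over the day's
#' time points (farm daily means first, then across farms), plus
#' per-region means at each clock time, plus overall mean-of-medians
#' summaries across regions.
#'
#' @param series Long data.frame with `farm_id`, `region`, `clock_time`
#'   and numeric variable columns.
#' @param variables Numeric columns to summarise (default: all).
#' @return List: `region` (region x variable mean/SEM), `by_time`
#'   (region x clock time x variable means), `overall` (mean-of-medians
#'   per variable).
#' @export
summarize_daily <- function(series, variables = NULL) {
  num <- vapply(series, is.numeric, logical(1))
  if (is.null(variables))
    variables <- setdiff(names(series)[num], c("farm_id"))
  farm_means <- stats::aggregate(series[variables],
                                 by = list(farm_id = series$farm_id,
                                           region = series$region),
                                 FUN = mean)
  region_tab <- do.call(rbind, lapply(variables, function(v) {
    m <- tapply(farm_means[[v]], farm_means$region, mean)
    s <- tapply(farm_means[[v]], farm_means$region, stats::sd)
    n <- tapply(farm_means[[v]], farm_means$region, length)
    data.frame(variable = v, region = names(m), mean = unname(m),
               sem = unname(s / sqrt(n)))
  }))
  by_time <- stats::aggregate(series[variables],
                              by = list(region = series$region,
                                        clock_time = series$clock_time),
                              FUN = mean)
  overall <- do.call(rbind, lapply(variables, function(v) {
    mm <- mean_of_medians(farm_means[[v]], farm_means$region)
    data.frame(variable = v, mean_of_medians = mm$mean, sem = mm$sem)
  }))
  list(region = region_tab, by_time = by_time, overall = overall)
}

#' Run the full analysis pipeline on synthetic or supplied data
#'
#' Stages: simulate (skipped when `farms`/`readings` are supplied) ->
#' indices -> region comparisons -> housing clustering (+ cluster-wise
#' covariate-adjusted ANOVA) -> VIF-screened regressions. Each stage's
#' tables are written as UTF-8 CSV under `out_dir` as soon as the stage
#' finishes, so earlier outputs survive a later failure; the resolved
#' configuration and a run log are written beside them. Deterministic
#' given `config$seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Generator configuration ([generator_config()]).
#' @param farms Optional farm table (else generated).
#' @param readings Optional microclimate readings (else generated in
#'   physical mode).
#' @return Invisible list with the per-stage results and a `status`
#'   ("ok" or "partial"); stage errors are recorded, not re-thrown.
#' @export
run_pipeline <- function(out_dir, config = generator_config(),
                         farms = NULL, readings = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("shedclim pipeline, seed %d", config$seed),
                 sprintf("R %s", getRversion()))
  results <- list()
  status <- "ok"
  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) e)
    if (inherits(out, "error")) {
      status <<- "partial"
      log_lines <<- c(log_lines, sprintf("stage %s FAILED: %s", name,
                                         conditionMessage(out)))
      NULL
    } else {
      log_lines <<- c(log_lines, sprintf("stage %s ok", name))
      out
    }
  }

  results$farms <- stage("simulate-farms", {
    f <- if (is.null(farms)) generate_farms(config) else farms
    .write_csv(f, file.path(out_dir, "farms.csv"))
    f
  })
  results$readings <- stage("simulate-microclimate", {
    r <- if (is.null(readings)) {
      generate_microclimate(results$farms, mode = "physical", config = config)
    } else readings
    .write_csv(r, file.path(out_dir, "readings.csv"))
    r
  })
  results$indices <- stage("indices", {
    idx <- compute_indices(results$readings)
    .write_csv(idx, file.path(out_dir, "indices.csv"))
    idx
  })
  results$summaries <- stage("summaries", {
    s <- summarize_daily(results$indices,
                         variables = intersect(c("AT", "RH", "AS", "GT", "Tdp",
                                                 "THI", "HLI", "AHLU"),
                                               names(results$indices)))
    .write_csv(s$region, file.path(out_dir, "summary_region.csv"))
    .write_csv(s$by_time, file.path(out_dir, "summary_by_time.csv"))
    .write_csv(s$overall, file.path(out_dir, "summary_overall.csv"))
    s
  })
  results$comparisons <- stage("compare", {
    vars <- c("altitude", "MatCow", "FloorCow", "RidgeHei", "EaveHei",
              "SideOpen", "FanCow", "HoseCoFlo", "Housing", "RoofType",
              "RoofVent", "Sprinkler", "RoofCooler")
    comps <- lapply(vars, function(v)
      tryCatch(compare_regions(results$farms, v), error = function(e) NULL))
    names(comps) <- vars
    rows <- lapply(vars, function(v) {
      cp <- comps[[v]]
      if (is.null(cp)) return(NULL)
      data.frame(variable = v, test = cp$test, p = cp$p,
                 letters = if (is.null(cp$letters)) NA_character_ else
                   paste(names(cp$letters), cp$letters, sep = ":",
                         collapse = ";"))
    })
    .write_csv(do.call(rbind, rows), file.path(out_dir, "comparisons.csv"))
    comps
  })
  results$clustering <- stage("cluster", {
    cl <- cluster_housing(results$farms)
    .write_csv(data.frame(farm_id = names(cl$labels), cluster = cl$labels),
               file.path(out_dir, "clusters.csv"))
    .write_csv(cl$vtest_quantitative, file.path(out_dir, "vtest_quantitative.csv"))
    .write_csv(cl$vtest_categorical, file.path(out_dir, "vtest_categorical.csv"))
    cl
  })
  results$cluster_anova <- stage("cluster-anova", {
    merged <- merge_farm_responses(results$farms, results$indices,
                                   responses = c("AT", "RH", "AS", "HLI", "THI"))
    lbl <- results$clustering$labels[merged$farm_id]
    out <- lapply(c("AT", "RH", "AS", "HLI", "THI"), function(resp)
      tryCatch(cluster_twoway_anova(merged[[resp]], lbl, merged$altitude,
                                    merged$latitude_class),
               error = function(e) NULL))
    names(out) <- c("AT", "RH", "AS", "HLI", "THI")
    rows <- do.call(rbind, lapply(names(out), function(r) {
      if (is.null(out[[r]])) return(NULL)
      data.frame(response = r, F = out[[r]]$statistic, p = out[[r]]$p)
    }))
    if (!is.null(rows))
      .write_csv(rows, file.path(out_dir, "cluster_anova.csv"))
    out
  })
  results$regression <- stage("regress", {
    model_mc <- generate_microclimate(results$farms, mode = "model",
                                      config = config)
    merged <- merge_farm_responses(results$farms, model_mc)
    fits <- lapply(c("AT", "AS", "HLI", "THI"), function(resp)
      fit_microclimate_model(merged, resp))
    names(fits) <- c("AT", "AS", "HLI", "THI")
    coef_rows <- do.call(rbind, lapply(names(fits), function(r) {
      ct <- fits[[r]]$coefficients
      if (is.null(ct)) return(NULL)
      cbind(response = r, ct)
    }))
    .write_csv(coef_rows, file.path(out_dir, "regression_coefficients.csv"))
    .write_csv(do.call(rbind, lapply(names(fits), function(r)
      cbind(response = r, fits[[r]]$vif))),
      file.path(out_dir, "regression_vif.csv"))
    fits
  })

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  cfg_flat <- config
  cfg_flat$coefficients <- lapply(cfg_flat$coefficients, as.list)
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(cfg_flat), file.path(out_dir, "config.yaml"))
  } else {
    utils::capture.output(utils::str(cfg_flat)) |>
      writeLines(file.path(out_dir, "config.txt"))
  }
  results$status <- status
  invisible(results)
}
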