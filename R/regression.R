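# VIF-screened multivariable regression of microclimate responses on
# geography and housing, with backward elimination and diagnostics.

#' Build a numeric design matrix from predictor variables
#'
#' Treatment contrasts for qualitative predictors; `latitude_class` uses
#' north as reference, other qualitative variables use the alphabetically
#' first level as reference. No intercept column (added by the fitters).
#'
#' @param data Data.frame of predictor columns.
#' @param predictors Predictor column names.
#' @return Numeric matrix, one column per quantitative variable or
#'   non-reference category; attribute `term` maps columns back to
#'   source variables.
#' @export
build_design <- function(data, predictors) {
  stopifnot(all(predictors %in% names(data)))
  df <- data[, predictors, drop = FALSE]
  for (v in predictors) {
    if (!is.numeric(df[[v]])) {
      lev <- sort(unique(as.character(df[[v]])))
      if (v == "latitude_class") lev <- union("north", lev)
      df[[v]] <- factor(df[[v]], levels = lev)
    }
  }
  mm <- stats::model.matrix(~ ., data = df)
  X <- mm[, -1, drop = FALSE]
  term <- attr(mm, "assign")[-1]
  colnames(X) <- make.names(colnames(X), unique = TRUE)
  attr(X, "term") <- predictors[term]
  X
}

#' Variance inflation factors of design columns
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing column
#' j on all other columns (with intercept). Perfectly collinear columns
#' get `Inf`.
#'
#' @param X Numeric design matrix (>= 2 columns, more rows than columns).
#' @return Named numeric vector of VIFs (each >= 1).
#' @export
compute_vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("at least two predictor columns are required")
  if (nrow(X) <= ncol(X)) stop("more rows than columns are required")
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r <- fit$residuals
    tot <- sum((X[, j] - mean(X[, j]))^2)
    if (tot == 0) return(Inf)
    r2 <- 1 - sum(r^2) / tot
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Iterative VIF screen
#'
#' Removes the single highest-VIF column (ties broken by column order)
#' and recomputes, until every remaining column has VIF below the
#' threshold. The full removal order is logged.
#'
#' @param X Numeric design matrix.
#' @param threshold VIF threshold (default 5).
#' @return List: `design` (retained columns), `removed` (data.frame of
#'   step, column, VIF at removal), `vif` (final VIFs).
#' @export
vif_screen <- function(X, threshold = 5) {
  X <- as.matrix(X)
  removed <- data.frame(step = integer(), column = character(),
                        vif = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  while (ncol(X) >= 2) {
    v <- compute_vif(X)
    if (max(v) < threshold) break
    j <- which.max(v)  # first index on ties
    step <- step + 1L
    removed <- rbind(removed, data.frame(step = step,
                                         column = colnames(X)[j],
                                         vif = unname(v[j])))
    X <- X[, -j, drop = FALSE]
  }
  final_vif <- if (ncol(X) >= 2) compute_vif(X) else stats::setNames(1, colnames(X))
  list(design = X, removed = removed, vif = final_vif)
}

.coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], row.names = NULL)
}

#' Ordinary least squares fit with a classical coefficient table
#'
#' Thin wrapper over [stats::lm()] returning the coefficient table
#' (estimate, classical SE, t, two-sided p from the t distribution with
#' residual df) and R-squared in percent. Errors on rank-deficient
#' designs rather than silently dropping columns.
#'
#' @param y Response vector.
#' @param X Numeric design matrix or data.frame of predictors.
#' @return List of class `shed_ols`: `model` (the `lm`), `coefficients`,
#'   `r_squared_pct`, `n`.
#' @export
fit_ols <- function(y, X) {
  df <- data.frame(.y = y, as.data.frame(X), check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (fit$rank < ncol(df))
    stop("rank-deficient design: ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  structure(list(model = fit, coefficients = .coef_table(fit),
                 r_squared_pct = 100 * summary(fit)$r.squared,
                 n = nrow(df)), class = "shed_ols")
}

#' Backward elimination at a p-value threshold
#'
#' Repeatedly refits after removing the single worst term: the term
#' whose p exceeds `p_keep` by the most (multi-level qualitative terms
#' are judged and removed as a block, using the largest level p). Stops
#' when every remaining term has p at or below `p_keep`; an intercept-only
#' model is allowed.
#'
#' @param data Data.frame holding response and predictors.
#' @param response Response column name.
#' @param predictors Candidate predictor names (variables, not columns).
#' @param p_keep Retention threshold on coefficient p-values (default 0.1).
#' @return List: `fit` (`shed_ols` or NULL if intercept-only),
#'   `coefficients`, `r_squared_pct`, `eliminated` (data.frame: step,
#'   term, p at removal), `retained`.
#' @export
backward_eliminate <- function(data, response, predictors, p_keep = 0.1) {
  terms_left <- predictors
  eliminated <- data.frame(step = integer(), term = character(),
                           p = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    if (!length(terms_left)) {
      fit <- NULL
      break
    }
    X <- build_design(data, terms_left)
    fit <- fit_ols(data[[response]], X)
    ct <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    col_var <- attr(X, "term")[match(ct$term, colnames(X))]
    if (anyNA(col_var))
      stop("internal: coefficient terms do not align with design columns")
    term_p <- tapply(ct$p, col_var, max)
    worst <- names(term_p)[which.max(term_p)]
    if (term_p[[worst]] <= p_keep) break
    step <- step + 1L
    eliminated <- rbind(eliminated,
                        data.frame(step = step, term = worst,
                                   p = unname(term_p[[worst]])))
    terms_left <- setdiff(terms_left, worst)
  }
  list(fit = fit,
       coefficients = if (is.null(fit)) NULL else fit$coefficients,
       r_squared_pct = if (is.null(fit)) 0 else fit$r_squared_pct,
       eliminated = eliminated, retained = terms_left)
}

#' Residual and leverage diagnostics for a fitted model
#'
#' Internally standardised residuals and hat-matrix diagonals, with
#' flags for `|r| > r_limit` (default 3) and leverage above
#' `h_factor * p / n` (default 2 times the mean leverage).
#'
#' @param fit A `shed_ols` or `lm` object.
#' @param r_limit Standardised-residual flag threshold.
#' @param h_factor Leverage flag multiple of the mean leverage p/n.
#' @return Data.frame: observation, std_residual, leverage, flags.
#' @export
ols_diagnostics <- function(fit, r_limit = 3, h_factor = 2) {
  model <- if (inherits(fit, "shed_ols")) fit$model else fit
  r <- stats::rstandard(model)
  # a perfect fit has sigma = 0, making rstandard 0/0; report exact zeros
  if (summary(model)$sigma < 1e-12) r <- rep(0, length(r))
  h <- stats::hatvalues(model)
  p <- model$rank
  n <- length(r)
  data.frame(observation = seq_len(n), std_residual = unname(r),
             leverage = unname(h),
             flag_residual = abs(r) > r_limit,
             flag_leverage = h > h_factor * p / n,
             row.names = NULL)
}

#' Full microclimate regression for one response
#'
#' The study's modelling recipe: build the design from geography
#' (altitude, latitude) plus the twelve housing variables, screen out
#' multicollinear columns by iterative VIF (threshold 5), fit the
#' initial multivariable model, backward-eliminate to coefficient
#' p <= 0.1, and attach residual/leverage diagnostics.
#'
#' @param data Merged farm-by-response table (see
#'   [merge_farm_responses()]).
#' @param response One of the response columns, e.g. `"AT"`.
#' @param predictors Candidate predictors; default altitude, latitude
#'   and the housing variables present in `data`.
#' @param vif_threshold VIF screening threshold (default 5).
#' @param p_keep Backward-elimination retention threshold (default 0.1).
#' @return List of class `shed_regression`: `response`, `vif` (report
#'   with excluded flag), `screen` (removal log), `elimination` log,
#'   `coefficients`, `r_squared_pct`, `diagnostics`, `retained`.
#' @export
fit_microclimate_model <- function(data, response,
                                   predictors = intersect(
                                     c("altitude", "latitude_class", "MatCow",
                                       "FloorCow", "RidgeHei", "EaveHei",
                                       "SideOpen", "FanCow", "HoseCoFlo",
                                       "Housing", "RoofType", "RoofVent",
                                       "Sprinkler", "RoofCooler"),
                                     names(data)),
                                   vif_threshold = 5, p_keep = 0.1) {
  stopifnot(response %in% names(data), !response %in% predictors)
  constant <- vapply(predictors, function(v) length(unique(data[[v]])) < 2,
                     logical(1))
  if (any(constant)) {
    message("dropping constant predictor(s): ",
            paste(predictors[constant], collapse = ", "))
    predictors <- predictors[!constant]
  }
  X <- build_design(data, predictors)
  scr <- vif_screen(X, vif_threshold)
  kept_vars <- unique(attr(X, "term")[colnames(X) %in% colnames(scr$design)])
  vif_report <- data.frame(
    column = colnames(X),
    variable = attr(X, "term"),
    excluded = !colnames(X) %in% colnames(scr$design),
    row.names = NULL
  )
  vif_report$vif <- NA_real_
  vif_report$vif[match(names(scr$vif), vif_report$column)] <- unname(scr$vif)
  vif_report$vif[match(scr$removed$column, vif_report$column)] <- scr$removed$vif
  be <- backward_eliminate(data, response, kept_vars, p_keep)
  diag <- if (!is.null(be$fit)) ols_diagnostics(be$fit) else NULL
  structure(list(response = response, vif = vif_report,
                 screen = scr$removed, elimination = be$eliminated,
                 coefficients = be$coefficients,
                 r_squared_pct = be$r_squared_pct,
                 retained = be$retained, fit = be$fit,
                 diagnostics = diag), class = "shed_regression")
}

#' @export
print.shed_regression <- function(x, ...) {
  cat(sprintf("Microclimate model for %s (R^2 = %.1f%%)\n",
              x$response, x$r_squared_pct))
  if (nrow(x$screen))
    cat("  VIF-excluded:", paste(x$screen$column, collapse = ", "), "\n")
  if (!is.null(x$coefficients)) {
    print(x$coefficients, digits = 3)
  } else {
    cat("  no term retained (intercept-only)\n")
  }
  invisible(x)
}
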