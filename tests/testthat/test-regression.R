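# VIF screening, OLS fitting, backward elimination, diagnostics.

test_that("VIF is 1 for orthogonal, infinite for duplicated columns", {
  X <- cbind(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(compute_vif(X)), c(1, 1))
  X2 <- cbind(x = rnorm(20))
  X2 <- cbind(X2, y = X2[, 1])
  expect_equal(unname(compute_vif(X2)), c(Inf, Inf))
  expect_error(compute_vif(X[, 1, drop = FALSE]), "two predictor")
  expect_error(compute_vif(X[1:2, ]), "more rows")
})

test_that("VIF reproduces the closed form at correlation 0.9", {
  # construct columns with sample correlation exactly 0.9
  set.seed(2)
  z1 <- scale(rnorm(50))[, 1]
  z2 <- residuals(lm(rnorm(50) ~ z1))
  z2 <- z2 / sqrt(mean(z2^2) / mean(z1^2))
  x2 <- 0.9 * z1 + sqrt(1 - 0.81) * z2
  v <- compute_vif(cbind(z1, x2))
  expect_equal(unname(v), rep(1 / (1 - 0.81), 2), tolerance = 1e-8)
})

test_that("VIF of any column is at least 1", {
  set.seed(5)
  X <- matrix(rnorm(200), ncol = 5)
  expect_true(all(compute_vif(X) >= 1))
})

test_that("the screen is the identity when all VIFs are below threshold", {
  set.seed(3)
  X <- matrix(rnorm(200), ncol = 4, dimnames = list(NULL, letters[1:4]))
  scr <- vif_screen(X)
  expect_equal(colnames(scr$design), letters[1:4])
  expect_equal(nrow(scr$removed), 0)
})

test_that("exactly one of two duplicated columns survives, by column order", {
  x <- rnorm(30)
  X <- cbind(d1 = x, d2 = x, z = rnorm(30))
  scr <- vif_screen(X)
  expect_equal(scr$removed$column, "d1")  # earlier column removed on tie
  expect_true("d2" %in% colnames(scr$design))
})

test_that("the screen drops the region-confounded equipment block", {
  cfg <- generator_config(n_farms_per_region = 100, seed = 11)
  farms <- generate_farms(cfg)
  X <- build_design(farms, c("altitude", "latitude_class", "MatCow",
                             "FloorCow", "RidgeHei", "EaveHei", "SideOpen",
                             "FanCow", "HoseCoFlo", "Housing", "RoofType",
                             "RoofVent", "Sprinkler", "RoofCooler"))
  scr <- vif_screen(X)
  marker_block <- c("FanCow", "Housingtie.up", "RoofTypemetal",
                    "RoofVentyes", "RoofCooleryes", "Sprinkleryes")
  expect_gt(nrow(scr$removed), 0)
  expect_true(all(scr$removed$column %in% marker_block))
  expect_true(all(c("altitude", "latitude_classsouth", "EaveHei",
                    "FloorCow", "SideOpen") %in% colnames(scr$design)))
  expect_true(all(scr$vif < 5))
})

test_that("OLS matches the normal-equations oracle", {
  set.seed(6)
  X <- matrix(rnorm(150), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 1 + X %*% c(2, -1, 0.5) + rnorm(50, sd = 0.3)
  fit <- fit_ols(y, X)
  beta <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  expect_equal(fit$coefficients$estimate, as.vector(beta), tolerance = 1e-8)
  # exact fit: slope 2, R^2 = 100% ("perfect fit" warnings are the point)
  fit2 <- suppressWarnings(fit_ols(2 * X[, 1], X[, 1, drop = FALSE]))
  expect_equal(fit2$coefficients$estimate[2], 2)
  expect_equal(fit2$r_squared_pct, 100)
  # rank deficiency is an error, not a silent drop
  expect_error(fit_ols(y, cbind(X, a2 = X[, "a"])), "rank-deficient")
})

test_that("residuals are orthogonal to the design; hat sums to rank", {
  set.seed(8)
  X <- matrix(rnorm(120), ncol = 3)
  y <- X %*% c(1, 2, 3) + rnorm(40)
  fit <- fit_ols(y, X)
  r <- residuals(fit$model)
  expect_lt(max(abs(crossprod(cbind(1, X), r))), 1e-8)
  expect_equal(sum(hatvalues(fit$model)), 4, tolerance = 1e-10)
})

test_that("backward elimination keeps significant terms and drops noise", {
  set.seed(10)
  n <- 400
  df <- data.frame(x = rnorm(n), z = rnorm(n))
  df$y <- 2 * df$x + rnorm(n)
  # all-significant model is untouched
  be0 <- backward_eliminate(df, "y", "x")
  expect_equal(be0$retained, "x")
  expect_equal(nrow(be0$eliminated), 0)
  # a pure-noise predictor survives only when its p lands below the
  # retention threshold, i.e. with probability ~p_keep = 0.1; over 100
  # replicates the drop rate should be consistent with 90%
  dropped <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(x = rnorm(n), z = rnorm(n))
    d$y <- 2 * d$x + rnorm(n)
    be <- backward_eliminate(d, "y", c("x", "z"))
    !"z" %in% be$retained
  }, logical(1))
  expect_gte(mean(dropped), 0.82)
  expect_lte(mean(dropped), 0.98)
  # all-noise models collapse to intercept-only in most replicates
  empty <- vapply(1:60, function(s) {
    set.seed(1000 + s)
    d <- data.frame(a = rnorm(60), b = rnorm(60), y = rnorm(60))
    be <- backward_eliminate(d, "y", c("a", "b"))
    length(be$retained) == 0
  }, logical(1))
  expect_gt(mean(empty), 0.5)
})

test_that("diagnostics flag gross outliers and honour trace identities", {
  set.seed(12)
  x <- rnorm(40)
  y <- 3 * x + rnorm(40, sd = 0.5)
  y[7] <- y[7] + 15
  fit <- fit_ols(y, cbind(x = x))
  dg <- ols_diagnostics(fit)
  expect_true(dg$flag_residual[7])
  expect_equal(sum(dg$flag_residual), 1)
  expect_equal(sum(dg$leverage), 2, tolerance = 1e-10)
  # perfect fit reports zero residuals
  dg0 <- suppressWarnings(ols_diagnostics(fit_ols(2 * x, cbind(x = x))))
  expect_equal(dg0$std_residual, rep(0, 40))
})

test_that("full microclimate models recover generator coefficients", {
  targets <- list(AT = c(altitude = -0.004, latitude_classsouth = -1.43,
                         EaveHei = -0.87, FloorCow = -0.12),
                  AS = c(EaveHei = 0.14))
  for (s in 1:3) {
    cfg <- generator_config(n_farms_per_region = 100, seed = 100 + s)
    farms <- generate_farms(cfg)
    mc <- generate_microclimate(farms, "model", cfg)
    merged <- merge_farm_responses(farms, mc)
    for (resp in names(targets)) {
      fit <- suppressMessages(fit_microclimate_model(merged, resp))
      for (trm in names(targets[[resp]])) {
        est <- fit$coefficients$estimate[fit$coefficients$term == trm]
        expect_length(est, 1)
        expect_equal(est, unname(targets[[resp]][trm]), tolerance = 0.15)
      }
      expect_true(all(
        fit$coefficients$p[fit$coefficients$term %in% names(targets[[resp]])] <= 0.1))
    }
  }
})

test_that("the RH-like case of no surviving terms is reported, not an error", {
  set.seed(20)
  d <- data.frame(a = rnorm(50), b = rnorm(50), y = rnorm(50))
  be <- backward_eliminate(d, "y", c("a", "b"))
  if (length(be$retained) == 0) {
    expect_null(be$fit)
    expect_equal(be$r_squared_pct, 0)
  }
  expect_true(nrow(be$eliminated) + length(be$retained) == 2)
})
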