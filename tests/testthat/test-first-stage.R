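test_that("noiseless synthetic data reproduce the generating slopes to 1e-8", {
  tr <- synthetic_truth(n_clusters = 30, households_per_cluster = 10,
                        participation_rate = 1, seed = 13,
                        sigma11 = 0, sigma00 = 0, sigma10 = 0,
                        cluster_fe_sd = 0)
  rec <- simulate_survey(tr)$records
  cfg <- pipeline_config()
  f1 <- fit_unit_value_eq(rec, cfg, quiet = TRUE)
  f0 <- fit_budget_share_eq(rec, cfg, quiet = TRUE)
  expect_equal(f1$beta_hat, tr$beta1, tolerance = 1e-8)
  expect_equal(f0$beta_hat, tr$beta0, tolerance = 1e-8)
  # year effects are identified relative to the first wave
  expect_equal(unname(f1$year_effects),
               tr$year_effects1[-1] - tr$year_effects1[1], tolerance = 1e-6)
})

test_that("cluster absorption equals explicit dummy-variable OLS", {
  rec <- prepare_survey(oracle_records(), pipeline_config())
  cfg <- pipeline_config()
  f1 <- fit_unit_value_eq(rec, cfg, quiet = TRUE)

  # independent oracle: lm() with explicit cluster dummies
  d <- deatonuv:::build_design(rec, cfg)
  keep <- setdiff(colnames(d$X), f1$aliased)
  df <- data.frame(y = d$lnv, d$X[, keep], cluster = factor(d$cluster))
  ols <- stats::lm(y ~ . , data = df)
  for (nm in keep)
    expect_equal(unname(f1$coefficients[nm]), unname(stats::coef(ols)[nm]),
                 tolerance = 1e-8)

  f0 <- fit_budget_share_eq(rec, cfg, quiet = TRUE)
  df0 <- data.frame(y = d$w, d$X[, setdiff(colnames(d$X), f0$aliased)],
                    cluster = factor(d$cluster))
  ols0 <- stats::lm(y ~ ., data = df0)
  expect_equal(unname(f0$coefficients["ln_x"]),
               unname(stats::coef(ols0)["ln_x"]), tolerance = 1e-8)
})

test_that("budget-share slope is invariant to a location shift of the share", {
  rec <- prepare_survey(oracle_records(), pipeline_config())
  cfg <- pipeline_config()
  f0 <- fit_budget_share_eq(rec, cfg, quiet = TRUE)
  rec2 <- rec
  rec2$budget_share <- rec2$budget_share + 0.37
  f0b <- fit_budget_share_eq(rec2, cfg, quiet = TRUE)
  expect_equal(f0$beta_hat, f0b$beta_hat, tolerance = 1e-10)
  expect_equal(unname(f0$coefficients["n_male"]),
               unname(f0b$coefficients["n_male"]), tolerance = 1e-10)
})

test_that("residuals are orthogonal to the included regressors", {
  rec <- simulate_survey(tiny_truth())$records
  cfg <- pipeline_config()
  f0 <- fit_budget_share_eq(rec, cfg, quiet = TRUE)
  d <- deatonuv:::build_design(rec, cfg)
  g <- match(d$cluster, unique(d$cluster))
  Xd <- apply(d$X, 2, function(v) v - ave(v, g))
  dots <- crossprod(Xd, f0$residuals) / nrow(Xd)
  expect_lt(max(abs(dots)), 1e-6)
})

test_that("default-scale slopes are consistent (within 3 SE at one draw)", {
  rec <- simulate_survey(synthetic_truth(seed = 314))$records
  cfg <- pipeline_config()
  fs <- first_stage(rec, cfg, quiet = TRUE)
  expect_lt(abs(fs$eq1$beta_hat - 0.78), 3 * fs$eq1$se["ln_x"])
  expect_lt(abs(fs$eq0$beta_hat - 0.15 * 0.02), 3 * fs$eq0$se["ln_x"])
  # F test for the absorbed cluster terms is reported with sane df
  expect_gt(fs$eq1$f_cluster$F, 1)
  # cluster-constant covariates (urban) shift one df from the dummies
  expect_equal(fs$eq0$f_cluster$df1,
               length(unique(rec$cluster_id)) - 1 - length(fs$eq0$aliased))
})

test_that("year-only mode drops the absorbers and keeps the design full rank", {
  rec <- prepare_survey(oracle_records(), pipeline_config())
  cfg <- pipeline_config(fe_mode_eq1 = "year_only")
  f1 <- fit_unit_value_eq(rec, cfg, quiet = TRUE)
  expect_equal(f1$n_absorbed, 0)
  expect_true("(Intercept)" %in% names(f1$coefficients))
  # a duplicated regressor is a genuine singularity without absorbers
  rec2 <- rec
  rec2$n_male <- rec2$hh_size  # ln_hhsize and hh_size copies collide in spirit
  d <- deatonuv:::build_design(rec2, cfg)
  d$X[, "n_male"] <- d$X[, "ln_hhsize"]
  expect_error(
    deatonuv:::fit_unit_value_eq_design(d, cfg, quiet = TRUE),
    class = "deatonuv_estimation_error")
})

test_that("residual covariances: identical series and independence limits", {
  rec <- simulate_survey(tiny_truth())$records
  cfg <- pipeline_config()
  f1 <- fit_unit_value_eq(rec, cfg, quiet = TRUE)
  s_same <- residual_covariances(f1, f1, cfg)
  expect_equal(s_same$sigma10, s_same$sigma11, tolerance = 1e-12)

  # independent errors: sigma10_hat within 3 Monte-Carlo SEs of zero
  tr <- synthetic_truth(n_clusters = 1200, participation_rate = 1,
                        sigma10 = 0, rho_time = 0, seed = 55)
  recI <- simulate_survey(tr)$records
  fsI <- first_stage(recI, cfg, quiet = TRUE)
  n <- fsI$sigma$n_both
  mc_se <- sqrt(tr$sigma11 * tr$sigma00 / n)
  expect_lt(abs(fsI$sigma$sigma10), 3 * mc_se)
})

test_that("temporal clustering scales moments by the serial-correlation factor", {
  # hand-computable example: 6 households x 2 waves, known residuals
  fake_fit <- function(r, hh) {
    list(residuals = r, household = hh, rows = seq_along(r),
         n = length(r), df_resid = length(r) - 1)
  }
  hh <- rep(letters[1:6], each = 2)
  r1 <- c(1, 2, -1, 1, 2, -1, 0, 1, 1, 1, -2, 1)
  r0 <- c(2, 0, 1, -1, 0, 1, 1, 0, -1, 1, 0, 2)
  f1 <- fake_fit(r1, hh); f0 <- fake_fit(r0, hh)
  s_t <- residual_covariances(f1, f0, pipeline_config(temporal_clustering = TRUE))
  s_n <- residual_covariances(f1, f0, pipeline_config(temporal_clustering = FALSE))
  # naive: sum(r1 * r0) / 11 = (2 - 2 - 1 + 0 + 0 + 2) / 11
  expect_equal(s_n$sigma10, 1 / 11)
  # household sums s1 = (3, 0, 1, 1, 2, -1), s0 = (2, 0, 1, 1, 0, 2):
  # sum(s1 * s0) = 6 + 0 + 1 + 1 + 0 - 2 = 6
  expect_equal(s_t$sigma10, 6 / 11)
  expect_equal(s_t$sigma11, (9 + 0 + 1 + 1 + 4 + 1) / 11)
  expect_equal(s_n$sigma11, sum(r1^2) / 11)

  # on AR(1) synthetic errors the clustered estimator expands sigma11 by
  # about 1 + (4 rho + 2 rho^2) / 3 for three waves
  tr <- synthetic_truth(n_clusters = 500, participation_rate = 1,
                        rho_time = 0.6, seed = 77)
  recA <- simulate_survey(tr)$records
  fsA <- first_stage(recA, pipeline_config(), quiet = TRUE)
  factor_expected <- 1 + (4 * 0.6 + 2 * 0.36) / 3
  expect_equal(fsA$sigma$sigma11 / fsA$sigma$sigma11_naive,
               factor_expected, tolerance = 0.1)
})

test_that("covariance estimation refuses a too-small intersection sample", {
  rec <- prepare_survey(toy_records(), pipeline_config())
  cfg <- pipeline_config()
  fake <- list(residuals = rnorm(5), household = letters[1:5], rows = 1:5,
               n = 5, df_resid = 4)
  expect_error(residual_covariances(fake, fake, cfg),
               class = "deatonuv_estimation_error")
})

test_that("survey-weighted regression matches weighted lm with dummies", {
  rec <- prepare_survey(oracle_records(), pipeline_config())
  cfg <- pipeline_config(weighted_regression = TRUE)
  f1 <- fit_unit_value_eq(rec, cfg, quiet = TRUE)
  d <- deatonuv:::build_design(rec, cfg)
  keep <- setdiff(colnames(d$X), f1$aliased)
  ols <- stats::lm(y ~ ., weights = d$weight,
                   data = data.frame(y = d$lnv, d$X[, keep],
                                     cluster = factor(d$cluster)))
  expect_equal(unname(f1$coefficients["ln_x"]),
               unname(stats::coef(ols)["ln_x"]), tolerance = 1e-8)
  f1u <- fit_unit_value_eq(rec, pipeline_config(), quiet = TRUE)
  expect_false(isTRUE(all.equal(f1$beta_hat, f1u$beta_hat)))
})
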