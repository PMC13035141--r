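# First stage: fixed-effects OLS of log unit value (consumers) and budget
# share (all records) on household resources, demographics and year dummies,
# with cluster absorption, household-clustered standard errors, purged values
# for cluster aggregation, and residual (co)variance estimates.

# Design matrix on the Table-style covariate list. Education logs use
# log(years + 1) so zero schooling is representable.
build_design <- function(records, config = pipeline_config()) {
  stopifnot(all(c("budget_share", "consumer", "quintile") %in% names(records)))
  yr <- sort(unique(records$year))
  X <- cbind(
    ln_x = log(records$total_expenditure),
    ln_hhsize = log(records$hh_size),
    ln_hhsize2 = log(records$hh_size)^2,
    sh_m0_5 = records$sh_m0_5, sh_f0_5 = records$sh_f0_5,
    sh_m6_17 = records$sh_m6_17, sh_f6_17 = records$sh_f6_17,
    sh_m18_49 = records$sh_m18_49, sh_f18_49 = records$sh_f18_49,
    sh_m_gt49 = records$sh_m_gt49,
    head_female = records$head_female,
    ln_head_edu = log1p(records$head_edu),
    ln_head_edu2 = log1p(records$head_edu)^2,
    n_male = records$n_male,
    ln_max_edu = log1p(records$edu_max),
    ln_max_edu2 = log1p(records$edu_max)^2,
    q2 = as.numeric(records$quintile == 2),
    q3 = as.numeric(records$quintile == 3),
    q4 = as.numeric(records$quintile == 4),
    q5 = as.numeric(records$quintile == 5),
    urban = records$urban
  )
  if (length(yr) > 1) {
    Y <- do.call(cbind, lapply(yr[-1], function(y) as.numeric(records$year == y)))
    colnames(Y) <- paste0("yr_", yr[-1])
    X <- cbind(X, Y)
  }
  list(X = X,
       lnv = ifelse(records$consumer, log(records$unit_value), NA_real_),
       w = records$budget_share,
       consumer = records$consumer,
       cluster = as.character(records$cluster_id),
       household = as.character(records$household_id),
       year = records$year,
       weight = records$weight)
}

# Weighted/unweighted OLS with optional one-way (cluster) absorption.
# Aliased columns: under absorption, columns constant within clusters are
# indistinguishable from the fixed effects and are dropped with a note;
# without absorption a rank-deficient design is an error naming the columns.
fit_fe_ols <- function(y, X, cluster = NULL, household, weights = NULL,
                       absorb = TRUE, f_test = TRUE, quiet = FALSE) {
  n <- length(y)
  if (is.null(weights)) wt <- rep(1, n) else wt <- weights
  if (absorb && is.null(cluster)) stop_estimation("absorption requires cluster ids")

  if (absorb) {
    g <- match(cluster, unique(cluster))
    G <- max(g)
    swg <- as.vector(rowsum(wt, g))
    demean <- function(v) v - (as.vector(rowsum(v * wt, g)) / swg)[g]
    Xd <- apply(X, 2, demean)
    yd <- demean(y)
  } else {
    G <- 0L
    X <- cbind(`(Intercept)` = 1, X)
    Xd <- X; yd <- y
  }
  sw <- sqrt(wt)
  fit <- stats::lm.fit(Xd * sw, yd * sw)
  coefs <- fit$coefficients
  aliased <- names(coefs)[is.na(coefs)]
  if (length(aliased)) {
    if (!absorb)
      stop_estimation("singular design; collinear column(s): %s",
                      paste(aliased, collapse = ", "))
    if (!quiet)
      message("fit_fe_ols: column(s) absorbed by cluster effects (dropped): ",
              paste(aliased, collapse = ", "))
  }
  coef0 <- ifelse(is.na(coefs), 0, coefs)
  k <- fit$rank
  resid <- as.vector(yd - Xd %*% coef0)           # within residuals
  rss <- sum(wt * resid^2)
  df_resid <- n - k - max(G - 1, 0) - as.integer(absorb)  # n - k - G (absorb) or n - k
  if (df_resid < 1) stop_estimation("no residual degrees of freedom")

  # household-clustered (CR1) covariance on non-aliased columns
  keep <- !is.na(coefs)
  Xk <- Xd[, keep, drop = FALSE] * sw
  XtXinv <- chol2inv(chol(crossprod(Xk)))
  hgrp <- match(household, unique(household))
  U <- rowsum(Xk * (resid * sw), hgrp)
  meat <- crossprod(U)
  Gh <- nrow(U)
  cr1 <- (Gh / (Gh - 1)) * ((n - 1) / df_resid)
  V <- cr1 * XtXinv %*% meat %*% XtXinv
  se <- rep(NA_real_, length(coefs)); names(se) <- names(coefs)
  se[keep] <- sqrt(diag(V))

  tss <- sum(wt * (y - weighted_mean(y, wt))^2)
  r2 <- 1 - rss / tss                              # full model incl. absorbed FE
  r2_adj <- 1 - (1 - r2) * (n - 1) / df_resid

  fstat <- NULL
  if (absorb && f_test && G > 1) {
    f0 <- stats::lm.fit(cbind(1, X)[, , drop = FALSE] * sw, y * sw)
    rss0 <- sum(wt * f0$residuals^2)
    k0 <- f0$rank
    df1 <- (n - k0) - df_resid                     # independent cluster constraints
    if (df1 > 0 && rss > 0)
      fstat <- list(F = ((rss0 - rss) / df1) / (rss / df_resid),
                    df1 = df1, df2 = df_resid)
  }

  cluster_fe <- NULL
  if (absorb) {
    raw_fe <- y - as.vector(X %*% coef0)
    cluster_fe <- as.vector(rowsum(raw_fe * wt, g) / swg)
    names(cluster_fe) <- unique(cluster)
  }

  list(coefficients = coefs, coef0 = coef0, se = se, residuals = resid,
       purged = y - as.vector(X %*% coef0), cluster_fe = cluster_fe,
       aliased = aliased, n = n, k = k, n_absorbed = G,
       df_resid = df_resid, rss = rss, r2 = r2, r2_adj = r2_adj,
       f_cluster = fstat)
}

eq_fit_result <- function(fit, rows, household, cluster, eq) {
  structure(list(
    eq = eq,
    coefficients = fit$coefficients, se = fit$se,
    beta_hat = unname(fit$coefficients["ln_x"]),
    year_effects = fit$coefficients[grep("^yr_", names(fit$coefficients))],
    residuals = fit$residuals, purged = fit$purged,
    cluster_fe = fit$cluster_fe, aliased = fit$aliased,
    rows = rows, household = household, cluster = cluster,
    n = fit$n, k = fit$k, n_absorbed = fit$n_absorbed,
    df_resid = fit$df_resid, r2 = fit$r2, r2_adj = fit$r2_adj,
    f_cluster = fit$f_cluster
  ), class = "deatonuv_eq_fit")
}

#' First-stage unit-value regression
#'
#' OLS of the log unit value on log total expenditure, household demographics
#' and year dummies over consuming records, with cluster effects absorbed by
#' default (`config$fe_mode_eq1`). Standard errors are clustered by household
#' to allow for serial correlation of the errors across waves.
#'
#' @param records prepared records ([prepare_survey()]).
#' @param config a [pipeline_config()].
#' @param quiet suppress notes about dropped clusters/absorbed columns.
#' @return an object of class `deatonuv_eq_fit` with coefficients, clustered
#'   SEs, within residuals, purged values (outcome minus estimated
#'   expenditure/demographic/year components, retaining cluster-level price
#'   variation), fit statistics and the cluster-dummy F test.
#' @export
fit_unit_value_eq <- function(records, config = pipeline_config(),
                              quiet = FALSE) {
  d <- build_design(records, config)
  fit_unit_value_eq_design(d, config, quiet)
}

fit_unit_value_eq_design <- function(d, config, quiet = FALSE, f_test = TRUE) {
  rows <- which(d$consumer)
  if (length(rows) < 2 || length(unique(d$cluster[rows])) < 2)
    stop_estimation("need at least 2 consuming records in at least 2 clusters")
  n_dropped <- length(setdiff(unique(d$cluster), unique(d$cluster[rows])))
  if (n_dropped && !quiet)
    message(sprintf(
      "fit_unit_value_eq: %d cluster(s) without consumers contribute no rows",
      n_dropped))
  wts <- if (config$weighted_regression) d$weight[rows] else NULL
  fit <- fit_fe_ols(d$lnv[rows], d$X[rows, , drop = FALSE],
                    cluster = d$cluster[rows], household = d$household[rows],
                    weights = wts,
                    absorb = config$fe_mode_eq1 == "cluster_and_year",
                    f_test = f_test, quiet = quiet)
  eq_fit_result(fit, rows, d$household[rows], d$cluster[rows], "unit_value")
}

#' First-stage budget-share regression
#'
#' OLS of the cigarette budget share on the same covariates over the entire
#' sample (zero shares of non-consuming households included), with cluster
#' fixed effects absorbed and household-clustered standard errors.
#'
#' @inheritParams fit_unit_value_eq
#' @return an object of class `deatonuv_eq_fit`; see [fit_unit_value_eq()].
#' @export
fit_budget_share_eq <- function(records, config = pipeline_config(),
                                quiet = FALSE) {
  d <- build_design(records, config)
  fit_budget_share_eq_design(d, config, quiet)
}

fit_budget_share_eq_design <- function(d, config, quiet = FALSE, f_test = TRUE) {
  n <- length(d$w)
  if (n < 2 || length(unique(d$cluster)) < 2)
    stop_estimation("need at least 2 records in at least 2 clusters")
  wts <- if (config$weighted_regression) d$weight else NULL
  fit <- fit_fe_ols(d$w, d$X, cluster = d$cluster, household = d$household,
                    weights = wts, absorb = TRUE, f_test = f_test,
                    quiet = quiet)
  eq_fit_result(fit, seq_len(n), d$household, d$cluster, "budget_share")
}

#' Residual variance and covariance of the first-stage errors
#'
#' Degrees-of-freedom-corrected estimates of `sigma11` (unit-value equation,
#' consumer sample), `sigma00` (budget-share equation, full sample) and
#' `sigma10` (their covariance on the intersection sample: consuming records,
#' where both residuals exist). With `config$temporal_clustering = TRUE`
#' (default) residuals are summed within household across waves before the
#' cross products are averaged, so serial correlation of the errors inflates
#' or deflates the estimates exactly as it inflates the error variance of a
#' cluster mean. Degrees of freedom are `n - k - G` (regressors plus absorbed
#' effects).
#'
#' @param fit1 fitted unit-value equation ([fit_unit_value_eq()]).
#' @param fit0 fitted budget-share equation ([fit_budget_share_eq()]).
#' @param config a [pipeline_config()].
#' @return named list `sigma11`, `sigma00`, `sigma10`, plus naive
#'   (non-temporally-clustered) versions and the intersection size `n_both`.
#' @export
residual_covariances <- function(fit1, fit0, config = pipeline_config()) {
  r1 <- fit1$residuals
  r0_all <- fit0$residuals
  pos <- match(fit1$rows, fit0$rows)
  if (anyNA(pos))
    stop_estimation("unit-value sample is not contained in the share sample")
  r0 <- r0_all[pos]
  n_both <- length(r1)
  if (n_both < 10)
    stop_estimation("intersection sample has %d records (< 10)", n_both)

  df11 <- fit1$df_resid
  df00 <- fit0$df_resid
  df10 <- n_both - (fit1$n - fit1$df_resid)   # n_both - k1 - G1

  cluster_sum <- function(r, h) as.vector(rowsum(r, match(h, unique(h))))
  if (config$temporal_clustering) {
    s1 <- cluster_sum(fit1$residuals, fit1$household)
    s0f <- cluster_sum(fit0$residuals, fit0$household)
    sigma11 <- sum(s1^2) / df11
    sigma00 <- sum(s0f^2) / df00
    h_int <- fit1$household
    s1i <- cluster_sum(r1, h_int)
    s0i <- as.vector(rowsum(r0, match(h_int, unique(h_int))))
    sigma10 <- sum(s1i * s0i) / max(df10, 1)
  } else {
    sigma11 <- sum(fit1$residuals^2) / df11
    sigma00 <- sum(fit0$residuals^2) / df00
    sigma10 <- sum(r1 * r0) / max(df10, 1)
  }
  list(sigma11 = sigma11, sigma00 = sigma00, sigma10 = sigma10,
       sigma11_naive = sum(fit1$residuals^2) / df11,
       sigma00_naive = sum(fit0$residuals^2) / df00,
       sigma10_naive = sum(r1 * r0) / max(df10, 1),
       n_both = n_both)
}

#' Fit both first-stage equations
#'
#' Convenience wrapper running [fit_unit_value_eq()],
#' [fit_budget_share_eq()] and [residual_covariances()].
#'
#' @inheritParams fit_unit_value_eq
#' @return an object of class `first_stage_fit`: `eq1`, `eq0`, `sigma`.
#' @export
first_stage <- function(records, config = pipeline_config(), quiet = FALSE) {
  d <- build_design(records, config)
  first_stage_design(d, config, quiet)
}

first_stage_design <- function(d, config, quiet = FALSE, f_test = TRUE) {
  eq1 <- fit_unit_value_eq_design(d, config, quiet, f_test = f_test)
  eq0 <- fit_budget_share_eq_design(d, config, quiet, f_test = f_test)
  structure(list(eq1 = eq1, eq0 = eq0,
                 sigma = residual_covariances(eq1, eq0, config)),
            class = "first_stage_fit")
}

#' @export
print.deatonuv_eq_fit <- function(x, ...) {
  cat(sprintf("First-stage %s regression (n = %d, clusters absorbed = %d)\n",
              x$eq, x$n, x$n_absorbed))
  cat(sprintf("  slope on log total expenditure: %.4f (SE %.4f)\n",
              x$beta_hat, x$se["ln_x"]))
  cat(sprintf("  R2 = %.3f (adj. %.3f)", x$r2, x$r2_adj))
  if (!is.null(x$f_cluster))
    cat(sprintf(" | cluster F(%d, %d) = %.3f",
                x$f_cluster$df1, x$f_cluster$df2, x$f_cluster$F))
  cat("\n")
  invisible(x)
}

#' @export
print.first_stage_fit <- function(x, ...) {
  print(x$eq1); print(x$eq0)
  cat(sprintf("  sigma11 = %.4g, sigma00 = %.4g, sigma10 = %.4g (n_both = %d)\n",
              x$sigma$sigma11, x$sigma$sigma00, x$sigma$sigma10,
              x$sigma$n_both))
  invisible(x)
}

#' Coefficient table of a first-stage fit
#'
#' @param fit a `deatonuv_eq_fit`.
#' @return tibble with `term`, `estimate`, `se`, `stars` (normal-approximation
#'   significance at 10/5/1% based on household-clustered SEs).
#' @export
coef_table <- function(fit) {
  est <- fit$coefficients
  se <- fit$se
  z <- abs(est / se)
  stars <- ifelse(is.na(z), "", ifelse(z > stats::qnorm(0.995), "***",
                  ifelse(z > stats::qnorm(0.975), "**",
                  ifelse(z > stats::qnorm(0.95), "*", ""))))
  tibble::tibble(term = names(est), estimate = unname(est),
                 se = unname(se), stars = stars)
}
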