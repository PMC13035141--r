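# Synthetic clustered panel survey with known generating parameters.
#
# The generator draws cluster-common log prices and cluster fixed effects,
# household demographics and log total expenditure, smoking participation at
# the household level, and jointly correlated AR(1) errors for the unit-value
# and budget-share equations; observed quantities follow from the accounting
# identities c = w * x and q = c / v.

#' Generating parameters of a synthetic survey
#'
#' Defines the structural model behind [simulate_survey()]:
#' \deqn{\ln v = \alpha_1 + \beta_1 \ln x + Z\gamma_1 + \psi \ln\pi_c + y_t + u^1}
#' \deqn{w = \alpha_0 + \beta_0 \ln x + Z\gamma_0 + \theta \ln\pi_c + f_c + y_t + u^0}
#' for consuming households, with \eqn{w = q = c = 0} for non-consumers.
#' `beta0`, `theta`, `gamma0` and the share-equation intercept are on the
#' conditional (consumer) scale; on the full estimation sample, slopes are
#' attenuated by the participation rate.
#'
#' Defaults emulate a three-wave national household panel: 400 clusters of 15
#' households followed over 3 waves (18,000 records), ~15% of households
#' consuming, a mean conditional budget share near 0.05, a quality (total
#' expenditure) elasticity of the unit value of 0.78, and cluster price
#' dispersion of 25 log points. The default `psi` is close to 1 (unit values
#' track prices nearly one-for-one, with mild quality shading) and `theta`
#' puts the structural price elasticity in the inelastic range typical of
#' cigarette demand; [implied_elasticities()] gives both the structural
#' elasticities and the exact large-sample limit of the two-stage estimator
#' under these parameters.
#'
#' @param alpha1,alpha0 intercepts of the two equations.
#' @param beta1 quality elasticity: slope of log unit value on log total
#'   expenditure.
#' @param beta0 slope of the (conditional) budget share on log total
#'   expenditure.
#' @param gamma1,gamma0 named covariate slope vectors; names must be design
#'   columns (e.g. `ln_hhsize`, `n_male`, `head_female`, `urban`).
#' @param psi price elasticity of the unit value.
#' @param theta price slope of the (conditional) budget share.
#' @param cluster_price_sd SD of the cluster log price \eqn{\ln\pi_c}.
#' @param cluster_fe_sd SD of the cluster effect \eqn{f_c} in the share
#'   equation.
#' @param year_effects1,year_effects0 per-wave shifts (first wave is the
#'   baseline, 0).
#' @param sigma11,sigma00,sigma10 variances and covariance of the
#'   contemporaneous errors \eqn{(u^1, u^0)}.
#' @param rho_time AR(1) autocorrelation of each error across waves within a
#'   household (applies to both equations and their cross-correlation).
#' @param participation_rate fraction of households that consume; drawn at
#'   household level and constant across waves (smoking status is highly
#'   persistent over one-year gaps).
#' @param n_clusters,households_per_cluster,n_waves design sizes.
#' @param seed integer seed.
#' @return a list of class `deaton_truth`.
#' @export
#' @examples
#' tr <- synthetic_truth(n_clusters = 20, seed = 42)
#' sim <- simulate_survey(tr)
#' nrow(sim$records)
synthetic_truth <- function(alpha1 = -3.65,
                            beta1 = 0.78,
                            gamma1 = c(ln_hhsize = -0.5774, n_male = 0.0317,
                                       head_female = 0.0624, urban = -0.0931),
                            alpha0 = -0.0885,
                            beta0 = 0.02,
                            gamma0 = c(ln_hhsize = -0.010, n_male = -0.0007,
                                       head_female = -0.0035, urban = -0.0018),
                            psi = 0.9951,
                            theta = 0.01684,
                            cluster_price_sd = 0.25,
                            cluster_fe_sd = 0.002,
                            year_effects1 = c(0, 0.10, 0.08),
                            year_effects0 = c(0, -0.005, -0.007),
                            sigma11 = 0.25,
                            sigma00 = 0.00015,
                            sigma10 = 0.00122,
                            rho_time = 0.3,
                            participation_rate = 0.15,
                            n_clusters = 400,
                            households_per_cluster = 15,
                            n_waves = 3,
                            seed = 20160418L) {
  truth <- structure(list(
    alpha1 = alpha1, beta1 = beta1, gamma1 = gamma1,
    alpha0 = alpha0, beta0 = beta0, gamma0 = gamma0,
    psi = psi, theta = theta,
    cluster_price_sd = cluster_price_sd, cluster_fe_sd = cluster_fe_sd,
    year_effects1 = year_effects1, year_effects0 = year_effects0,
    sigma11 = sigma11, sigma00 = sigma00, sigma10 = sigma10,
    rho_time = rho_time, participation_rate = participation_rate,
    n_clusters = as.integer(n_clusters),
    households_per_cluster = as.integer(households_per_cluster),
    n_waves = as.integer(n_waves), seed = as.integer(seed)
  ), class = "deaton_truth")
  validate_truth(truth)
  truth
}

validate_truth <- function(truth) {
  with(truth, {
    if (sigma11 < 0 || sigma00 < 0)
      stop_config("error variances must be non-negative")
    if (abs(sigma10) > sqrt(sigma11 * sigma00) + 1e-12)
      stop_config("|sigma10| must not exceed sqrt(sigma11 * sigma00)")
    if (participation_rate <= 0 || participation_rate > 1)
      stop_config("participation_rate must be in (0, 1]")
    if (abs(rho_time) >= 1) stop_config("|rho_time| must be < 1")
    if (length(year_effects1) != n_waves || length(year_effects0) != n_waves)
      stop_config("year_effects must have one entry per wave")
    if (n_clusters < 1 || households_per_cluster < 1 || n_waves < 1)
      stop_config("design sizes must be positive")
  })
  invisible(truth)
}

# Stationary bivariate AR(1) draws: T waves of (u1, u0) per household, with
# contemporaneous covariance Sigma and common autocorrelation rho. Returns a
# list of two n x T matrices.
draw_ar1_errors <- function(n, T, sigma11, sigma00, sigma10, rho) {
  chol_draw <- function(n) {
    if (sigma11 == 0 && sigma00 == 0)
      return(cbind(numeric(n), numeric(n)))
    S <- matrix(c(sigma11, sigma10, sigma10, sigma00), 2)
    # tolerate semidefinite corner cases (one zero variance)
    ev <- eigen(S, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
    matrix(stats::rnorm(2 * n), n, 2) %*% t(L)
  }
  u1 <- matrix(0, n, T); u0 <- matrix(0, n, T)
  z <- chol_draw(n)
  u1[, 1] <- z[, 1]; u0[, 1] <- z[, 2]
  if (T > 1) {
    sc <- sqrt(1 - rho^2)
    for (t in 2:T) {
      e <- chol_draw(n) * sc
      u1[, t] <- rho * u1[, t - 1] + e[, 1]
      u0[, t] <- rho * u0[, t - 1] + e[, 2]
    }
  }
  list(u1 = u1, u0 = u0)
}

#' Simulate a clustered panel expenditure survey
#'
#' Generates a canonical household-by-wave table from a [synthetic_truth()]
#' model. Cluster log prices and cluster effects are drawn once per cluster
#' (prices are constant across waves; common temporal movement is carried by
#' the year effects); participation is a household-level draw independent of
#' prices and expenditure; consumer errors are jointly correlated across
#' equations and AR(1)-persistent across waves. Identical seeds give
#' byte-identical tables.
#'
#' @param truth a [synthetic_truth()].
#' @param prepare run [prepare_survey()] on the result (default `TRUE`).
#' @param return_latent also return the latent cluster table (`ln_pi`, `f_c`)
#'   and per-record errors, for diagnostics and calibration tests.
#' @param config a [pipeline_config()] used only when `prepare = TRUE`.
#' @return list with `records` (tibble), `truth`, and if requested `latent`
#'   (list of `clusters` and `errors` tibbles). Consumer budget shares falling
#'   outside (0, 1) are clamped to a narrow interior range; if more than 1% of
#'   consumers need clamping the parameter set is rejected with an error.
#' @export
simulate_survey <- function(truth = synthetic_truth(), prepare = TRUE,
                            return_latent = FALSE,
                            config = pipeline_config()) {
  validate_truth(truth)
  with_preserved_seed(truth$seed, {
    C <- truth$n_clusters; H <- truth$households_per_cluster
    T <- truth$n_waves
    nh <- C * H                      # households
    n <- nh * T                      # records

    cl_id <- sprintf("C%03d", seq_len(C))
    ln_pi <- stats::rnorm(C, 0, truth$cluster_price_sd)
    f_c <- stats::rnorm(C, 0, truth$cluster_fe_sd)
    urban_c <- stats::rbinom(C, 1, 0.35)
    mu_x_c <- stats::rnorm(C, 0, 0.22)

    hh_cluster <- rep(seq_len(C), each = H)
    hh_id <- sprintf("H%05d", seq_len(nh))
    hh_size <- pmin(1L + stats::rpois(nh, 4), 22L)
    # age-sex composition: multinomial member counts at national frequencies
    grp_p <- c(0.041, 0.036, 0.131, 0.121, 0.184, 0.251, 0.118, 0.118)
    comp <- t(vapply(hh_size,
                     function(k) stats::rmultinom(1, k, grp_p)[, 1],
                     integer(8)))
    shares <- comp / hh_size
    n_male <- comp[, 1] + comp[, 3] + comp[, 5] + comp[, 7]
    head_female <- stats::rbinom(nh, 1, 0.21)
    head_edu <- pmin(stats::rpois(nh, 4), 15L)
    edu_max <- pmin(head_edu + stats::rpois(nh, 3), 15L)
    smoker <- stats::rbinom(nh, 1, truth$participation_rate) == 1
    weight_h <- exp(stats::rnorm(nh, 0, 0.3))

    lnx_h <- 8.08 + 0.25 * (log(hh_size) - log(5)) + mu_x_c[hh_cluster] +
      stats::rnorm(nh, 0, 0.48)

    err <- draw_ar1_errors(nh, T, truth$sigma11, truth$sigma00,
                           truth$sigma10, truth$rho_time)

    # expand household rows over waves (household-major ordering)
    idx <- rep(seq_len(nh), each = T)
    wave <- rep(seq_len(T), times = nh)
    lnx <- lnx_h[idx] + stats::rnorm(n, 0, 0.15)
    x <- exp(lnx)

    covars <- cbind(ln_hhsize = log(hh_size), n_male = n_male,
                    head_female = head_female, urban = urban_c[hh_cluster])
    zg1 <- drop(covars[, names(truth$gamma1), drop = FALSE] %*% truth$gamma1)
    zg0 <- drop(covars[, names(truth$gamma0), drop = FALSE] %*% truth$gamma0)

    u1 <- as.vector(t(err$u1)); u0 <- as.vector(t(err$u0))
    lnv <- truth$alpha1 + truth$beta1 * lnx + zg1[idx] +
      truth$psi * ln_pi[hh_cluster][idx] + truth$year_effects1[wave] + u1
    w <- truth$alpha0 + truth$beta0 * lnx + zg0[idx] +
      truth$theta * ln_pi[hh_cluster][idx] + f_c[hh_cluster][idx] +
      truth$year_effects0[wave] + u0

    cons <- smoker[idx]
    w_cons <- w[cons]
    out_of_range <- w_cons <= 0 | w_cons >= 1
    if (mean(out_of_range) > 0.01)
      stop_generation(paste0(
        "%.1f%% of consumer budget shares fall outside (0, 1); ",
        "rescale beta0/sigma00/intercepts"), 100 * mean(out_of_range))
    w_cons <- pmin(pmax(w_cons, 5e-4), 0.95)

    cig_exp <- numeric(n); cig_q <- numeric(n)
    cig_exp[cons] <- w_cons * x[cons]
    cig_q[cons] <- cig_exp[cons] / exp(lnv[cons])

    records <- tibble::tibble(
      household_id = hh_id[idx],
      cluster_id = cl_id[hh_cluster][idx],
      year = 2015L + wave,
      cig_expenditure = cig_exp,
      cig_quantity = cig_q,
      total_expenditure = x,
      hh_size = hh_size[idx],
      n_male = n_male[idx],
      edu_max = edu_max[idx],
      head_female = head_female[idx],
      head_edu = head_edu[idx],
      urban = urban_c[hh_cluster][idx]
    )
    sh <- tibble::as_tibble(shares[idx, , drop = FALSE], .name_repair = "minimal")
    names(sh) <- .share_fields
    records <- dplyr::bind_cols(records, sh)
    records$weight <- weight_h[idx]

    if (prepare) records <- prepare_survey(records, config)

    out <- list(records = records, truth = truth)
    if (return_latent) {
      out$latent <- list(
        clusters = tibble::tibble(cluster_id = cl_id, ln_pi = ln_pi,
                                  f_c = f_c, urban = urban_c),
        errors = tibble::tibble(household_id = hh_id[idx],
                                year = 2015L + wave,
                                consumer = cons, u1 = u1, u0 = u0,
                                n_clamped = sum(out_of_range)))
    }
    out
  })
}

#' Elasticities implied by the generating parameters
#'
#' Two readings of "what the pipeline should find" on synthetic data:
#'
#' * `method = "structural"`: the household-level elasticities of the
#'   generating model, `eps_p = theta/wbar - psi` and
#'   `eps_I = 1 + beta0/wbar - beta1`, with `theta` and `beta0` expressed on
#'   the scale of the estimation sample (multiplied by the participation rate
#'   under `wbar_mode = "unconditional"`; the participation factor cancels
#'   against `wbar`, so the value is the same under both modes).
#' * `method = "estimator_limit"`: the exact large-sample limit of the
#'   two-stage estimator — the quality-correction identities applied to the
#'   limit inputs `beta1`, `beta0* = p beta0`, `wbar*` and the limit
#'   cluster slope `phi* = p theta / psi`.
#'
#' The two coincide when the generating `(theta, psi)` satisfy the
#' quality-theory restriction embedded in the identities (and always for
#' `eps_I`); otherwise the difference measures the identities' modelling
#' error, not an estimation failure. Parameter-recovery and coverage checks
#' therefore compare estimates against the estimator limit.
#'
#' `wbar` is estimated from a single large simulated survey (the share mean
#' depends on the whole covariate distribution and has no convenient closed
#' form); an internal fixed seed makes the result a deterministic property of
#' the model.
#'
#' @param truth a [synthetic_truth()].
#' @param wbar_mode `"unconditional"` or `"conditional"`.
#' @param method see above.
#' @param psi_formula identity variant used under `"estimator_limit"`.
#' @param n_clusters_sim number of clusters in the auxiliary simulation.
#' @return named list: `eps_p`, `eps_I`, `wbar` (and under
#'   `"estimator_limit"` also the limit `phi`, `zeta`, `theta`, `psi`).
#' @export
implied_elasticities <- function(truth = synthetic_truth(),
                                 wbar_mode = c("unconditional", "conditional"),
                                 method = c("structural", "estimator_limit"),
                                 psi_formula = c("as_printed", "deaton_1997"),
                                 n_clusters_sim = 1200L) {
  wbar_mode <- match.arg(wbar_mode)
  method <- match.arg(method)
  psi_formula <- match.arg(psi_formula)
  big <- truth
  big$n_clusters <- as.integer(n_clusters_sim)
  big$households_per_cluster <- max(big$households_per_cluster, 15L)
  big$seed <- 285714L
  rec <- simulate_survey(big, prepare = TRUE)$records
  # the empirical participation rate of the auxiliary sample, so that the
  # unconditional and conditional readings agree exactly
  p <- mean(rec$consumer)
  wbar <- if (wbar_mode == "unconditional") mean(rec$budget_share)
          else mean(rec$budget_share[rec$consumer])
  scale_p <- if (wbar_mode == "unconditional") p else 1
  if (method == "structural") {
    return(list(eps_p = scale_p * truth$theta / wbar - truth$psi,
                eps_I = 1 + scale_p * truth$beta0 / wbar - truth$beta1,
                wbar = wbar))
  }
  # estimator limit: Eq.-2 quantities are always estimated unconditionally,
  # so the limit slope and share slope carry the participation factor
  # regardless of which wbar enters the identities
  beta0_lim <- p * truth$beta0
  phi_lim <- if (truth$psi != 0) p * truth$theta / truth$psi else 0
  zeta <- zeta_hat(truth$beta1, beta0_lim, wbar)
  theta <- theta_hat(phi_lim, zeta, wbar)
  psi <- psi_hat(theta, zeta, truth$beta1, wbar, psi_formula)
  list(eps_p = price_elasticity(theta, psi, wbar),
       eps_I = expenditure_elasticity(beta0_lim, truth$beta1, wbar),
       wbar = wbar, phi = phi_lim, zeta = zeta, theta = theta, psi = psi)
}

#' @export
print.deaton_truth <- function(x, ...) {
  cat("Synthetic survey generating model\n")
  cat(sprintf("  design: %d clusters x %d households x %d waves (%d records)\n",
              x$n_clusters, x$households_per_cluster, x$n_waves,
              x$n_clusters * x$households_per_cluster * x$n_waves))
  cat(sprintf("  participation %.2f | beta1 %.3f beta0 %.4f | theta %.4f psi %.3f\n",
              x$participation_rate, x$beta1, x$beta0, x$theta, x$psi))
  cat(sprintf("  cluster price SD %.2f | sigma11 %.3g sigma00 %.3g sigma10 %.3g | rho_t %.2f\n",
              x$cluster_price_sd, x$sigma11, x$sigma00, x$sigma10, x$rho_time))
  invisible(x)
}
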