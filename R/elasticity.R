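# Quality-correction identities recovering the structural price response from
# the first-stage slopes and the cluster-level EIV slope, plus the cluster
# bootstrap for inference.

#' Deaton quality-correction identities
#'
#' The algebra linking the reduced-form estimates to the structural price
#' coefficients: `zeta_hat` is the quality-response ratio
#' `beta1 / (beta0 + wbar (1 - beta1))`; `theta_hat` converts the
#' cluster-level EIV slope `phi` into the budget-share price slope
#' `phi / (1 + (wbar - phi) zeta)`; `psi_hat` recovers the price elasticity
#' of the unit value under one of two algebraic variants (see
#' [pipeline_config()]); `price_elasticity` is `theta / wbar - psi`; and
#' `expenditure_elasticity` is `1 + beta0 / wbar - beta1`. Both `psi`
#' variants satisfy `psi = 1` when `theta = wbar` or `beta1 = 0`.
#'
#' @param beta1 slope of log unit value on log total expenditure.
#' @param beta0 slope of budget share on log total expenditure.
#' @param wbar sample mean budget share (> 0).
#' @param phi errors-in-variables cluster slope.
#' @param zeta quality-response ratio.
#' @param theta budget-share price slope.
#' @param psi unit-value price elasticity.
#' @param psi_formula `"as_printed"` or `"deaton_1997"`.
#' @return a scalar (all functions are vectorised over their inputs).
#' @name quality-correction
#' @examples
#' z <- zeta_hat(0.5, 0.02, 0.1)      # 7.142857
#' th <- theta_hat(0.05, z, 0.1)      # 0.0368421
#' price_elasticity(0, 1, 0.05)       # -1
NULL

#' @rdname quality-correction
#' @export
zeta_hat <- function(beta1, beta0, wbar) {
  den <- beta0 + wbar * (1 - beta1)
  if (any(den == 0)) stop_estimation("zeta denominator beta0 + wbar(1 - beta1) is zero")
  beta1 / den
}

#' @rdname quality-correction
#' @export
theta_hat <- function(phi, zeta, wbar) {
  den <- 1 + (wbar - phi) * zeta
  if (any(den == 0)) stop_estimation("theta denominator 1 + (wbar - phi) zeta is zero")
  phi / den
}

#' @rdname quality-correction
#' @export
psi_hat <- function(theta, zeta, beta1, wbar,
                    psi_formula = c("as_printed", "deaton_1997")) {
  psi_formula <- match.arg(psi_formula)
  if (psi_formula == "as_printed") {
    den <- beta1 + wbar
    if (any(den == 0)) stop_estimation("psi denominator beta1 + wbar is zero")
    1 - beta1 * (wbar - theta) / den
  } else {
    1 + zeta * (theta - wbar)
  }
}

#' @rdname quality-correction
#' @export
price_elasticity <- function(theta, psi, wbar) {
  if (any(wbar <= 0)) stop_estimation("wbar must be positive")
  theta / wbar - psi
}

#' @rdname quality-correction
#' @export
expenditure_elasticity <- function(beta0, beta1, wbar) {
  if (any(wbar <= 0)) stop_estimation("wbar must be positive")
  1 + beta0 / wbar - beta1
}

# Full point estimation on a prebuilt design (shared by the user-facing
# wrapper and every bootstrap replicate).
estimate_from_design <- function(d, config, quiet = TRUE, f_test = TRUE) {
  fs <- first_stage_design(d, config, quiet = quiet, f_test = f_test)
  agg <- aggregate_clusters(NULL, fs)
  eiv <- eiv_phi(agg, fs$sigma$sigma10, fs$sigma$sigma11, config)
  wbar <- switch(config$wbar_mode,
                 unconditional = mean(d$w),
                 conditional = mean(d$w[d$consumer]))
  beta1 <- fs$eq1$beta_hat
  beta0 <- fs$eq0$beta_hat
  zeta <- zeta_hat(beta1, beta0, wbar)
  theta <- theta_hat(eiv$phi_hat, zeta, wbar)
  psi <- psi_hat(theta, zeta, beta1, wbar, config$psi_formula)
  list(eps_p = price_elasticity(theta, psi, wbar),
       eps_I = expenditure_elasticity(beta0, beta1, wbar),
       wbar = wbar, beta1 = beta1, beta0 = beta0,
       phi = eiv$phi_hat, zeta = zeta, theta = theta, psi = psi,
       first_stage = fs, aggregates = agg, eiv = eiv)
}

#' Point estimates of the price and expenditure elasticity
#'
#' Runs the full two-stage procedure: first-stage fixed-effects regressions,
#' residual (co)variances, cluster aggregation, the errors-in-variables
#' slope, and the quality-correction identities.
#'
#' @param records prepared records ([prepare_survey()] / [simulate_survey()]).
#' @param config a [pipeline_config()].
#' @param quiet suppress first-stage notes.
#' @return a list with the structural estimates (`eps_p`, `eps_I`, `wbar`,
#'   `beta1`, `beta0`, `phi`, `zeta`, `theta`, `psi`) and the underlying
#'   fitted objects (`first_stage`, `aggregates`, `eiv`).
#' @export
estimate_elasticities <- function(records, config = pipeline_config(),
                                  quiet = FALSE) {
  estimate_from_design(build_design(records, config), config, quiet = quiet)
}

# One bootstrap replicate: resample survey clusters with replacement (all
# waves of a cluster move together); duplicated clusters are treated as
# distinct resampled clusters, and their households as distinct households.
boot_replicate <- function(d, sampled_clusters, config, row_index) {
  rows_list <- row_index[sampled_clusters]
  sizes <- lengths(rows_list)
  rows <- unlist(rows_list, use.names = FALSE)
  new_cl <- rep(seq_along(sampled_clusters), sizes)
  db <- list(X = d$X[rows, , drop = FALSE],
             lnv = d$lnv[rows], w = d$w[rows],
             consumer = d$consumer[rows],
             cluster = as.character(new_cl),
             household = paste0(new_cl, "/", d$household[rows]),
             year = d$year[rows], weight = d$weight[rows])
  estimate_from_design(db, config, quiet = TRUE, f_test = FALSE)
}

#' Cluster-bootstrap elasticity estimates
#'
#' Resamples survey-design clusters with replacement (keeping all waves of a
#' cluster together, preserving the within-cluster price commonality and
#' household dependence), reruns the entire two-stage pipeline per replicate,
#' and reports bootstrap SEs and 95% percentile confidence intervals for the
#' price and expenditure elasticity. Replicates where the corrected EIV
#' denominator is non-positive are dropped and counted; more than 20%
#' dropped replicates aborts. A fixed seed gives identical results.
#'
#' @param records prepared records.
#' @param config a [pipeline_config()]; `bootstrap_reps` and `seed` are taken
#'   from it unless overridden.
#' @param reps,seed optional overrides.
#' @return an object of class `elasticity_fit`: point estimates, `se_p`,
#'   `se_I`, `ci_p`, `ci_I`, the replicate draws, `n_boot`, `n_dropped`,
#'   `seed`.
#' @export
bootstrap_elasticities <- function(records, config = pipeline_config(),
                                   reps = NULL, seed = NULL) {
  reps <- as.integer(reps %||% config$bootstrap_reps)
  seed <- as.integer(seed %||% config$seed)
  d <- build_design(records, config)
  point <- estimate_from_design(d, config, quiet = TRUE)
  clusters <- sort(unique(d$cluster))
  row_index <- split(seq_along(d$cluster), d$cluster)[clusters]

  draws <- with_preserved_seed(seed, {
    lapply(seq_len(reps), function(b) {
      sampled <- sample(clusters, length(clusters), replace = TRUE)
      tryCatch(
        boot_replicate(d, sampled, config, row_index)[
          c("eps_p", "eps_I", "phi", "theta", "psi", "zeta",
            "beta1", "beta0", "wbar")],
        deatonuv_estimation_error = function(e) NULL)
    })
  })
  ok <- !vapply(draws, is.null, logical(1))
  n_dropped <- sum(!ok)
  if (n_dropped / reps > 0.2)
    stop_estimation(
      "%d of %d bootstrap replicates failed (corrected EIV denominator non-positive)",
      n_dropped, reps)
  boot <- dplyr::bind_rows(lapply(draws[ok], tibble::as_tibble))

  pci <- stats::quantile(boot$eps_p, c(0.025, 0.975), names = FALSE)
  ici <- stats::quantile(boot$eps_I, c(0.025, 0.975), names = FALSE)
  structure(c(point[c("eps_p", "eps_I", "wbar", "beta1", "beta0",
                      "phi", "zeta", "theta", "psi")],
              list(se_p = stats::sd(boot$eps_p),
                   se_I = stats::sd(boot$eps_I),
                   ci_p = pci, ci_I = ici,
                   boot = boot, n_boot = sum(ok), n_dropped = n_dropped,
                   seed = seed,
                   first_stage = point$first_stage,
                   aggregates = point$aggregates, eiv = point$eiv)),
            class = "elasticity_fit")
}

#' Elasticity summary table
#'
#' @param fit an `elasticity_fit` from [bootstrap_elasticities()].
#' @return tibble with `term`, `estimate`, `se`, `p_value` (normal
#'   approximation from the bootstrap SE), `ci_low`, `ci_high` (95%
#'   percentile bootstrap).
#' @export
elasticity_table <- function(fit) {
  stopifnot(inherits(fit, "elasticity_fit"))
  p_of <- function(est, se) 2 * stats::pnorm(-abs(est / se))
  tibble::tibble(
    term = c("expenditure_elasticity", "price_elasticity"),
    estimate = c(fit$eps_I, fit$eps_p),
    se = c(fit$se_I, fit$se_p),
    p_value = c(p_of(fit$eps_I, fit$se_I), p_of(fit$eps_p, fit$se_p)),
    ci_low = c(fit$ci_I[1], fit$ci_p[1]),
    ci_high = c(fit$ci_I[2], fit$ci_p[2]))
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat("Deaton unit-value elasticity estimates\n")
  cat(sprintf("  price elasticity:       %.4f (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$eps_p, x$se_p, x$ci_p[1], x$ci_p[2]))
  cat(sprintf("  expenditure elasticity: %.4f (SE %.4f, 95%% CI [%.4f, %.4f])\n",
              x$eps_I, x$se_I, x$ci_I[1], x$ci_I[2]))
  cat(sprintf("  wbar = %.5f | beta1 = %.4f beta0 = %.5f | phi = %.5f theta = %.5f psi = %.4f\n",
              x$wbar, x$beta1, x$beta0, x$phi, x$theta, x$psi))
  cat(sprintf("  %d bootstrap replicates (%d dropped), seed %d\n",
              x$n_boot, x$n_dropped, x$seed))
  invisible(x)
}
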