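# Second stage: aggregate purged first-stage values to survey clusters and
# estimate the errors-in-variables slope of cluster budget shares on cluster
# log unit values, correcting both moments for the sampling noise that the
# household-level errors leave in the cluster means.

#' Cluster-level purged averages
#'
#' Averages the purged first-stage values (outcome minus estimated
#' expenditure, demographic and year components) within each survey-design
#' cluster, pooling the waves: `y1c` over consuming records (log unit value
#' side), `y0c` over all records (budget share side). These means retain the
#' cluster-common price signal plus averaged-down household noise.
#'
#' @param records prepared records (used only for the cluster universe).
#' @param fit a [first_stage()] fit.
#' @return tibble of class `cluster_aggregates`: `cluster_id`, `y1c`, `y0c`,
#'   `n_c` (records), `n_c_plus` (consuming records; `y1c` is `NA` where 0).
#' @export
aggregate_clusters <- function(records, fit) {
  stopifnot(inherits(fit, "first_stage_fit"))
  cl0 <- fit$eq0$cluster
  ids <- sort(unique(cl0))
  g0 <- match(cl0, ids)
  y0c <- as.vector(rowsum(fit$eq0$purged, g0)) / tabulate(g0, length(ids))
  n_c <- tabulate(g0, length(ids))

  cl1 <- fit$eq1$cluster
  g1 <- match(cl1, ids)
  n_c_plus <- tabulate(g1, length(ids))
  # rowsum orders rows by group value and stores it in rownames
  tmp <- rowsum(fit$eq1$purged, g1)
  y1c <- rep(NA_real_, length(ids))
  gi <- as.integer(rownames(tmp))
  y1c[gi] <- as.vector(tmp) / n_c_plus[gi]

  structure(tibble::tibble(cluster_id = ids, y1c = y1c, y0c = y0c,
                           n_c = n_c, n_c_plus = n_c_plus),
            class = c("cluster_aggregates", class(tibble::tibble())))
}

#' Errors-in-variables slope of cluster demand on cluster unit values
#'
#' The regression slope of `y0c` on `y1c` across clusters, with the
#' measurement-error moments subtracted:
#' `phi = (cov(y1c, y0c) - sigma10 / n) / (var(y1c) - sigma11 / n+)`.
#' The corrections undo the attenuation caused by averaged household-level
#' errors: the noise variance of a cluster mean of `n+` consumer records is
#' `sigma11 / n+`, and the noise covariance between the two means (the share
#' mean runs over all `n` records, of which only consumers carry an error
#' from the unit-value equation) is `sigma10 / n`. Cluster-size summaries
#' default to harmonic means, matching the average of per-cluster `1/n`
#' noise moments; both divisor conventions are configurable.
#'
#' @param aggregates a [aggregate_clusters()] table.
#' @param sigma10,sigma11 error moments from [residual_covariances()] (use
#'   the temporally clustered versions so serial correlation is carried into
#'   the corrections).
#' @param config a [pipeline_config()].
#' @param use_corrections set `FALSE` to return the naive (attenuated)
#'   covariance/variance slope.
#' @return object of class `eiv_fit`: `phi_hat`, raw moments, the two
#'   subtracted corrections, the size summaries and `n_clusters_used`.
#' @export
eiv_phi <- function(aggregates, sigma10, sigma11,
                    config = pipeline_config(), use_corrections = TRUE) {
  a <- aggregates[!is.na(aggregates$y1c), , drop = FALSE]
  if (nrow(a) < 3)
    stop_estimation("need >= 3 clusters with consuming records (have %d)",
                    nrow(a))
  size_summary <- switch(config$eiv_size_summary,
                         harmonic = harmonic_mean,
                         arithmetic = mean)
  n_tilde_plus <- size_summary(a$n_c_plus)
  n_tilde <- switch(config$eiv_sigma10_divisor,
                    all_records = size_summary(a$n_c),
                    consumers = n_tilde_plus)
  cov_raw <- stats::cov(a$y1c, a$y0c)
  var_raw <- stats::var(a$y1c)
  correction10 <- if (use_corrections) sigma10 / n_tilde else 0
  correction11 <- if (use_corrections) sigma11 / n_tilde_plus else 0
  denom <- var_raw - correction11
  if (denom <= 0)
    stop_estimation(paste0(
      "corrected cluster variance is non-positive (%.3g - %.3g); ",
      "the price signal is too weak relative to measurement error - ",
      "more or larger clusters are needed"), var_raw, correction11)
  structure(list(phi_hat = (cov_raw - correction10) / denom,
                 cov_raw = cov_raw, var_raw = var_raw,
                 correction10 = correction10, correction11 = correction11,
                 n_tilde = n_tilde, n_tilde_plus = n_tilde_plus,
                 n_clusters_used = nrow(a)),
            class = "eiv_fit")
}

#' @export
print.eiv_fit <- function(x, ...) {
  cat(sprintf("Errors-in-variables cluster slope: phi = %.5f (%d clusters)\n",
              x$phi_hat, x$n_clusters_used))
  cat(sprintf("  cov %.4g - %.4g over var %.4g - %.4g\n",
              x$cov_raw, x$correction10, x$var_raw, x$correction11))
  invisible(x)
}
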