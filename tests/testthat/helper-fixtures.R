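# Shared fixtures, built in code.

# Equal age-sex shares summing to one.
flat_shares <- function(n) {
  sh <- matrix(1 / 8, n, 8)
  colnames(sh) <- c("sh_m0_5", "sh_f0_5", "sh_m6_17", "sh_f6_17",
                    "sh_m18_49", "sh_f18_49", "sh_m_gt49", "sh_f_gt49")
  tibble::as_tibble(sh)
}

# A tiny canonical table with hand-controllable outcomes.
toy_records <- function(cig_exp = c(40, 60, 5),
                        cig_q = c(20, 20, 10),
                        total = c(1000, 2000, 500),
                        cluster = c("A", "A", "B"),
                        year = c(2016L, 2016L, 2017L),
                        weight = c(1, 1, 1)) {
  n <- length(cig_exp)
  dplyr::bind_cols(
    tibble::tibble(
      household_id = sprintf("H%02d", seq_len(n)),
      cluster_id = cluster, year = year,
      cig_expenditure = cig_exp, cig_quantity = cig_q,
      total_expenditure = total,
      hh_size = rep(4L, n), n_male = rep(2L, n), edu_max = rep(8L, n),
      head_female = rep(0L, n), head_edu = rep(5L, n), urban = rep(0L, n)),
    flat_shares(n),
    tibble::tibble(weight = weight))
}

# Small, fast synthetic model for unit tests.
tiny_truth <- function(...) {
  synthetic_truth(n_clusters = 60, households_per_cluster = 8,
                  participation_rate = 0.4, seed = 99L, ...)
}

# Random age-sex composition shares summing to one (so the share columns
# carry within-cluster variation and stay full rank without absorbers).
random_shares <- function(n) {
  counts <- t(stats::rmultinom(n, 6, rep(1 / 8, 8)))
  sh <- counts / rowSums(counts)
  colnames(sh) <- names(flat_shares(1))
  tibble::as_tibble(sh)
}

# Random small dataset for regression-oracle comparisons: 5 clusters,
# 60 records, everything varying within clusters, all households consuming.
oracle_records <- function(seed = 11) {
  withr::with_seed(seed, {
    n <- 60
    cl <- rep(sprintf("C%d", 1:5), each = 12)
    hh <- rep(sprintf("H%02d", 1:30), each = 2)
    yr <- rep(c(2016L, 2017L), times = 30)
    total <- exp(rnorm(n, 8, 0.5))
    q <- exp(rnorm(n, 3, 0.4))
    v <- exp(rnorm(n, 2, 0.3) + 0.1 * as.integer(factor(cl)))
    dplyr::bind_cols(
      tibble::tibble(
        household_id = hh, cluster_id = cl, year = yr,
        cig_expenditure = q * v, cig_quantity = q, total_expenditure = total,
        hh_size = sample(2:8, n, TRUE), n_male = sample(0:3, n, TRUE),
        edu_max = sample(0:15, n, TRUE), head_female = rbinom(n, 1, 0.3),
        head_edu = sample(0:15, n, TRUE), urban = rbinom(n, 1, 0.5)),
      random_shares(n),
      tibble::tibble(weight = runif(n, 0.5, 1.5)))
  })
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path, progress = FALSE)
  path
}
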