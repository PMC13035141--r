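#' Pipeline configuration
#'
#' Collects every tunable choice of the estimation pipeline in one validated
#' list, so that a run is fully described by (data, config, seed).
#'
#' @param column_map named character vector mapping canonical field names to
#'   source-file column names, e.g. `c(household_id = "hhid", ...)`. `NULL`
#'   means the file already uses canonical names (see [load_survey()]).
#' @param base_year deflation target year; currency fields are re-expressed in
#'   this year's prices.
#' @param cpi_series named numeric vector, `names` = survey years, values =
#'   consumer price index. Must contain `base_year`. `NULL` disables deflation
#'   (data already in constant prices).
#' @param recall_divisor divisor converting annual totals to weekly
#'   equivalents. Default `365/7` (true weeks per year); `52` is the common
#'   rounded alternative.
#' @param annual_fields canonical currency fields recorded on an annual recall
#'   that must be divided by `recall_divisor` at load time.
#' @param weighted_descriptives use survey weights in [survey_descriptives()].
#' @param weighted_regression use survey weights in the first-stage
#'   regressions. Default `FALSE`: the second stage treats clusters as the
#'   units of observation and design weights are not needed for consistency.
#' @param fe_mode_eq1 `"cluster_and_year"` (default) absorbs cluster effects
#'   and year dummies in the unit-value equation; `"year_only"` drops the
#'   cluster absorbers (the textbook first stage, which leaves the spatial
#'   price signal in the residual variance).
#' @param psi_formula algebraic variant of the quality-correction identity
#'   used to recover the price elasticity of the unit value:
#'   `"as_printed"` gives `psi = 1 - beta1 * (wbar - theta) / (beta1 + wbar)`;
#'   `"deaton_1997"` gives `psi = 1 + zeta * (theta - wbar)`.
#' @param wbar_mode budget-share mean entering the elasticity identities:
#'   `"unconditional"` (default) averages over the full estimation sample
#'   including non-consuming households, matching the unconditional
#'   budget-share regression; `"conditional"` averages over consumers only.
#' @param eiv_size_summary summary of per-cluster sizes used in the
#'   errors-in-variables corrections: `"harmonic"` (default; the correction is
#'   an average of per-cluster error variances proportional to `1/n_c`) or
#'   `"arithmetic"`.
#' @param eiv_sigma10_divisor cluster-size base for the covariance correction:
#'   `"all_records"` (default) divides `sigma10` by the all-household cluster
#'   size `n_c`, `"consumers"` by the consumer count `n_c+`.
#' @param temporal_clustering aggregate first-stage residuals within household
#'   across waves before forming the error (co)variances, so that serial
#'   correlation of the errors propagates into the corrections. Default `TRUE`.
#' @param winsorise_unit_values optional length-2 probability vector, e.g.
#'   `c(0.01, 0.99)`, winsorising log unit values among consumers before
#'   estimation. `NULL` (default) leaves unit values untouched.
#' @param bootstrap_reps number of cluster-bootstrap replications (>= 1).
#' @param seed integer seed governing every stochastic step.
#'
#' @return a list of class `deatonuv_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(bootstrap_reps = 200, seed = 7)
#' cfg$recall_divisor
pipeline_config <- function(column_map = NULL,
                            base_year = 2017,
                            cpi_series = NULL,
                            recall_divisor = 365 / 7,
                            annual_fields = "total_expenditure",
                            weighted_descriptives = TRUE,
                            weighted_regression = FALSE,
                            fe_mode_eq1 = c("cluster_and_year", "year_only"),
                            psi_formula = c("as_printed", "deaton_1997"),
                            wbar_mode = c("unconditional", "conditional"),
                            eiv_size_summary = c("harmonic", "arithmetic"),
                            eiv_sigma10_divisor = c("all_records", "consumers"),
                            temporal_clustering = TRUE,
                            winsorise_unit_values = NULL,
                            bootstrap_reps = 1000L,
                            seed = 1L) {
  fe_mode_eq1 <- match.arg(fe_mode_eq1)
  psi_formula <- match.arg(psi_formula)
  wbar_mode <- match.arg(wbar_mode)
  eiv_size_summary <- match.arg(eiv_size_summary)
  eiv_sigma10_divisor <- match.arg(eiv_sigma10_divisor)

  if (!is.null(cpi_series)) {
    if (is.null(names(cpi_series)) || any(!nzchar(names(cpi_series))))
      stop_config("cpi_series must be a named vector (names = years)")
    if (!as.character(base_year) %in% names(cpi_series))
      stop_config("cpi_series does not contain base_year %s", base_year)
    if (any(cpi_series <= 0))
      stop_config("cpi_series values must be positive")
  }
  if (!is.numeric(recall_divisor) || recall_divisor <= 0)
    stop_config("recall_divisor must be a positive number")
  if (!is.numeric(bootstrap_reps) || bootstrap_reps < 1)
    stop_config("bootstrap_reps must be >= 1")
  if (!is.null(winsorise_unit_values) &&
      (length(winsorise_unit_values) != 2 ||
       any(winsorise_unit_values < 0 | winsorise_unit_values > 1)))
    stop_config("winsorise_unit_values must be two probabilities in [0, 1]")

  structure(list(
    column_map = column_map,
    base_year = base_year,
    cpi_series = cpi_series,
    recall_divisor = recall_divisor,
    annual_fields = annual_fields,
    weighted_descriptives = isTRUE(weighted_descriptives),
    weighted_regression = isTRUE(weighted_regression),
    fe_mode_eq1 = fe_mode_eq1,
    psi_formula = psi_formula,
    wbar_mode = wbar_mode,
    eiv_size_summary = eiv_size_summary,
    eiv_sigma10_divisor = eiv_sigma10_divisor,
    temporal_clustering = isTRUE(temporal_clustering),
    winsorise_unit_values = winsorise_unit_values,
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = as.integer(seed)
  ), class = "deatonuv_config")
}
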