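# Data model and preprocessing: loading, deflation, recall harmonisation,
# unit values, budget shares, consumption quintiles, weighted descriptives.

# Canonical household-by-wave fields. Share columns are the age-sex
# composition of the household (fractions of members, summing to 1).
.share_fields <- c("sh_m0_5", "sh_f0_5", "sh_m6_17", "sh_f6_17",
                   "sh_m18_49", "sh_f18_49", "sh_m_gt49", "sh_f_gt49")

.required_fields <- c("household_id", "cluster_id", "year",
                      "cig_expenditure", "cig_quantity", "total_expenditure",
                      "hh_size", "n_male", "edu_max", "head_female",
                      "head_edu", "urban", .share_fields, "weight")

#' Convert an annual amount to its weekly equivalent
#'
#' @param annual_value non-negative amount per year.
#' @param recall_divisor weeks per year; default `365/7`.
#' @return amount per week.
#' @export
#' @examples
#' to_weekly(5200, recall_divisor = 52) # 100
to_weekly <- function(annual_value, recall_divisor = 365 / 7) {
  if (any(annual_value < 0, na.rm = TRUE))
    stop_validation("annual_value must be non-negative")
  annual_value / recall_divisor
}

#' Deflate currency values to base-year prices
#'
#' Multiplies each value by `cpi(base_year) / cpi(year)`. Base-year rows are
#' unchanged; the operation is idempotent once values are in base-year prices.
#'
#' @param value numeric currency values.
#' @param year survey year of each value.
#' @param cpi_series named numeric vector of index values, names = years.
#' @param base_year target year; must appear in `cpi_series`.
#' @return deflated values.
#' @export
#' @examples
#' deflate(110, 2018, c(`2017` = 100, `2018` = 110), 2017) # 100
deflate <- function(value, year, cpi_series, base_year) {
  yrs <- as.character(year)
  if (!as.character(base_year) %in% names(cpi_series))
    stop_config("cpi_series does not contain base_year %s", base_year)
  missing_years <- setdiff(unique(yrs), names(cpi_series))
  if (length(missing_years))
    stop_config("cpi_series missing year(s): %s",
                paste(missing_years, collapse = ", "))
  value * unname(cpi_series[as.character(base_year)] / cpi_series[yrs])
}

#' Unit value of the good
#'
#' Expenditure divided by quantity, defined only for consuming records.
#' Vectorised; a zero quantity with positive expenditure is a data
#' inconsistency and raises an error naming the offending rows.
#'
#' @param cig_expenditure expenditure per week (>= 0).
#' @param cig_quantity quantity per week (>= 0).
#' @return unit value where quantity and expenditure are both positive,
#'   otherwise `NA`.
#' @export
#' @examples
#' compute_unit_value(40, 20)  # 2
#' compute_unit_value(0, 0)    # NA (non-consumer)
compute_unit_value <- function(cig_expenditure, cig_quantity) {
  if (any(cig_expenditure < 0, na.rm = TRUE) ||
      any(cig_quantity < 0, na.rm = TRUE))
    stop_validation("expenditure and quantity must be non-negative")
  bad <- which(cig_quantity == 0 & cig_expenditure > 0)
  if (length(bad))
    stop_validation(
      "positive expenditure with zero quantity in row(s): %s",
      paste(utils::head(bad, 10), collapse = ", "))
  ifelse(cig_quantity > 0 & cig_expenditure > 0,
         cig_expenditure / cig_quantity, NA_real_)
}

#' Load a household-by-wave survey table from delimited text
#'
#' Reads a CSV/TSV with one row per household and wave, maps source columns to
#' the canonical schema, validates, harmonises recall periods, deflates
#' currency fields and derives unit values, budget shares and consumption
#' quintiles via [prepare_survey()].
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated, otherwise
#'   comma-separated. Empty fields are missing values.
#' @param config a [pipeline_config()]; `config$column_map` maps canonical
#'   field names to the file's column names (`NULL` = file already canonical).
#' @return a tibble of prepared records (one per household x wave).
#' @export
load_survey <- function(path, config = pipeline_config()) {
  if (!file.exists(path)) stop_config("input file not found: %s", path)
  delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)

  cmap <- config$column_map
  if (!is.null(cmap)) {
    missing_src <- setdiff(unname(cmap), names(raw))
    if (length(missing_src))
      stop_config("mapped column(s) absent from file: %s",
                  paste(missing_src, collapse = ", "))
    raw <- raw[, unname(cmap), drop = FALSE]
    names(raw) <- names(cmap)
  }
  missing_fields <- setdiff(.required_fields, names(raw))
  if (length(missing_fields))
    stop_config("required column(s) missing: %s",
                paste(missing_fields, collapse = ", "))

  # recall harmonisation before deflation (both are scalar multiplications,
  # order does not matter numerically)
  for (f in intersect(config$annual_fields, names(raw)))
    raw[[f]] <- to_weekly(raw[[f]], config$recall_divisor)
  if (!is.null(config$cpi_series)) {
    for (f in c("cig_expenditure", "total_expenditure"))
      raw[[f]] <- deflate(raw[[f]], raw$year, config$cpi_series,
                          config$base_year)
  }
  prepare_survey(raw, config)
}

#' Validate and derive analysis fields on a canonical survey table
#'
#' Checks the record invariants (non-negative expenditures, positive total
#' expenditure and weights, age-sex shares summing to one), rejects rows with
#' missing total expenditure (reporting their ids), and derives `unit_value`,
#' `budget_share`, the `consumer` flag, and pooled per-capita consumption
#' `quintile` (from total annual per-capita consumption).
#'
#' @param records canonical tibble (see [load_survey()] for the schema).
#' @param config a [pipeline_config()].
#' @return the prepared tibble.
#' @export
prepare_survey <- function(records, config = pipeline_config()) {
  records <- tibble::as_tibble(records)
  missing_fields <- setdiff(.required_fields, names(records))
  if (length(missing_fields))
    stop_config("required column(s) missing: %s",
                paste(missing_fields, collapse = ", "))

  drop <- which(is.na(records$total_expenditure))
  if (length(drop)) {
    message(sprintf(
      "prepare_survey: excluding %d record(s) with missing total expenditure (household %s)",
      length(drop),
      paste(unique(records$household_id[drop]), collapse = ", ")))
    records <- records[-drop, , drop = FALSE]
  }
  num_fields <- c("cig_expenditure", "cig_quantity", "total_expenditure")
  for (f in num_fields) {
    v <- records[[f]]
    bad <- which(!is.finite(v) | v < 0)
    if (f == "total_expenditure") bad <- union(bad, which(v <= 0))
    if (length(bad))
      stop_validation("invalid %s (negative, zero total, or non-numeric) in row(s): %s",
                      f, paste(utils::head(bad, 10), collapse = ", "))
  }
  if (any(records$weight <= 0, na.rm = TRUE) || anyNA(records$weight))
    stop_validation("survey weights must be positive")
  share_sum <- rowSums(as.matrix(records[, .share_fields]))
  off <- which(abs(share_sum - 1) > 1e-9)
  if (length(off))
    stop_validation("age-sex composition shares do not sum to 1 in row(s): %s",
                    paste(utils::head(off, 10), collapse = ", "))

  records$unit_value <- compute_unit_value(records$cig_expenditure,
                                           records$cig_quantity)
  records$budget_share <- records$cig_expenditure / records$total_expenditure
  records$consumer <- !is.na(records$unit_value)

  if (!is.null(config$winsorise_unit_values) && any(records$consumer)) {
    pr <- sort(config$winsorise_unit_values)
    uv <- records$unit_value[records$consumer]
    lim <- stats::quantile(uv, pr, names = FALSE)
    records$unit_value[records$consumer] <- pmin(pmax(uv, lim[1]), lim[2])
  }

  # consumption quintiles from total annual per-capita consumption, pooled
  pc_annual <- records$total_expenditure * config$recall_divisor / records$hh_size
  br <- stats::quantile(pc_annual, probs = seq(0, 1, 0.2), names = FALSE)
  br[1] <- -Inf; br[length(br)] <- Inf
  br <- unique(br)  # degenerate distributions collapse some quintiles
  records$quintile <- as.integer(cut(pc_annual, breaks = br, labels = FALSE))
  records
}

#' Weighted descriptive statistics of the analysis variables
#'
#' Survey-weighted mean, SD and 10th/90th percentiles for the outcome
#' variables, with the consumption rows (quantity, expenditure, unit value,
#' budget share) computed over consuming records only, plus cluster-size
#' summaries.
#'
#' @param records prepared records (see [prepare_survey()]).
#' @param config a [pipeline_config()]; `config$weighted_descriptives = FALSE`
#'   gives unweighted moments.
#' @return a tibble with one row per variable
#'   (`variable`, `n`, `mean`, `sd`, `q10`, `q90`).
#' @export
survey_descriptives <- function(records, config = pipeline_config()) {
  if (!nrow(records)) stop_validation("no records to describe")
  w <- if (config$weighted_descriptives) records$weight else rep(1, nrow(records))
  if (all(w == 0)) stop_validation("all weights are zero")

  row_stat <- function(name, x, wt) {
    q <- weighted_quantile(x, wt, c(0.1, 0.9))
    tibble::tibble(variable = name, n = length(x),
                   mean = weighted_mean(x, wt), sd = weighted_sd(x, wt),
                   q10 = q[[1]], q90 = q[[2]])
  }
  cons <- records$consumer
  out <- dplyr::bind_rows(
    row_stat("total_expenditure_weekly", records$total_expenditure, w),
    row_stat("reports_cigarettes", as.numeric(cons), w),
    row_stat("cig_quantity_weekly", records$cig_quantity[cons], w[cons]),
    row_stat("cig_expenditure_weekly", records$cig_expenditure[cons], w[cons]),
    row_stat("unit_value", records$unit_value[cons], w[cons]),
    row_stat("budget_share", records$budget_share[cons], w[cons])
  )
  # unit values can also be summarised as a ratio of means; the two differ on
  # heterogeneous data and both are reported
  out <- dplyr::bind_rows(out, tibble::tibble(
    variable = "unit_value_ratio_of_means", n = sum(cons),
    mean = weighted_mean(records$cig_expenditure[cons], w[cons]) /
      weighted_mean(records$cig_quantity[cons], w[cons]),
    sd = NA_real_, q10 = NA_real_, q90 = NA_real_))

  n_c <- table(records$cluster_id)
  n_h <- tapply(records$household_id, records$cluster_id,
                function(h) length(unique(h)))
  out <- dplyr::bind_rows(
    out,
    row_stat("records_per_cluster", as.numeric(n_c), rep(1, length(n_c))),
    row_stat("households_per_cluster", as.numeric(n_h), rep(1, length(n_h))),
    tibble::tibble(variable = "n_clusters", n = length(n_c),
                   mean = length(n_c), sd = NA_real_,
                   q10 = NA_real_, q90 = NA_real_),
    tibble::tibble(variable = "n_records", n = nrow(records),
                   mean = nrow(records), sd = NA_real_,
                   q10 = NA_real_, q90 = NA_real_)
  )
  out
}
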