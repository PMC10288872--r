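## Cohort-table schema shared by the statistics layer, the simulator and the
## CLI. One row per subject:
##   subject_id, group (control | FAS | NS-FASD), sex (0 female / 1 male,
##   "F"/"M" accepted), age_years, tcxs_cm2, cxps_<parcel>_cm2 x7,
##   ccps_<parcel>_mm2 x7, cc_total_mm2.

cohort_required_columns <- function() {
  c("subject_id", "group", "sex", "age_years", "tcxs_cm2",
    cxps_column(parcel_names()), ccps_column(parcel_names()), "cc_total_mm2")
}

#' Read a cohort table
#'
#' Reads and validates the per-subject CSV consumed by the statistics layer.
#' Unknown columns are dropped with a warning; a missing mandatory column or
#' a non-numeric area is an error. `sex` is normalised to 0 (female) / 1
#' (male). All areas must be positive except callosal areas, which may be 0
#' (partial agenesis).
#'
#' @param path CSV file.
#' @return A `data.frame` with the canonical schema.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(df)
}

#' Validate (and normalise) a cohort table
#'
#' @param df A data frame in the cohort schema.
#' @return The validated data frame, columns in canonical order.
#' @export
validate_cohort <- function(df) {
  req <- cohort_required_columns()
  missing <- setdiff(req, names(df))
  if (length(missing) > 0L)
    stop("cohort table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(df), req)
  if (length(extra) > 0L)
    warning("ignoring unknown cohort column(s): ",
            paste(extra, collapse = ", "))
  df <- df[req]
  if (!all(df$group %in% c("control", "FAS", "NS-FASD")))
    stop("group must be one of control, FAS, NS-FASD")
  if (is.character(df$sex)) {
    if (!all(df$sex %in% c("F", "M")))
      stop("sex must be F/M or 0/1")
    df$sex <- ifelse(df$sex == "M", 1L, 0L)
  }
  if (!all(df$sex %in% c(0, 1))) stop("sex must be F/M or 0/1")
  num_cols <- setdiff(req, c("subject_id", "group", "sex"))
  for (cn in num_cols) {
    if (!is.numeric(df[[cn]]))
      stop("column '", cn, "' must be numeric")
    if (any(!is.finite(df[[cn]])))
      stop("column '", cn, "' contains non-finite values")
  }
  if (any(df$age_years <= 0)) stop("age_years must be > 0")
  if (any(df$age_years < 6 | df$age_years > 25))
    warning("age_years outside the 6-25 year range the models were built for")
  pos_cols <- c("tcxs_cm2", cxps_column(parcel_names()))
  for (cn in pos_cols)
    if (any(df[[cn]] <= 0)) stop("column '", cn, "' must be > 0")
  cc_cols <- c(ccps_column(parcel_names()), "cc_total_mm2")
  for (cn in cc_cols)
    if (any(df[[cn]] < 0)) stop("column '", cn, "' must be >= 0")
  df
}

#' Write a cohort table
#'
#' @param df Cohort data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
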