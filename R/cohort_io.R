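# CSV persistence of per-eye cohort tables.

.COHORT_MANDATORY <- c("patient_id", "eye", "lens_name", "K_D", "ACD_mm",
                       "AL_mm", "implanted_power_D", "postop_se_D")
.COHORT_OPTIONAL <- c("preop_se_D", "continuous_power_D")

check_cohort_table <- function(df) {
  miss <- setdiff(.COHORT_MANDATORY, names(df))
  if (length(miss))
    stop("cohort table is missing mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  unknown <- setdiff(names(df), c(.COHORT_MANDATORY, .COHORT_OPTIONAL))
  if (length(unknown))
    warning("ignoring unknown cohort column(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  bad <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      stop(sprintf("%s (row%s %s)", what, if (length(rows) > 1) "s" else "",
                   paste(rows, collapse = ", ")), call. = FALSE)
  }
  bad(!df$eye %in% c("OD", "OS"), "eye must be OD or OS")
  bad(!is.finite(df$K_D) | df$K_D < 30 | df$K_D > 60,
      "K_D outside the 30-60 D range")
  bad(!is.finite(df$ACD_mm) | df$ACD_mm < 1.5 | df$ACD_mm > 5.0,
      "ACD_mm outside the 1.5-5.0 mm range")
  bad(!is.finite(df$AL_mm) | df$AL_mm < 18 | df$AL_mm > 32,
      "AL_mm outside the 18-32 mm range")
  invisible(df)
}

#' Read and write per-eye cohort CSV files
#'
#' The cohort schema has one row per eye: `patient_id`, `eye` (`OD`/`OS`),
#' `lens_name`, `K_D`, `ACD_mm`, `AL_mm`, `implanted_power_D`,
#' `postop_se_D`, and optionally `preop_se_D` and `continuous_power_D`.
#' Reading validates the biometry invariants (K 30-60 D, ACD 1.5-5.0 mm,
#' AL 18-32 mm) and reports offending row numbers; unknown columns produce
#' a warning and are kept. Writing rounds numeric columns to 6 decimals, so
#' a write/read round trip is lossless at that precision. CRLF and LF line
#' endings are both accepted.
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a validated `iol_cohort` data.frame.
#'   `write_cohort()`: `path`, invisibly.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cohort_table(df)
  class(df) <- c("iol_cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort Cohort data.frame (e.g. from [generate_cohort()]).
#' @param overwrite Refuse to clobber an existing file unless `TRUE`.
#' @export
write_cohort <- function(cohort, path, overwrite = FALSE) {
  check_cohort_table(cohort)
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; pass overwrite = TRUE to replace it",
         call. = FALSE)
  out <- as.data.frame(cohort)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
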