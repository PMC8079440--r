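# Tidy-table I/O. Tables are plain CSV, one row per (subject, visit):
# subject_id, site, visit_time_months, gender, age_baseline, icv, diagnosis,
# apoe, then the 62 region columns in canonical order (plus an optional
# acquisition column for scan-rescan tables). Numeric cells are written with
# 17 significant digits so a write -> read round trip is value-exact.

#' Write a thickness table to CSV
#'
#' @param table Tidy thickness table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_thickness_table <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a thickness table from CSV
#'
#' @param path CSV path as written by [write_thickness_table()].
#' @return data.frame with character id columns and numeric measurements.
#' @export
read_thickness_table <- function(path) {
  if (!file.exists(path)) stop_config("cannot read '%s': no such file", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("subject_id", "site", "diagnosis"))
    if (col %in% names(tab)) tab[[col]] <- as.character(tab[[col]])
  tab
}

#' Validate a thickness table against the expected schema
#'
#' Checks the column set (covariates plus the 62 region columns), strict
#' positivity and finiteness of every thickness cell, and uniqueness of
#' (subject, visit[, acquisition]) keys. Returns a machine-readable report
#' rather than raising, so callers can decide how strict to be.
#'
#' @param x A data.frame or a path to a CSV file.
#' @return List with `valid` (logical), `missing_columns` (character),
#'   and `violations` (data.frame with columns row, column, issue).
#' @export
validate_thickness_table <- function(x) {
  if (is.character(x)) x <- read_thickness_table(x)
  codes <- dkt_region_codes()
  required <- c(covariate_columns(), codes)
  missing_cols <- setdiff(required, names(x))
  viol <- data.frame(row = integer(), column = character(),
                     issue = character(), stringsAsFactors = FALSE)
  for (code in intersect(codes, names(x))) {
    v <- x[[code]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      viol <- rbind(viol, data.frame(
        row = bad, column = code,
        issue = ifelse(is.finite(v[bad]), "non-positive", "non-finite"),
        stringsAsFactors = FALSE))
  }
  if (all(c("subject_id", "visit_time_months") %in% names(x))) {
    key <- paste(x$subject_id, x$visit_time_months,
                 if ("acquisition" %in% names(x)) x$acquisition else "")
    dup <- which(duplicated(key))
    if (length(dup))
      viol <- rbind(viol, data.frame(
        row = dup, column = "subject_id",
        issue = "duplicate (subject, visit) key", stringsAsFactors = FALSE))
  }
  list(valid = length(missing_cols) == 0L && nrow(viol) == 0L,
       missing_columns = missing_cols, violations = viol)
}
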