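# Scan-rescan repeatability via the intraclass correlation coefficient.
# The estimator is the two-way random-effects, average-measures ICC —
# ICC(2,k) with k = 2 acquisitions, the "average random rater" reading —
# computed from the mean squares of the subject x acquisition two-way
# ANOVA:
#
#   ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)
#
# where MSR, MSC, MSE are the subject, acquisition and residual mean
# squares and n the number of subjects.

#' Scan-rescan intraclass correlation per region
#'
#' @param rescan_table Table from [generate_scan_rescan()] (or any tidy
#'   thickness table with an `acquisition` column): exactly 2 acquisitions
#'   per subject, at least 5 subjects, complete design.
#' @return data.frame with one row per region: `region`, `icc`,
#'   `var_between` (between-subject variance component, mm^2) and
#'   `var_residual` (residual variance, mm^2).
#' @export
compute_icc <- function(rescan_table) {
  if (!"acquisition" %in% names(rescan_table))
    stop_config("rescan table needs an 'acquisition' column")
  counts <- table(rescan_table$subject_id, rescan_table$acquisition)
  if (ncol(counts) != 2L || any(counts != 1L))
    stop_config("design must be complete: exactly 2 acquisitions per subject")
  n <- nrow(counts)
  if (n < 5L) stop_config("need >= 5 subjects")
  k <- 2L
  codes <- intersect(dkt_region_codes(), names(rescan_table))
  if (length(codes) == 0L) stop_config("no region columns found")
  sub <- factor(rescan_table$subject_id)
  acq <- factor(rescan_table$acquisition)
  out <- lapply(codes, function(code) {
    x <- rescan_table[[code]]
    m <- mean(x)
    m_i <- tapply(x, sub, mean)
    m_j <- tapply(x, acq, mean)
    msr <- k * sum((m_i - m)^2) / (n - 1)
    msc <- n * sum((m_j - m)^2) / (k - 1)
    mse <- sum((x - m_i[sub] - m_j[acq] + m)^2) / ((n - 1) * (k - 1))
    icc <- (msr - mse) / (msr + (msc - mse) / n)
    data.frame(region = code, icc = icc,
               var_between = (msr - mse) / k, var_residual = mse,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
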