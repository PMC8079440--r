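# Lifespan regional models: per region an ordinary least-squares fit
# thickness ~ gender + age, used to predict thickness at representative ages
# (25, 50, 75 years) for each gender. Predictions are displayed relative to
# the single largest predicted value across every (pipeline, region, age,
# gender) cell — the normalization used by radar-style comparisons of
# regional thickness profiles between pipelines.

#' Fit per-region lifespan linear models
#'
#' @param table One-visit-per-subject tidy thickness table.
#' @return Named list (region-set order) of class `lifespan_models`; each
#'   element holds `coefficients` (intercept mm, gender mm, age mm/year),
#'   `sigma` (residual sd) and `df_residual`.
#' @export
fit_lifespan_models <- function(table) {
  if (nrow(table) < 10L) stop_config("need >= 10 subjects")
  if (length(unique(table$gender)) < 2L &&
      length(unique(table$age_baseline)) < 2L)
    stop_config("rank-deficient design: single gender and single age")
  codes <- dkt_region_codes()
  missing <- setdiff(codes, names(table))
  if (length(missing))
    stop_config("missing region column '%s'", missing[1])
  X <- stats::model.matrix(~ gender + age_baseline, data = table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_config("rank-deficient design: gender/age not both identifiable")
  Y <- as.matrix(table[, codes])
  coefs <- qr.coef(qrX, Y)          # 3 x 62
  resid <- qr.resid(qrX, Y)
  dfres <- nrow(X) - qrX$rank
  out <- lapply(seq_along(codes), function(k) {
    cf <- coefs[, k]
    names(cf) <- c("intercept", "gender", "age")
    list(region = codes[k], coefficients = cf,
         sigma = sqrt(sum(resid[, k]^2) / dfres), df_residual = dfres)
  })
  names(out) <- codes
  class(out) <- "lifespan_models"
  out
}

#' Predict relative (radar) thickness values across the lifespan
#'
#' Evaluates every pipeline's fitted lifespan models at the requested ages
#' for both genders and divides all predictions by the single maximum
#' predicted value over every (pipeline, region, age, gender) cell. The
#' reference cell (relative value exactly 1) is flagged. Requested ages
#' outside the fitted age range trigger a warning (extrapolation), not an
#' error.
#'
#' @param models Named list: one `lifespan_models` per pipeline.
#' @param ages Ages (years) at which to predict (default 25, 50, 75).
#' @param genders Gender codes to predict for (default `c(0, 1)`).
#' @param age_range Optional fitted-data age range used for the
#'   extrapolation warning.
#' @return data.frame with columns pipeline, region, hemisphere, age,
#'   gender, predicted_mm, relative_value, is_reference.
#' @export
predict_relative_thickness <- function(models, ages = c(25, 50, 75),
                                       genders = c(0, 1), age_range = NULL) {
  stopifnot(is.list(models), length(models) >= 1L)
  if (is.null(names(models)))
    names(models) <- paste0("pipeline", seq_along(models))
  if (!is.null(age_range) &&
      any(ages < age_range[1] | ages > age_range[2]))
    warning("requested age outside the fitted data range; extrapolating")
  regions <- dkt_regions()
  grid <- expand.grid(pipeline = names(models), region = regions$code,
                      age = ages, gender = genders,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$hemisphere <- regions$hemisphere[match(grid$region, regions$code)]
  grid$predicted_mm <- mapply(function(pl, rg, a, g) {
    cf <- models[[pl]][[rg]]$coefficients
    unname(cf["intercept"] + cf["gender"] * g + cf["age"] * a)
  }, grid$pipeline, grid$region, grid$age, grid$gender)
  ref <- which.max(grid$predicted_mm)
  grid$relative_value <- grid$predicted_mm / grid$predicted_mm[ref]
  grid$is_reference <- seq_len(nrow(grid)) == ref
  grid[, c("pipeline", "region", "hemisphere", "age", "gender",
           "predicted_mm", "relative_value", "is_reference")]
}

#' Paired t-test between two pipelines' predicted thickness profiles
#'
#' Two-sided paired t-test over matched (region, age, gender) cells of the
#' predicted thickness values. A zero-variance difference vector with a
#' nonzero mean is a degenerate case: flagged with a warning and reported
#' as the p -> 0 limit rather than dividing by zero; identical inputs give
#' t = 0, p = 1.
#'
#' @param pred_a,pred_b Radar tables from [predict_relative_thickness()]
#'   restricted to one pipeline each (or any data.frames with matched rows
#'   and a `predicted_mm` column).
#' @return List with `t`, `p_value`, `df`, `mean_difference`.
#' @export
paired_region_ttest <- function(pred_a, pred_b) {
  if (nrow(pred_a) != nrow(pred_b))
    stop_config("prediction tables must have matched cells")
  keys <- c("region", "age", "gender")
  if (all(keys %in% names(pred_a)) && all(keys %in% names(pred_b))) {
    ka <- do.call(paste, pred_a[keys])
    kb <- do.call(paste, pred_b[keys])
    if (!identical(sort(ka), sort(kb)))
      stop_config("region/age/gender cells do not match")
    if (!anyDuplicated(ka)) pred_b <- pred_b[match(ka, kb), ]
  }
  d <- pred_a$predicted_mm - pred_b$predicted_mm
  n <- length(d)
  if (n < 3L) stop_config("need >= 3 matched pairs")
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    if (mean(d) == 0) return(list(t = 0, p_value = 1, df = n - 1,
                                  mean_difference = 0))
    warning("zero-variance nonzero difference: reporting the p -> 0 limit")
    return(list(t = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                mean_difference = mean(d)))
  }
  tstat <- mean(d) / (sd_d / sqrt(n))
  list(t = tstat, p_value = 2 * stats::pt(-abs(tstat), df = n - 1),
       df = n - 1, mean_difference = mean(d))
}
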