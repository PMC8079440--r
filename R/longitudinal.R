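# Supervised longitudinal evaluation. For each region the change from
# baseline is modeled as
#
#   dY ~ Y_bl + AGE_bl + ICV_bl + APOE_bl + GENDER + DIAGNOSIS_bl
#        + VISIT:DIAGNOSIS_bl + (1 | subject) + (1 | site)
#
# fitted by REML (lme4). The VISIT:DIAGNOSIS_bl interaction (with no VISIT
# main effect) parameterizes one trajectory slope per diagnosis group, so
# the diagnostic contrasts LMCI-CN, AD-LMCI and AD-CN are differences of
# trajectory terms and do not depend on the factor coding. Multiplicity
# within the triple of contrasts is handled with the studentized-range
# (Tukey) distribution; across the 62 regions each contrast family is
# adjusted by Benjamini-Hochberg FDR.

DIAGNOSIS_LEVELS <- c("CN", "LMCI", "AD")
CONTRAST_LABELS <- c("LMCI-CN", "AD-LMCI", "AD-CN")

#' Build the change-from-baseline table
#'
#' One row per (subject, follow-up visit, region): the change in thickness
#' from the baseline visit plus the subject's baseline covariates. Subjects
#' lacking a visit at time 0 are excluded, with the exclusion count logged.
#'
#' @param table Longitudinal tidy thickness table.
#' @param regions Region codes to include (default all 62).
#' @return Long data.frame with columns subject_id, site, region, delta_y,
#'   y_bl, age_bl, icv_bl, apoe_bl, gender, diagnosis_bl, visit; attribute
#'   `n_excluded` counts subjects dropped for a missing baseline.
#' @export
prepare_delta <- function(table, regions = dkt_region_codes()) {
  missing <- setdiff(regions, names(table))
  if (length(missing))
    stop_config("missing region column '%s'", missing[1])
  has_bl <- tapply(table$visit_time_months, table$subject_id,
                   function(v) any(v == 0))
  excluded <- names(has_bl)[!has_bl]
  if (length(excluded)) {
    message(sprintf("excluding %d subject(s) without a baseline visit",
                    length(excluded)))
    table <- table[!table$subject_id %in% excluded, , drop = FALSE]
  }
  fu <- table[table$visit_time_months > 0, , drop = FALSE]
  if (nrow(fu) == 0L) stop_config("table has no follow-up visits")
  bl <- table[table$visit_time_months == 0, , drop = FALSE]
  bl_row <- match(fu$subject_id, bl$subject_id)
  n_fu <- nrow(fu)
  out <- do.call(rbind, lapply(regions, function(code) {
    data.frame(
      subject_id = fu$subject_id,
      site = fu$site,
      region = code,
      delta_y = fu[[code]] - bl[[code]][bl_row],
      y_bl = bl[[code]][bl_row],
      age_bl = bl$age_baseline[bl_row],
      icv_bl = bl$icv[bl_row],
      apoe_bl = bl$apoe[bl_row],
      gender = fu$gender,
      diagnosis_bl = bl$diagnosis[bl_row],
      visit = fu$visit_time_months,
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- length(excluded)
  out
}

#' Fit the baseline-change mixed model for one region
#'
#' REML linear mixed model of the change from baseline on baseline
#' covariates and diagnosis-specific trajectory slopes, with crossed random
#' intercepts for subject and site. ICV is rescaled to units of 10^6 mm^3
#' internally so all fixed-effect columns are of comparable magnitude. A
#' singular fit (e.g. the site variance estimated at zero) is not an error:
#' the model is returned with `boundary_fit = TRUE`.
#'
#' @param delta DeltaRecord rows for a single region (from
#'   [prepare_delta()]).
#' @param visit_coding `"continuous"` (months; the trajectory term is a
#'   slope in mm/month) or `"categorical"` (visit as a factor).
#' @return List of class `contrast_model`: `model` (the lmerMod),
#'   `boundary_fit`, `region`, `visit_coding`.
#' @export
fit_contrast_model <- function(delta,
                               visit_coding = c("continuous",
                                                "categorical")) {
  visit_coding <- match.arg(visit_coding)
  present <- unique(delta$diagnosis_bl)
  absent <- setdiff(DIAGNOSIS_LEVELS, present)
  if (length(absent))
    stop_config("missing diagnosis level: %s", paste(absent, collapse = ", "))
  if (length(unique(delta$site)) < 2L) stop_config("need >= 2 sites")
  per_group <- tapply(delta$subject_id, delta$diagnosis_bl,
                      function(s) length(unique(s)))
  if (any(per_group[DIAGNOSIS_LEVELS] < 2L))
    stop_config("need >= 2 subjects per diagnosis group")
  d <- delta
  d$diagnosis_bl <- factor(d$diagnosis_bl, levels = DIAGNOSIS_LEVELS)
  d$icv_bl <- d$icv_bl / 1e6
  if (visit_coding == "categorical") d$visit <- factor(d$visit)
  fit <- lme4::lmer(
    delta_y ~ y_bl + age_bl + icv_bl + apoe_bl + gender + diagnosis_bl +
      visit:diagnosis_bl + (1 | subject_id) + (1 | site),
    data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))
  structure(list(model = fit,
                 boundary_fit = lme4::isSingular(fit),
                 region = if ("region" %in% names(delta))
                   delta$region[1] else NA_character_,
                 visit_coding = visit_coding),
            class = "contrast_model")
}

#' Tukey diagnostic contrasts of the trajectory terms
#'
#' Pairwise differences of the three diagnosis-specific trajectory slopes
#' (LMCI-CN, AD-LMCI, AD-CN). Each contrast's p-value uses the studentized
#' range distribution with 3 means, so multiplicity within the triple is
#' handled Tukey-style; degrees of freedom are taken as a containment-type
#' residual df (observations minus fixed-effect rank minus subjects).
#'
#' @param cm A `contrast_model` (continuous visit coding).
#' @return data.frame: contrast, estimate (mm/month), se, t, df, p_raw.
#' @export
tukey_diagnostic_contrasts <- function(cm) {
  stopifnot(inherits(cm, "contrast_model"))
  if (cm$visit_coding != "continuous")
    stop_config("Tukey trajectory contrasts require continuous visit coding")
  fit <- cm$model
  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  slope_names <- paste0("diagnosis_bl", DIAGNOSIS_LEVELS, ":visit")
  if (!all(slope_names %in% names(fe)))
    stop_config("trajectory terms not found in the fitted model")
  cmat <- rbind("LMCI-CN" = c(-1, 1, 0),
                "AD-LMCI" = c(0, -1, 1),
                "AD-CN"  = c(-1, 0, 1))
  est <- as.numeric(cmat %*% fe[slope_names])
  v <- vc[slope_names, slope_names]
  se <- sqrt(diag(cmat %*% v %*% t(cmat)))
  n_obs <- stats::nobs(fit)
  n_sub <- lme4::ngrps(fit)[["subject_id"]]
  df <- max(n_obs - length(fe) - n_sub, 1)
  tval <- est / se
  p <- stats::ptukey(sqrt(2) * abs(tval), nmeans = 3, df = df,
                     lower.tail = FALSE)
  data.frame(contrast = CONTRAST_LABELS, estimate = est, se = se,
             t = tval, df = df, p_raw = p, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment of the region x contrast p matrix
#'
#' @param p_matrix Numeric matrix, regions x contrasts, raw p-values.
#' @param family `"contrast"` (default): BH applied down each contrast
#'   column across regions; `"global"`: BH over the whole matrix at once.
#' @param log_floor Floor applied before taking log10 (default 1e-300).
#' @return List with `adjusted` and `log10` matrices of the same shape.
#' @export
fdr_adjust <- function(p_matrix, family = c("contrast", "global"),
                       log_floor = 1e-300) {
  family <- match.arg(family)
  p_matrix <- as.matrix(p_matrix)
  if (any(!is.finite(p_matrix)) || any(p_matrix < 0) || any(p_matrix > 1))
    stop_config("p-values must lie in [0, 1]")
  adj <- if (family == "contrast")
    apply(p_matrix, 2, stats::p.adjust, method = "BH")
  else
    matrix(stats::p.adjust(p_matrix, method = "BH"), nrow(p_matrix),
           dimnames = dimnames(p_matrix))
  list(adjusted = adj, log10 = log10(pmax(adj, log_floor)))
}

#' Run the full longitudinal diagnostic-contrast evaluation
#'
#' prepare_delta -> per-region mixed-model fit -> Tukey trajectory
#' contrasts -> per-contrast BH-FDR across regions.
#'
#' @param table Longitudinal tidy thickness table.
#' @param regions Region codes (default all 62).
#' @param fdr_family Passed to [fdr_adjust()].
#' @param visit_coding Passed to [fit_contrast_model()].
#' @return data.frame with one row per region x contrast: region,
#'   hemisphere, contrast, estimate, p_raw, p_fdr, log10_p_fdr,
#'   boundary_fit_flag.
#' @export
run_longitudinal_evaluation <- function(table, regions = dkt_region_codes(),
                                        fdr_family = "contrast",
                                        visit_coding = "continuous") {
  delta <- prepare_delta(table, regions)
  rows <- list()
  pmat <- matrix(NA_real_, length(regions), 3L,
                 dimnames = list(regions, CONTRAST_LABELS))
  flags <- logical(length(regions))
  for (i in seq_along(regions)) {
    code <- regions[i]
    res <- tryCatch({
      cm <- fit_contrast_model(delta[delta$region == code, , drop = FALSE],
                               visit_coding = visit_coding)
      list(cm = cm, ct = tukey_diagnostic_contrasts(cm))
    }, error = function(e)
      stop_config("region %s: %s", code, conditionMessage(e)))
    pmat[i, ] <- res$ct$p_raw
    flags[i] <- res$cm$boundary_fit
    rows[[i]] <- res$ct
  }
  fdr <- fdr_adjust(pmat, family = fdr_family)
  hemis <- dkt_regions()
  out <- do.call(rbind, lapply(seq_along(regions), function(i) {
    data.frame(region = regions[i],
               hemisphere = hemis$hemisphere[match(regions[i], hemis$code)],
               contrast = CONTRAST_LABELS,
               estimate = rows[[i]]$estimate,
               p_raw = rows[[i]]$p_raw,
               p_fdr = fdr$adjusted[i, ],
               log10_p_fdr = fdr$log10[i, ],
               boundary_fit_flag = flags[i],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
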