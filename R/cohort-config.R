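#' Default per-region mean thickness profile
#'
#' Arbitrary but anatomically plausible region means (mm) used as generator
#' defaults. The entorhinal cortex is the maximum, and the right hemisphere
#' gets a small positive offset, so that with the default (negative) age
#' slope and positive male gender effect the largest predicted value over a
#' lifespan grid is the right entorhinal region for a young male — the
#' natural reference cell for relative (radar) thickness displays. These are
#' design defaults of the simulator, not estimates from any cohort.
#'
#' @return Named numeric vector of length 62 (mm), names = region codes.
#' @export
default_alpha0 <- function() {
  base <- c(
    cACC = 2.9, cMFG = 2.7, CUN = 1.9, ENT = 3.6, FUS = 2.8, IPL = 2.5,
    ITG = 2.9, iCC = 2.5, LOG = 2.2, LOF = 2.7, LING = 2.0, MOF = 2.5,
    MTG = 2.9, PARH = 2.8, paraC = 2.4, pOPER = 2.7, pORB = 2.9,
    pTRI = 2.6, periCAL = 1.7, postC = 2.0, PCC = 2.5, preC = 2.6,
    PCUN = 2.4, rACC = 3.0, rMFG = 2.5, SFG = 2.8, SPL = 2.2, STG = 2.9,
    SMAR = 2.6, TT = 2.4, INS = 3.1
  )
  codes <- dkt_region_codes()
  out <- c(base, base + 0.005)
  names(out) <- codes
  out
}

# recycle a scalar or validate a length-62 (optionally named) vector
expand_region_param <- function(x, what) {
  codes <- dkt_region_codes()
  if (length(x) == 1L) x <- rep(as.numeric(x), 62L)
  if (length(x) != 62L)
    stop_config("'%s' must be a scalar or a length-62 vector", what)
  if (!is.null(names(x)) && !identical(names(x), codes)) {
    if (!all(codes %in% names(x)))
      stop_config("'%s' names do not cover the region set", what)
    x <- x[codes]
  }
  x <- as.numeric(x)
  names(x) <- codes
  x
}

#' Generative configuration for synthetic thickness cohorts
#'
#' Bundles every parameter of the synthetic-data generators: cohort sizes and
#' visit schedule, per-region generative parameters of the hierarchical
#' linear-growth model (population mean `alpha0` in mm, population slope
#' `beta0` in mm/month, between-subject intercept sd `tau`, slope sd `rho`,
#' residual sd `sigma`, all in mm), diagnosis-specific additive slope
#' offsets, covariate effects, the second-pipeline measurement perturbation,
#' and the seed. Time is measured in months throughout; slopes are mm/month.
#'
#' @param group_sizes Named counts per diagnosis for the longitudinal cohort
#'   (default `c(CN = 197, LMCI = 324, AD = 142)`).
#' @param visit_schedule Visit times in months, strictly increasing from 0
#'   (default `seq(0, 36, by = 6)`).
#' @param n_sites Number of acquisition sites/datasets (labels `site1`...).
#' @param age_range Baseline age range in years (default `c(4, 94)`).
#' @param alpha0,beta0,tau,rho,sigma Per-region generative parameters;
#'   scalars are recycled over the 62 regions.
#' @param diagnosis_slope_offsets Named additive slope offsets (mm/month)
#'   per diagnosis group.
#' @param gender_effect Additive thickness effect (mm) of gender code 1
#'   (coding: 0 = female, 1 = male).
#' @param age_slope Cross-sectional age effect (mm/year), scalar or
#'   per-region.
#' @param site_sd Sd (mm) of the site random intercept added in longitudinal
#'   generation (default 0.02) so a site term is identifiable downstream.
#' @param retention_prob Per-visit retention probability after baseline
#'   (default 1 = no dropout); a missed visit truncates the schedule.
#' @param pipeline_b_noise_sd,pipeline_b_bias Cell-wise Gaussian noise sd and
#'   constant bias (mm) applied to create the second pipeline's measurements.
#' @param seed Integer master seed.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(group_sizes = c(CN = 197, LMCI = 324, AD = 142),
                          visit_schedule = seq(0, 36, by = 6),
                          n_sites = 5,
                          age_range = c(4, 94),
                          alpha0 = default_alpha0(),
                          beta0 = -0.002,
                          tau = 0.30,
                          rho = 0.005,
                          sigma = 0.10,
                          diagnosis_slope_offsets = c(CN = 0, LMCI = -0.002,
                                                      AD = -0.004),
                          gender_effect = 0.02,
                          age_slope = -0.01,
                          site_sd = 0.02,
                          retention_prob = 1,
                          pipeline_b_noise_sd = 0.05,
                          pipeline_b_bias = 0.02,
                          seed = 1L) {
  cfg <- list(
    group_sizes = group_sizes,
    visit_schedule = as.numeric(visit_schedule),
    n_sites = as.integer(n_sites),
    age_range = as.numeric(age_range),
    alpha0 = expand_region_param(alpha0, "alpha0"),
    beta0 = expand_region_param(beta0, "beta0"),
    tau = expand_region_param(tau, "tau"),
    rho = expand_region_param(rho, "rho"),
    sigma = expand_region_param(sigma, "sigma"),
    diagnosis_slope_offsets = diagnosis_slope_offsets,
    gender_effect = as.numeric(gender_effect),
    age_slope = expand_region_param(age_slope, "age_slope"),
    site_sd = as.numeric(site_sd),
    retention_prob = as.numeric(retention_prob),
    pipeline_b_noise_sd = as.numeric(pipeline_b_noise_sd),
    pipeline_b_bias = as.numeric(pipeline_b_bias),
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (any(cfg$tau < 0) || any(cfg$rho < 0) || any(cfg$sigma < 0) ||
      cfg$site_sd < 0 || cfg$pipeline_b_noise_sd < 0)
    stop_config("variance-scale parameters must be >= 0")
  if (any(cfg$group_sizes < 0))
    stop_config("group sizes must be >= 0")
  if (length(cfg$visit_schedule) < 1L)
    stop_config("visit schedule must be non-empty")
  if (cfg$visit_schedule[1] != 0 ||
      (length(cfg$visit_schedule) > 1L && any(diff(cfg$visit_schedule) <= 0)))
    stop_config("visit schedule must be strictly increasing from 0")
  if (length(cfg$age_range) != 2L || diff(cfg$age_range) < 0 ||
      cfg$age_range[1] <= 0)
    stop_config("age_range must be a positive, non-decreasing pair of years")
  if (cfg$n_sites < 1L) stop_config("n_sites must be >= 1")
  if (cfg$retention_prob < 0 || cfg$retention_prob > 1)
    stop_config("retention_prob must lie in [0, 1]")
  invisible(cfg)
}

#' Read a cohort configuration from a key-value text file
#'
#' The file holds one `key: value` pair per line (lists comma-separated,
#' named entries as `name=value`); keys match the arguments of
#' [cohort_config()]. Unknown keys are an error. Lines starting with `#`
#' are comments.
#'
#' @param path Path to the configuration file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop_config("cannot parse config line: '%s'", ln)
    key <- m[2]
    raw <- strsplit(m[3], ",")[[1]]
    raw <- trimws(raw)
    if (all(grepl("=", raw, fixed = TRUE))) {
      nm <- sub("=.*$", "", raw)
      val <- as.numeric(sub("^.*=", "", raw))
      names(val) <- trimws(nm)
    } else {
      val <- suppressWarnings(as.numeric(raw))
      if (anyNA(val)) val <- raw
    }
    args[[key]] <- val
  }
  unknown <- setdiff(names(args), names(formals(cohort_config)))
  if (length(unknown))
    stop_config("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(cohort_config, args)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes),
                                 x$group_sizes), collapse = " "), "\n")
  cat("  schedule (months):", paste(x$visit_schedule, collapse = ", "), "\n")
  cat("  sites:", x$n_sites, " age range:", paste(x$age_range,
                                                  collapse = "-"), "\n")
  cat(sprintf("  tau=%.3g rho=%.3g sigma=%.3g (region medians, mm)\n",
              stats::median(x$tau), stats::median(x$rho),
              stats::median(x$sigma)))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
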