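# Synthetic cohort generators. All thickness is in mm, time in months,
# age in years. Every generator derives its RNG stream from the config seed
# with derive_seed() so adding one generator call never perturbs another's
# randomness.

clip_positive <- function(mat, floor_mm = 1e-3) {
  n_clip <- sum(mat < floor_mm)
  if (n_clip > 0) {
    mat[mat < floor_mm] <- floor_mm
    message(sprintf("clipped %d non-positive thickness cells to %.0e mm",
                    n_clip, floor_mm))
  }
  attr(mat, "n_clipped") <- n_clip
  mat
}

sample_subject_covariates <- function(n, cfg, diagnosis) {
  apoe_freq <- c(CN = 0.15, LMCI = 0.25, AD = 0.35, none = 0.15)
  data.frame(
    subject_id = sprintf("sub%05d", seq_len(n)),
    site = paste0("site", sample.int(cfg$n_sites, n, replace = TRUE)),
    gender = stats::rbinom(n, 1L, 0.5),  # 0 = female, 1 = male
    age_baseline = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
    icv = pmax(stats::rnorm(n, 1.45e6, 1.4e5), 8e5),
    diagnosis = diagnosis,
    apoe = stats::rbinom(n, 2L, apoe_freq[diagnosis]),
    stringsAsFactors = FALSE
  )
}

assemble_table <- function(subjects, visit_time, thickness) {
  out <- data.frame(
    subject_id = subjects$subject_id,
    site = subjects$site,
    visit_time_months = visit_time,
    gender = subjects$gender,
    age_baseline = subjects$age_baseline,
    icv = subjects$icv,
    diagnosis = subjects$diagnosis,
    apoe = subjects$apoe,
    stringsAsFactors = FALSE
  )
  thickness <- as.data.frame(thickness)
  names(thickness) <- dkt_region_codes()
  cbind(out, thickness)
}

#' Generate a multi-site cross-sectional thickness cohort
#'
#' One visit per subject. Per region k the generated thickness is
#' `alpha0_k + age_slope_k * age + gender_effect * gender + u_i + e`, with
#' subject intercept `u_i ~ N(0, tau_k^2)` (shared correlation across
#' regions of one subject) and residual `e ~ N(0, sigma_k^2)`. Ages are
#' uniform over the configured range (default 4-94 years, emulating pooled
#' multi-site lifespan cohorts); sites are uniform labels.
#'
#' @param config A [cohort_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @return List with `subjects` (covariate data.frame) and `table` (tidy
#'   thickness table, one row per subject). The table carries attribute
#'   `n_clipped`, the count of cells clipped to stay positive.
#' @export
generate_cross_sectional <- function(config, n_subjects) {
  validate_cohort_config(config)
  if (n_subjects < 1L) stop_config("n_subjects must be >= 1")
  set.seed(derive_seed(config$seed, "cross_sectional", n_subjects))
  subjects <- sample_subject_covariates(n_subjects, config, "none")
  K <- 62L
  u <- stats::rnorm(n_subjects)  # shared standard intercept, scaled per region
  thick <- matrix(0, n_subjects, K)
  for (k in seq_len(K)) {
    thick[, k] <- config$alpha0[k] +
      config$age_slope[k] * subjects$age_baseline +
      config$gender_effect * subjects$gender +
      config$tau[k] * u +
      stats::rnorm(n_subjects, 0, config$sigma[k])
  }
  thick <- clip_positive(thick)
  tab <- assemble_table(subjects, 0, thick)
  attr(tab, "n_clipped") <- attr(thick, "n_clipped")
  list(subjects = subjects, table = tab)
}

#' Generate a three-group longitudinal thickness cohort
#'
#' Emulates an ADNI-like design: diagnosis groups of configured sizes
#' (default 197 CN / 324 LMCI / 142 AD), visits every 6 months up to 36
#' months. Per subject i and region k:
#' intercept `a_ik ~ N(alpha0_k, tau_k^2)`, slope
#' `b_ik ~ N(beta0_k + offset(diagnosis), rho_k^2)` (mm/month), and
#' `Y_ikj = a_ik + s(site, k) + b_ik * t_j + N(0, sigma_k^2)` where
#' `s(site, k) ~ N(0, site_sd^2)` is a site random intercept. Optional
#' dropout truncates each subject's schedule at the first missed visit
#' (per-visit retention probability `retention_prob`).
#'
#' @param config A [cohort_config()].
#' @return List with `subjects`, `table` (one row per subject-visit), and
#'   `true_params` (the per-region generative values, for recovery checks).
#' @export
generate_longitudinal <- function(config) {
  validate_cohort_config(config)
  if (length(config$visit_schedule) < 1L)
    stop_config("visit schedule is empty")
  set.seed(derive_seed(config$seed, "longitudinal"))
  sizes <- config$group_sizes
  diagnosis <- rep(names(sizes), times = sizes)
  n <- length(diagnosis)
  if (n < 1L) stop_config("no subjects configured")
  subjects <- sample_subject_covariates(n, config, diagnosis)
  K <- 62L
  tt <- config$visit_schedule
  J <- length(tt)

  # per-subject schedule truncation at first missed visit
  n_vis <- rep(J, n)
  if (config$retention_prob < 1) {
    for (i in seq_len(n)) {
      keep <- J
      for (j in 2:J) {
        if (stats::runif(1) > config$retention_prob) { keep <- j - 1L; break }
      }
      n_vis[i] <- keep
    }
  }
  row_sub <- rep(seq_len(n), times = n_vis)
  row_t <- unlist(lapply(n_vis, function(m) tt[seq_len(m)]), use.names = FALSE)
  n_obs <- length(row_t)

  site_levels <- sort(unique(subjects$site))
  offs <- config$diagnosis_slope_offsets[subjects$diagnosis]

  thick <- matrix(0, n_obs, K)
  for (k in seq_len(K)) {
    a_i <- stats::rnorm(n, config$alpha0[k], config$tau[k])
    b_i <- stats::rnorm(n, config$beta0[k] + offs, config$rho[k])
    s_site <- stats::rnorm(length(site_levels), 0, config$site_sd)
    names(s_site) <- site_levels
    thick[, k] <- a_i[row_sub] + s_site[subjects$site[row_sub]] +
      b_i[row_sub] * row_t + stats::rnorm(n_obs, 0, config$sigma[k])
  }
  thick <- clip_positive(thick)
  tab <- assemble_table(subjects[row_sub, ], row_t, thick)
  rownames(tab) <- NULL
  attr(tab, "n_clipped") <- attr(thick, "n_clipped")
  list(subjects = subjects, table = tab,
       true_params = list(alpha0 = config$alpha0, beta0 = config$beta0,
                          tau = config$tau, rho = config$rho,
                          sigma = config$sigma))
}

#' Generate a scan-rescan repeatability table
#'
#' Two same-day acquisitions per subject: both share the subject's true
#' regional value `alpha0_k + N(0, tau_k^2)` and receive independent
#' residuals of sd `sigma_k`. The `acquisition` column (1 or 2) records the
#' repeat index; both rows have visit time 0.
#'
#' @param config A [cohort_config()].
#' @param n_subjects Number of subjects (>= 2; the intraclass correlation is
#'   undefined for fewer).
#' @return Tidy thickness table with `2 * n_subjects` rows and an extra
#'   `acquisition` column.
#' @export
generate_scan_rescan <- function(config, n_subjects) {
  validate_cohort_config(config)
  if (n_subjects < 2L)
    stop_config("n_subjects must be >= 2 (ICC undefined otherwise)")
  set.seed(derive_seed(config$seed, "scan_rescan", n_subjects))
  subjects <- sample_subject_covariates(n_subjects, config, "none")
  K <- 62L
  truth <- matrix(0, n_subjects, K)
  for (k in seq_len(K))
    truth[, k] <- stats::rnorm(n_subjects, config$alpha0[k], config$tau[k])
  meas <- rbind(truth, truth) +
    matrix(stats::rnorm(2L * n_subjects * K, 0,
                        rep(config$sigma, each = 2L * n_subjects)),
           2L * n_subjects, K)
  meas <- clip_positive(meas)
  idx <- rep(seq_len(n_subjects), 2L)
  tab <- assemble_table(subjects[idx, ], 0, meas)
  tab$acquisition <- rep(1:2, each = n_subjects)
  rownames(tab) <- NULL
  attr(tab, "n_clipped") <- attr(meas, "n_clipped")
  tab
}

#' Emulate a second measurement pipeline on an existing table
#'
#' Pipeline A is the input unchanged; pipeline B adds a constant bias and
#' independent cell-wise Gaussian noise (`pipeline_b_bias`,
#' `pipeline_b_noise_sd` of the config) to every thickness cell, clipped to
#' stay positive. Row keys and covariates are identical between the two
#' outputs, emulating two software pipelines measuring the same scans.
#'
#' @param table A tidy thickness table.
#' @param config A [cohort_config()].
#' @return List with elements `A` and `B`.
#' @export
emulate_pipeline_pair <- function(table, config) {
  validate_cohort_config(config)
  if (nrow(table) == 0L) stop_config("input table is empty")
  set.seed(derive_seed(config$seed, "pipeline_b", nrow(table)))
  codes <- dkt_region_codes()
  missing <- setdiff(codes, names(table))
  if (length(missing))
    stop_config("table lacks region columns: %s",
                paste(utils::head(missing, 3), collapse = ", "))
  b <- table
  m <- as.matrix(table[, codes]) + config$pipeline_b_bias
  if (config$pipeline_b_noise_sd > 0)
    m <- m + matrix(stats::rnorm(length(m), 0, config$pipeline_b_noise_sd),
                    nrow(m), ncol(m))
  m <- clip_positive(m)
  b[, codes] <- m
  attr(b, "n_clipped") <- attr(m, "n_clipped")
  list(A = table, B = b)
}
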