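# Shared fixtures, built in code at test time.

# small, fast cohort configuration
small_config <- function(...) {
  cohort_config(group_sizes = c(CN = 20, LMCI = 20, AD = 20),
                n_sites = 3, age_range = c(55, 90), seed = 101L, ...)
}

# noiseless configuration: every stochastic term off; overrides allowed
silent_config <- function(...) {
  args <- list(tau = 0, rho = 0, sigma = 0, site_sd = 0,
               gender_effect = 0, age_slope = 0,
               diagnosis_slope_offsets = c(CN = 0, LMCI = 0, AD = 0),
               pipeline_b_noise_sd = 0, pipeline_b_bias = 0, seed = 7L)
  user <- list(...)
  args[names(user)] <- user
  do.call(cohort_config, args)
}

# hand-made one-subject-per-row table with given region values
toy_table <- function(values, visit = 0, subject = NULL, acquisition = NULL) {
  n <- nrow(values)
  tab <- data.frame(
    subject_id = subject %||% sprintf("s%02d", seq_len(n)),
    site = "site1",
    visit_time_months = visit,
    gender = 0, age_baseline = 50, icv = 1.4e6,
    diagnosis = "none", apoe = 0,
    stringsAsFactors = FALSE)
  values <- as.data.frame(values)
  names(values) <- dkt_region_codes()[seq_len(ncol(values))]
  tab <- cbind(tab, values)
  if (!is.null(acquisition)) tab$acquisition <- acquisition
  tab
}

# quick mcmc settings for unit tests
fast_mcmc <- function(seed = 1L, n_chains = 2, n_iterations = 1200,
                      n_warmup = 400) {
  mcmc_config(n_chains = n_chains, n_iterations = n_iterations,
              n_warmup = n_warmup, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
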