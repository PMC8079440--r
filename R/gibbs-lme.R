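# Bayesian hierarchical linear mixed-effects model for one region's
# longitudinal thickness series:
#
#   Y_ij ~ N(a_i + b_i * t_ij, sigma^2)
#   a_i  ~ N(alpha0, tau^2)        b_i ~ N(beta0, rho^2)
#   alpha0, beta0 ~ N(0, mean_prior_sd^2)
#   sigma, tau, rho ~ half-Cauchy(0, cauchy_scale)
#
# The sampler is a Gibbs scheme in which every step is conditionally
# conjugate: the half-Cauchy scale priors are represented by the
# inverse-gamma mixture  s^2 | psi ~ IG(1/2, 1/psi), psi ~ IG(1/2, 1/A^2),
# whose marginal for s is exactly half-Cauchy(0, A). A slice-sampling
# update for the scales is available as an independent fallback and must
# agree with the conjugate route.
#
# The quantity of interest is the variance ratio r = tau / sigma: the
# between-subject variability of a region relative to its residual
# (within-subject, measurement) variability. Larger r means the measurement
# separates individuals better from noise, i.e. a more reliable biomarker.

#' Prior configuration for the hierarchical model
#'
#' @param mean_prior_sd Standard deviation of the Normal(0, .) prior on the
#'   population intercept and slope (default 10; the scale parameter is
#'   interpreted as a standard deviation, the convention of mainstream
#'   Bayesian sampling software).
#' @param cauchy_scale Scale of the half-Cauchy prior on the three
#'   variance-scale parameters (default 5).
#' @return List of class `prior_config`.
#' @export
prior_config <- function(mean_prior_sd = 10, cauchy_scale = 5) {
  if (mean_prior_sd <= 0 || cauchy_scale <= 0)
    stop_config("prior scales must be > 0")
  structure(list(mean_prior_sd = mean_prior_sd, cauchy_scale = cauchy_scale),
            class = "prior_config")
}

#' MCMC configuration
#'
#' @param n_chains Number of chains (>= 2, default 4).
#' @param n_iterations Iterations per chain including warmup (default 2000).
#' @param n_warmup Warmup iterations discarded per chain (default 1000).
#' @param seed Integer seed.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 4, n_iterations = 2000, n_warmup = 1000,
                        seed = 1L) {
  if (n_chains < 2) stop_config("n_chains must be >= 2")
  if (n_warmup < 1 || n_iterations <= n_warmup)
    stop_config("need n_iterations > n_warmup >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

rinvgamma1 <- function(shape, scale) 1 / stats::rgamma(1L, shape, rate = scale)

# univariate stepping-out slice sampler (Neal 2003) on an unbounded scale
slice_step <- function(x0, logf, w = 0.5, m = 50L) {
  y <- logf(x0) - stats::rexp(1L)
  u <- stats::runif(1L)
  l <- x0 - w * u
  r <- l + w
  j <- floor(m * stats::runif(1L))
  k <- m - 1 - j
  while (j > 0 && logf(l) > y) { l <- l - w; j <- j - 1 }
  while (k > 0 && logf(r) > y) { r <- r + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1L, l, r)
    if (logf(x1) >= y) return(x1)
    if (x1 < x0) l <- x1 else r <- x1
  }
}

# draw a variance-scale parameter given its sum of squares:
# p(s | ...) propto s^{-n} exp(-ss/(2 s^2)) * halfCauchy(s; A), via slice
# sampling on log(s)
slice_scale <- function(s0, n, ss, A) {
  logf <- function(ls) {
    s2 <- exp(2 * ls)
    -n * ls - ss / (2 * s2) - log1p(s2 / A^2) + ls
  }
  exp(slice_step(log(s0), logf))
}

#' Extract one region's longitudinal observations from a tidy table
#'
#' @param table Tidy thickness table.
#' @param region Region code (e.g. `"lh_ENT"`).
#' @return data.frame with columns `subject_id`, `t` (months), `y` (mm).
#' @export
region_observations <- function(table, region) {
  if (!region %in% names(table))
    stop_config("missing region column '%s' in table", region)
  data.frame(subject_id = table$subject_id, t = table$visit_time_months,
             y = table[[region]], stringsAsFactors = FALSE)
}

#' Fit the hierarchical model to one region by Gibbs sampling
#'
#' @param visits data.frame with columns `subject_id`, `t` (months), `y`
#'   (mm), as produced by [region_observations()].
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()].
#' @param region Label stored on the result.
#' @param method `"pe"` for the conjugate inverse-gamma parameter-expansion
#'   updates of the half-Cauchy scales (default), `"slice"` for direct slice
#'   sampling of the scales.
#' @param include_slopes If `FALSE`, subject slopes and the population slope
#'   are fixed at zero (intercept-only variant, used e.g. for closed-form
#'   cross-checks on scan-like data).
#' @param fix_scales Optional named list/vector with any of `tau`, `rho`,
#'   `sigma`: those scales are held fixed instead of sampled (testing hook
#'   for conjugate closed-form checks).
#' @return An object of class `region_posterior`: pooled post-warmup draws
#'   of `alpha0`, `beta0`, `tau`, `rho`, `sigma` and the derived ratio `r`,
#'   posterior median and central 95% credible interval of `r`, split R-hat
#'   and effective sample size per parameter, and a `converged` flag
#'   (FALSE if any R-hat exceeds 1.1; reported as a warning flag, never an
#'   error).
#' @export
fit_region_lme <- function(visits, priors = prior_config(),
                           mcmc = mcmc_config(), region = "region",
                           method = c("pe", "slice"),
                           include_slopes = TRUE, fix_scales = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(priors, "prior_config"), inherits(mcmc, "mcmc_config"))
  if (!all(c("subject_id", "t", "y") %in% names(visits)))
    stop_config("visits must have columns subject_id, t, y")
  visits <- visits[is.finite(visits$y), , drop = FALSE]
  sub <- factor(visits$subject_id)
  N <- nlevels(sub)
  if (N < 2L) stop_config("need >= 2 subjects")
  idx <- as.integer(sub)
  n_i <- tabulate(idx, N)
  if (max(n_i) < 2L)
    stop_config(paste("non-identifiable: every subject has a single visit,",
                      "so residual and slope variability are confounded"))
  y <- visits$y
  t <- visits$t
  n_obs <- length(y)
  sum_t <- as.numeric(rowsum(t, idx))
  sum_t2 <- as.numeric(rowsum(t^2, idx))
  A <- priors$cauchy_scale
  s0sq <- priors$mean_prior_sd^2
  fixed <- function(nm) !is.null(fix_scales) && nm %in% names(fix_scales)

  n_keep <- mcmc$n_iterations - mcmc$n_warmup
  pars <- c("alpha0", "beta0", "tau", "rho", "sigma")
  draws <- array(NA_real_, c(n_keep, mcmc$n_chains, 5L),
                 dimnames = list(NULL, NULL, pars))

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(derive_seed(mcmc$seed, "chain", ch))
    # data-based initialization with per-chain jitter
    ybar_i <- as.numeric(rowsum(y, idx)) / n_i
    a <- ybar_i + stats::rnorm(N, 0, 0.01)
    b <- rep(0, N)
    alpha0 <- mean(y) + stats::rnorm(1L, 0, 0.05)
    beta0 <- 0
    tau <- if (fixed("tau")) fix_scales[["tau"]] else
      max(stats::sd(ybar_i), 0.05) * exp(stats::rnorm(1L, 0, 0.2))
    sigma <- if (fixed("sigma")) fix_scales[["sigma"]] else
      max(stats::sd(y - ybar_i[idx]), 0.05) * exp(stats::rnorm(1L, 0, 0.2))
    rho <- if (fixed("rho")) fix_scales[["rho"]] else
      0.01 * exp(stats::rnorm(1L, 0, 0.2))
    psi_tau <- psi_rho <- psi_sigma <- 1

    for (it in seq_len(mcmc$n_iterations)) {
      # subject intercepts
      prec_a <- n_i / sigma^2 + 1 / tau^2
      s_a <- as.numeric(rowsum(y - b[idx] * t, idx))
      a <- (s_a / sigma^2 + alpha0 / tau^2) / prec_a +
        stats::rnorm(N) / sqrt(prec_a)
      if (include_slopes) {
        # subject slopes
        prec_b <- sum_t2 / sigma^2 + 1 / rho^2
        s_b <- as.numeric(rowsum((y - a[idx]) * t, idx))
        b <- (s_b / sigma^2 + beta0 / rho^2) / prec_b +
          stats::rnorm(N) / sqrt(prec_b)
        # population slope
        prec0 <- N / rho^2 + 1 / s0sq
        beta0 <- sum(b) / rho^2 / prec0 + stats::rnorm(1L) / sqrt(prec0)
      }
      # population intercept
      prec0 <- N / tau^2 + 1 / s0sq
      alpha0 <- sum(a) / tau^2 / prec0 + stats::rnorm(1L) / sqrt(prec0)

      ss_tau <- sum((a - alpha0)^2)
      ss_rho <- sum((b - beta0)^2)
      resid <- y - a[idx] - b[idx] * t
      ss_sig <- sum(resid^2)

      if (method == "pe") {
        if (!fixed("tau")) {
          psi_tau <- rinvgamma1(1, 1 / tau^2 + 1 / A^2)
          tau <- sqrt(rinvgamma1((N + 1) / 2, 1 / psi_tau + ss_tau / 2))
        }
        if (include_slopes && !fixed("rho")) {
          psi_rho <- rinvgamma1(1, 1 / rho^2 + 1 / A^2)
          rho <- sqrt(rinvgamma1((N + 1) / 2, 1 / psi_rho + ss_rho / 2))
        }
        if (!fixed("sigma")) {
          psi_sigma <- rinvgamma1(1, 1 / sigma^2 + 1 / A^2)
          sigma <- sqrt(rinvgamma1((n_obs + 1) / 2,
                                   1 / psi_sigma + ss_sig / 2))
        }
      } else {
        if (!fixed("tau")) tau <- slice_scale(tau, N, ss_tau, A)
        if (include_slopes && !fixed("rho"))
          rho <- slice_scale(rho, N, ss_rho, A)
        if (!fixed("sigma")) sigma <- slice_scale(sigma, n_obs, ss_sig, A)
      }

      if (it > mcmc$n_warmup)
        draws[it - mcmc$n_warmup, ch, ] <- c(alpha0, beta0, tau, rho, sigma)
    }
  }

  pooled <- do.call(rbind, lapply(seq_len(mcmc$n_chains),
                                  function(ch) draws[, ch, ]))
  colnames(pooled) <- pars
  pooled <- cbind(pooled, r = pooled[, "tau"] / pooled[, "sigma"])
  rh <- vapply(pars, function(p) rhat(draws[, , p]), numeric(1))
  es <- vapply(pars, function(p) ess(draws[, , p]), numeric(1))
  if (!include_slopes) { rh[c("beta0", "rho")] <- NA; es[c("beta0", "rho")] <- NA }
  if (!is.null(fix_scales)) {
    rh[names(rh) %in% names(fix_scales)] <- NA
    es[names(es) %in% names(fix_scales)] <- NA
  }
  q <- empirical_quantile(pooled[, "r"], c(0.025, 0.5, 0.975))
  structure(list(region = region,
                 draws = pooled,
                 chain_draws = draws,
                 r_median = q[2], r_ci_95 = c(q[1], q[3]),
                 rhat = rh, ess = es,
                 converged = all(is.na(rh) | rh < 1.1),
                 n_subjects = N, n_obs = n_obs,
                 method = method, include_slopes = include_slopes),
            class = "region_posterior")
}

# empirical (inverse-ECDF, type 1) percentile: sorted[ceiling(n * p)]
empirical_quantile <- function(x, probs) {
  xs <- sort(x)
  n <- length(xs)
  xs[pmax(1L, ceiling(n * probs))]
}

#' Posterior variance ratio of a fitted region
#'
#' The ratio r = tau / sigma is formed draw-by-draw and summarized by its
#' empirical posterior median and central 95% interval.
#'
#' @param posterior A `region_posterior`.
#' @return List with `r_median` and `r_ci_95` (length-2 vector).
#' @export
variance_ratio <- function(posterior) {
  stopifnot(inherits(posterior, "region_posterior"))
  r <- posterior$draws[, "r"]
  if (length(r) < 100L) stop_config("need >= 100 retained draws")
  if (any(posterior$draws[, "sigma"] <= 0))
    stop("internal consistency error: non-positive sigma draw")
  q <- empirical_quantile(r, c(0.025, 0.5, 0.975))
  list(r_median = q[2], r_ci_95 = c(q[1], q[3]))
}

#' Fit the hierarchical model to every region of a table
#'
#' Each region is fitted independently with a chain seed derived
#' deterministically from the master seed and the region code, so results do
#' not depend on execution order and adding regions never perturbs others.
#'
#' @param table Tidy thickness table (longitudinal).
#' @param priors A [prior_config()].
#' @param mcmc An [mcmc_config()]; its seed acts as the master seed.
#' @param regions Region codes to fit (default: all 62).
#' @param verbose Print one progress line per region.
#' @param ... Passed to [fit_region_lme()].
#' @return Named list of `region_posterior` objects in region-set order,
#'   class `region_posterior_list`.
#' @export
fit_all_regions <- function(table, priors = prior_config(),
                            mcmc = mcmc_config(), regions = dkt_region_codes(),
                            verbose = FALSE, ...) {
  missing <- setdiff(regions, names(table))
  if (length(missing))
    stop_config("missing region column '%s' in table", missing[1])
  out <- vector("list", length(regions))
  names(out) <- regions
  for (code in regions) {
    m <- mcmc
    m$seed <- derive_seed(mcmc$seed, code)
    out[[code]] <- fit_region_lme(region_observations(table, code),
                                  priors = priors, mcmc = m, region = code,
                                  ...)
    if (verbose) message(sprintf("  %s: r = %.2f [%.2f, %.2f]", code,
                                 out[[code]]$r_median,
                                 out[[code]]$r_ci_95[1],
                                 out[[code]]$r_ci_95[2]))
  }
  class(out) <- "region_posterior_list"
  out
}

#' Summarize fitted regions across one or more pipelines
#'
#' @param results Named list: one `region_posterior_list` per pipeline.
#' @return List with `per_region` (one row per pipeline x region: posterior
#'   medians of sigma, tau and r plus the 95% interval of r) and
#'   `across_regions` (per pipeline and statistic, the across-region
#'   quartiles of the per-region medians; long format).
#' @export
summarize_pipelines <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  if (is.null(names(results)))
    names(results) <- paste0("pipeline", seq_along(results))
  region_sets <- lapply(results, names)
  if (length(unique(vapply(region_sets, paste, character(1),
                           collapse = ","))) != 1L)
    stop_config("pipelines have mismatched region sets")
  per_region <- do.call(rbind, lapply(names(results), function(pl) {
    rp <- results[[pl]]
    data.frame(
      pipeline = pl,
      region = names(rp),
      sigma_median = vapply(rp, function(p)
        empirical_quantile(p$draws[, "sigma"], 0.5), numeric(1)),
      tau_median = vapply(rp, function(p)
        empirical_quantile(p$draws[, "tau"], 0.5), numeric(1)),
      r_median = vapply(rp, function(p) p$r_median, numeric(1)),
      r_lo = vapply(rp, function(p) p$r_ci_95[1], numeric(1)),
      r_hi = vapply(rp, function(p) p$r_ci_95[2], numeric(1)),
      stringsAsFactors = FALSE)
  }))
  rownames(per_region) <- NULL
  across <- do.call(rbind, lapply(names(results), function(pl) {
    sub <- per_region[per_region$pipeline == pl, ]
    do.call(rbind, lapply(c(sigma = "sigma_median", tau = "tau_median",
                            r = "r_median"), function(col) {
      q <- stats::quantile(sub[[col]], c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(pipeline = pl, statistic = sub("_median$", "", col),
                 q25 = q[1], q50 = q[2], q75 = q[3],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(across) <- NULL
  list(per_region = per_region, across_regions = across)
}

#' Write the per-region posterior summary CSV
#'
#' Columns: region, alpha0, beta0, tau, rho, sigma (posterior medians),
#' r_median, r_lo, r_hi, rhat_max, ess_min.
#'
#' @param results A `region_posterior_list`.
#' @param path Output CSV path.
#' @return The summary data.frame, invisibly.
#' @export
write_posterior_summary <- function(results, path) {
  med <- function(p, nm) empirical_quantile(p$draws[, nm], 0.5)
  df <- do.call(rbind, lapply(results, function(p) data.frame(
    region = p$region,
    alpha0 = med(p, "alpha0"), beta0 = med(p, "beta0"),
    tau = med(p, "tau"), rho = med(p, "rho"), sigma = med(p, "sigma"),
    r_median = p$r_median, r_lo = p$r_ci_95[1], r_hi = p$r_ci_95[2],
    rhat_max = max(p$rhat, na.rm = TRUE),
    ess_min = min(p$ess, na.rm = TRUE),
    stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' @export
print.region_posterior <- function(x, ...) {
  cat(sprintf("<region_posterior %s> %d subjects, %d obs, %d draws\n",
              x$region, x$n_subjects, x$n_obs, nrow(x$draws)))
  cat(sprintf("  r = %.3f [%.3f, %.3f]   max R-hat = %.3f%s\n",
              x$r_median, x$r_ci_95[1], x$r_ci_95[2],
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  (NOT converged)"))
  invisible(x)
}
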