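# construct a minimal region_posterior by hand (for summary-path tests)
fake_posterior <- function(tau, sigma, region = "lh_cACC") {
  n <- length(tau)
  draws <- cbind(alpha0 = rep(2.5, n), beta0 = rep(0, n), tau = tau,
                 rho = rep(0.01, n), sigma = sigma, r = tau / sigma)
  q <- sort(tau / sigma)[pmax(1, ceiling(n * c(0.025, 0.5, 0.975)))]
  structure(list(region = region, draws = draws,
                 r_median = q[2], r_ci_95 = c(q[1], q[3]),
                 rhat = c(alpha0 = 1), ess = c(alpha0 = n), converged = TRUE,
                 n_subjects = 10, n_obs = 30, method = "pe",
                 include_slopes = TRUE),
            class = "region_posterior")
}

test_that("constant tau and sigma draws give an exact variance ratio", {
  p <- fake_posterior(rep(0.2, 200), rep(0.1, 200))
  vr <- variance_ratio(p)
  expect_identical(vr$r_median, 2)
  expect_identical(unname(vr$r_ci_95), c(2, 2))
})

test_that("credible intervals match a brute-force sort-based percentile", {
  set.seed(88)
  tau <- rlnorm(501, -1, 0.3)
  sigma <- rlnorm(501, -2, 0.2)
  vr <- variance_ratio(fake_posterior(tau, sigma))
  r <- sort(tau / sigma)
  expect_identical(vr$r_median, r[ceiling(501 * 0.5)])
  expect_identical(unname(vr$r_ci_95),
                   c(r[ceiling(501 * 0.025)], r[ceiling(501 * 0.975)]))
  expect_error(variance_ratio(fake_posterior(rep(0.2, 50), rep(0.1, 50))),
               ">= 100")
})

test_that("identifiability and configuration contracts are enforced", {
  d <- data.frame(subject_id = c("a", "b", "c"), t = 0, y = c(2, 3, 2.5))
  expect_error(fit_region_lme(d), "non-identifiable")
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  expect_error(mcmc_config(n_iterations = 100, n_warmup = 100),
               "n_iterations")
  expect_error(prior_config(cauchy_scale = 0), "prior scales")
})

test_that("with fixed scales the population intercept matches the conjugate
           closed form", {
  set.seed(12)
  N <- 5; tt <- c(0, 6, 12)
  a <- rnorm(N, 2.5, 0.05)
  b <- rnorm(N, -0.002, 0.005)
  d <- data.frame(subject_id = rep(sprintf("s%d", 1:N), each = 3),
                  t = rep(tt, N),
                  y = rep(a, each = 3) + rep(b, each = 3) * rep(tt, N) +
                    rnorm(3 * N, 0, 0.05))
  scales <- c(tau = 0.05, rho = 0.005, sigma = 0.05)
  # closed form: integrate the random effects, GLS with the N(0, 100) prior
  Z <- kronecker(diag(N), rep(1, 3))
  Zt <- Z * d$t
  V <- scales["sigma"]^2 * diag(3 * N) +
    scales["tau"]^2 * tcrossprod(Z) + scales["rho"]^2 * tcrossprod(Zt)
  X <- cbind(1, d$t)
  Vi <- solve(V)
  P <- t(X) %*% Vi %*% X + diag(2) / 100
  Pm <- solve(P, t(X) %*% Vi %*% d$y)
  alpha0_mean <- Pm[1]
  alpha0_sd <- sqrt(solve(P)[1, 1])

  fit <- fit_region_lme(
    d, mcmc = mcmc_config(n_chains = 2, n_iterations = 30000,
                          n_warmup = 2000, seed = 4),
    fix_scales = scales)
  expect_lt(abs(mean(fit$draws[, "alpha0"]) - alpha0_mean), 1e-3)
  expect_lt(abs(sd(fit$draws[, "alpha0"]) - alpha0_sd) / alpha0_sd, 0.05)
})

test_that("conjugate and slice-sampling scale updates agree", {
  set.seed(42)
  N <- 4
  a <- rnorm(N, 2.5, 0.3)
  d <- data.frame(subject_id = rep(paste0("s", 1:N), each = 3),
                  t = rep(c(0, 6, 12), N),
                  y = rep(a, each = 3) + rnorm(3 * N, 0, 0.15))
  mc <- mcmc_config(n_chains = 2, n_iterations = 6000, n_warmup = 1000,
                    seed = 9)
  f_pe <- fit_region_lme(d, mcmc = mc, include_slopes = FALSE)
  f_sl <- fit_region_lme(d, mcmc = mc, include_slopes = FALSE,
                         method = "slice")
  for (par in c("tau", "sigma")) {
    m1 <- median(f_pe$draws[, par])
    m2 <- median(f_sl$draws[, par])
    expect_lt(abs(m1 - m2) / m1, 0.05)
  }
})

test_that("per-region fits are deterministic and order-independent", {
  cfg <- cohort_config(group_sizes = c(CN = 40), n_sites = 2,
                       diagnosis_slope_offsets = c(CN = 0), seed = 55)
  tab <- generate_longitudinal(cfg)$table
  mc <- fast_mcmc(seed = 6, n_iterations = 600, n_warmup = 200)
  two <- fit_all_regions(tab, mcmc = mc, regions = c("lh_CUN", "lh_ENT"))
  rev2 <- fit_all_regions(tab, mcmc = mc, regions = c("lh_ENT", "lh_CUN"))
  expect_identical(two$lh_ENT$draws, rev2$lh_ENT$draws)
  again <- fit_all_regions(tab, mcmc = mc, regions = c("lh_CUN", "lh_ENT"))
  expect_identical(vapply(two, function(p) p$r_median, numeric(1)),
                   vapply(again, function(p) p$r_median, numeric(1)))
  expect_error(fit_all_regions(tab[, -10], mcmc = mc), "missing region")
})

test_that("added measurement noise lowers the variance ratio region-wise", {
  cfg <- cohort_config(group_sizes = c(CN = 70, LMCI = 0, AD = 0),
                       n_sites = 3, pipeline_b_bias = 0,
                       pipeline_b_noise_sd = 0.08, seed = 77)
  pair <- emulate_pipeline_pair(generate_longitudinal(cfg)$table, cfg)
  mc <- fast_mcmc(seed = 8, n_iterations = 800, n_warmup = 300)
  regions <- dkt_region_codes()[seq(1, 62, by = 6)]  # 11 regions
  fa <- fit_all_regions(pair$A, mcmc = mc, regions = regions)
  fb <- fit_all_regions(pair$B, mcmc = mc, regions = regions)
  ra <- vapply(fa, function(p) p$r_median, numeric(1))
  rb <- vapply(fb, function(p) p$r_median, numeric(1))
  expect_gte(sum(rb < ra), 9)
})

test_that("pipeline summaries are exact recomputations of the raw draws", {
  set.seed(5)
  ps <- lapply(c("lh_cACC", "lh_cMFG"), function(rg)
    fake_posterior(rlnorm(200, -1, 0.2), rlnorm(200, -2, 0.2), rg))
  names(ps) <- c("lh_cACC", "lh_cMFG")
  class(ps) <- "region_posterior_list"
  s <- summarize_pipelines(list(A = ps, B = ps))
  expect_equal(nrow(s$per_region), 2 * 2)
  # independent recomputation from the raw draws
  stats_map <- c(sigma_median = "sigma", tau_median = "tau", r_median = "r")
  for (i in seq_len(nrow(s$per_region))) {
    p <- ps[[s$per_region$region[i]]]
    for (col in names(stats_map)) {
      x <- sort(p$draws[, stats_map[[col]]])
      expect_identical(s$per_region[[col]][i], x[ceiling(length(x) * 0.5)])
    }
  }
  # identical posteriors across regions give zero across-region IQR
  same <- list(A = structure(list(lh_cACC = ps[[1]], lh_cMFG = ps[[1]]),
                             class = "region_posterior_list"))
  same$A$lh_cMFG$region <- "lh_cMFG"
  s2 <- summarize_pipelines(same)
  expect_true(all(s2$across_regions$q75 - s2$across_regions$q25 == 0))
  bad <- list(A = ps, B = ps[1])
  expect_error(summarize_pipelines(bad), "mismatched region sets")
})
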