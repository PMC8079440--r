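test_that("noiseless cross-sectional generation reproduces the region means", {
  cfg <- silent_config()
  g <- generate_cross_sectional(cfg, 5)
  for (code in c("lh_cACC", "rh_ENT", "lh_periCAL"))
    expect_equal(g$table[[code]], rep(unname(cfg$alpha0[code]), 5))
})

test_that("generated ages respect the configured lifespan range", {
  g <- generate_cross_sectional(cohort_config(seed = 3), 300)
  expect_true(all(g$table$age_baseline >= 4 & g$table$age_baseline <= 94))
  g2 <- generate_cross_sectional(cohort_config(age_range = c(55, 90),
                                               seed = 3), 100)
  expect_true(all(g2$table$age_baseline >= 55 & g2$table$age_baseline <= 90))
})

test_that("cross-sectional dispersion matches the generative moments", {
  # with one visit per subject the per-region sd about the fixed effects
  # is sqrt(tau^2 + sigma^2); moment-matching at n = 2000
  cfg <- cohort_config(tau = 0.2, sigma = 0.1, gender_effect = 0,
                       age_slope = 0, seed = 21)
  g <- generate_cross_sectional(cfg, 2000)
  target <- sqrt(0.2^2 + 0.1^2)
  for (code in c("lh_cACC", "rh_SFG")) {
    s <- sd(g$table[[code]])
    expect_lt(abs(s - target) / target, 0.05)
  }
})

test_that("longitudinal defaults give the reference cohort shape", {
  g <- generate_longitudinal(cohort_config(seed = 5))
  counts <- table(g$subjects$diagnosis)
  expect_equal(as.vector(counts[c("CN", "LMCI", "AD")]),
               c(197L, 324L, 142L))
  expect_equal(max(g$table$visit_time_months), 36)
  expect_equal(nrow(g$table), (197 + 324 + 142) * 7)
})

test_that("zero-noise longitudinal trajectories are exactly linear", {
  cfg <- silent_config(group_sizes = c(CN = 3, LMCI = 2, AD = 2),
                       diagnosis_slope_offsets = c(CN = 0, LMCI = -0.002,
                                                   AD = -0.004),
                       beta0 = -0.001)
  g <- generate_longitudinal(cfg)
  for (code in c("lh_ENT", "rh_INS")) {
    slope_true <- cfg$beta0[code] +
      cfg$diagnosis_slope_offsets[g$table$diagnosis]
    expect_equal(g$table[[code]],
                 unname(cfg$alpha0[code] +
                        slope_true * g$table$visit_time_months))
  }
})

test_that("per-subject OLS intercept spread matches the variance formula", {
  cfg <- cohort_config(group_sizes = c(CN = 500), tau = 0.25, sigma = 0.10,
                       rho = 0, site_sd = 0,
                       diagnosis_slope_offsets = c(CN = 0), seed = 31)
  g <- generate_longitudinal(cfg)
  tt <- cfg$visit_schedule
  # OLS sampling variance of the intercept for the common schedule
  stt <- sum((tt - mean(tt))^2)
  v_int <- 0.10^2 * (1 / length(tt) + mean(tt)^2 / stt)
  target <- sqrt(0.25^2 + v_int)
  code <- "lh_FUS"
  ints <- vapply(split(seq_len(nrow(g$table)), g$table$subject_id),
                 function(ix) unname(coef(lm(g$table[[code]][ix] ~
                                               g$table$visit_time_months[ix]))[1]),
                 numeric(1))
  expect_lt(abs(sd(ints) - target) / target, 0.10)
})

test_that("dropout truncates schedules and never removes the baseline", {
  cfg <- cohort_config(group_sizes = c(CN = 150, LMCI = 0, AD = 0),
                       retention_prob = 0.7, seed = 13)
  g <- generate_longitudinal(cfg)
  per_sub <- split(g$table$visit_time_months, g$table$subject_id)
  expect_true(all(vapply(per_sub, function(v) v[1] == 0, logical(1))))
  # truncation: visit times are always a prefix of the schedule
  expect_true(all(vapply(per_sub, function(v)
    identical(v, cfg$visit_schedule[seq_along(v)]), logical(1))))
  expect_lt(mean(lengths(per_sub)), 7)
})

test_that("scan-rescan acquisitions share the truth and differ by residuals", {
  cfg0 <- cohort_config(sigma = 0, seed = 17)
  tab0 <- generate_scan_rescan(cfg0, 10)
  expect_equal(nrow(tab0), 20L)
  a1 <- tab0[tab0$acquisition == 1, dkt_region_codes()]
  a2 <- tab0[tab0$acquisition == 2, dkt_region_codes()]
  expect_equal(unname(as.matrix(a1)), unname(as.matrix(a2)))
  expect_error(generate_scan_rescan(cfg0, 1), "ICC undefined")
})

test_that("the emulated pipeline pair has the configured bias and noise", {
  cfg <- small_config()
  g <- generate_cross_sectional(cfg, 200)
  # trivial: zero perturbation leaves the table unchanged
  p0 <- emulate_pipeline_pair(g$table, silent_config())
  expect_equal(p0$B, p0$A, ignore_attr = TRUE)
  # deterministic shift
  ps <- emulate_pipeline_pair(
    g$table, cohort_config(pipeline_b_bias = 0.1, pipeline_b_noise_sd = 0))
  d <- as.matrix(ps$B[, dkt_region_codes()]) -
    as.matrix(ps$A[, dkt_region_codes()])
  expect_equal(unname(d), matrix(0.1, nrow(d), ncol(d)))
  # Monte-Carlo moment check on > 10^4 cells
  pn <- emulate_pipeline_pair(
    g$table, cohort_config(pipeline_b_bias = 0, pipeline_b_noise_sd = 0.2,
                           seed = 41))
  d <- as.matrix(pn$B[, dkt_region_codes()]) -
    as.matrix(pn$A[, dkt_region_codes()])
  expect_gt(length(d), 1e4)
  expect_lt(abs(sd(d) - 0.2) / 0.2, 0.05)
})

test_that("a fixed seed reproduces every generator bit-identically", {
  cfg <- small_config()
  expect_identical(generate_cross_sectional(cfg, 50),
                   generate_cross_sectional(cfg, 50))
  expect_identical(generate_longitudinal(cfg), generate_longitudinal(cfg))
  expect_identical(generate_scan_rescan(cfg, 20),
                   generate_scan_rescan(cfg, 20))
})

test_that("generated thickness is strictly positive and clipping is counted", {
  g <- generate_cross_sectional(cohort_config(seed = 2), 500)
  vals <- as.matrix(g$table[, dkt_region_codes()])
  expect_true(all(vals > 0))
  expect_true(is.numeric(attr(g$table, "n_clipped")))
})
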