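test_that("change-from-baseline rows are exact differences", {
  vals <- matrix(2.5, 3, 62)
  tab <- rbind(toy_table(matrix(3.0, 1, 62), visit = 0),
               toy_table(matrix(2.9, 1, 62), visit = 6),
               toy_table(matrix(2.8, 1, 62), visit = 12))
  tab$subject_id <- "s01"
  delta <- prepare_delta(tab, regions = "lh_ENT")
  expect_equal(delta$delta_y[delta$visit == 6], -0.1)
  expect_equal(delta$delta_y[delta$visit == 12], -0.2)
  expect_equal(delta$y_bl, rep(3.0, 2))
})

test_that("subjects without a baseline are excluded with a logged count", {
  cfg <- small_config()
  g <- generate_longitudinal(cfg)
  tab <- g$table
  drop_subj <- unique(tab$subject_id)[1]
  tab <- tab[!(tab$subject_id == drop_subj & tab$visit_time_months == 0), ]
  expect_message(delta <- prepare_delta(tab, regions = "lh_ENT"),
                 "excluding 1 subject")
  expect_false(drop_subj %in% delta$subject_id)
  expect_equal(attr(delta, "n_excluded"), 1L)
  # baseline-only table is an error
  bl_only <- g$table[g$table$visit_time_months == 0, ]
  expect_error(prepare_delta(bl_only, regions = "lh_ENT"), "no follow-up")
})

test_that("delta row count is (visits - 1) per subject per region", {
  cfg <- small_config(retention_prob = 0.8)
  g <- generate_longitudinal(cfg)
  regions <- dkt_region_codes()[1:5]
  delta <- prepare_delta(g$table, regions = regions)
  per_sub <- table(g$table$subject_id)
  expect_equal(nrow(delta), sum(per_sub - 1L) * length(regions))
})

test_that("the contrast model recovers a generated AD slope deficit", {
  cfg <- cohort_config(group_sizes = c(CN = 100, LMCI = 100, AD = 100),
                       n_sites = 5, age_range = c(55, 90), seed = 71)
  g <- generate_longitudinal(cfg)
  delta <- prepare_delta(g$table, regions = "lh_MTG")
  cm <- fit_contrast_model(delta)
  ct <- tukey_diagnostic_contrasts(cm)
  # generated offsets: CN 0, LMCI -0.002, AD -0.004 mm/month
  ad_cn <- ct$estimate[ct$contrast == "AD-CN"]
  expect_lt(ad_cn, 0)
  expect_lt(abs(ad_cn - (-0.004)) / 0.004, 0.5)
  # exact linear identity of the contrast estimates
  expect_equal(ct$estimate[ct$contrast == "AD-CN"],
               ct$estimate[ct$contrast == "AD-LMCI"] +
                 ct$estimate[ct$contrast == "LMCI-CN"])
})

test_that("Tukey p-values match an independent studentized-range
           computation", {
  cfg <- small_config()
  g <- generate_longitudinal(cfg)
  delta <- prepare_delta(g$table, regions = "lh_SFG")
  cm <- fit_contrast_model(delta)
  ct <- tukey_diagnostic_contrasts(cm)
  # recompute from the fitted fixed effects and their covariance
  fe <- lme4::fixef(cm$model)
  vc <- as.matrix(vcov(cm$model))
  nm <- paste0("diagnosis_bl", c("CN", "LMCI", "AD"), ":visit")
  est <- fe[nm[3]] - fe[nm[1]]  # AD minus CN trajectory term
  se <- sqrt(vc[nm[3], nm[3]] + vc[nm[1], nm[1]] - 2 * vc[nm[3], nm[1]])
  df <- nobs(cm$model) - length(fe) -
    lme4::ngrps(cm$model)[["subject_id"]]
  p_ref <- ptukey(sqrt(2) * abs(est / se), 3, df, lower.tail = FALSE)
  row <- ct[ct$contrast == "AD-CN", ]
  expect_equal(row$estimate, unname(est))
  expect_equal(row$p_raw, unname(p_ref))
})

test_that("model preconditions are enforced with named levels", {
  cfg <- small_config()
  g <- generate_longitudinal(cfg)
  delta <- prepare_delta(g$table, regions = "lh_ENT")
  no_ad <- delta[delta$diagnosis_bl != "AD", ]
  expect_error(fit_contrast_model(no_ad), "AD")
  one_site <- delta[delta$site == delta$site[1], ]
  expect_error(fit_contrast_model(one_site), "sites")
})

test_that("Benjamini-Hochberg adjustment matches the step-up definition", {
  out <- fdr_adjust(matrix(c(0.01, 0.02, 0.03), 3, 1))
  expect_equal(as.vector(out$adjusted), c(0.03, 0.03, 0.03))
  expect_equal(as.vector(out$log10), rep(log10(0.03), 3))
  ones <- fdr_adjust(matrix(1, 5, 3))
  expect_true(all(ones$adjusted == 1))
  # brute-force step-up oracle on random vectors
  bh_bruteforce <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- numeric(m)
    prev <- 1
    for (i in m:1) {
      prev <- min(prev, m / i * p[o[i]])
      adj[o[i]] <- prev
    }
    adj
  }
  set.seed(91)
  for (rep in 1:5) {
    p <- runif(62)
    out <- fdr_adjust(matrix(p, 62, 1))
    expect_equal(as.vector(out$adjusted), bh_bruteforce(p))
    expect_true(all(out$adjusted >= p))
    # monotone in the raw ordering
    o <- order(p)
    expect_true(all(diff(out$adjusted[o]) >= -1e-15))
  }
  expect_error(fdr_adjust(matrix(c(0.5, 1.2), 2, 1)), "\\[0, 1\\]")
})

test_that("the full longitudinal evaluation has the expected shape and
           determinism", {
  cfg <- small_config()
  g <- generate_longitudinal(cfg)
  regions <- dkt_region_codes()[c(1, 2, 33)]
  res <- run_longitudinal_evaluation(g$table, regions = regions)
  expect_equal(nrow(res), length(regions) * 3L)
  expect_true(all(res$contrast %in% c("LMCI-CN", "AD-LMCI", "AD-CN")))
  expect_true(all(res$p_fdr >= res$p_raw))
  expect_equal(res$log10_p_fdr, log10(res$p_fdr))
  res2 <- run_longitudinal_evaluation(g$table, regions = regions)
  expect_identical(res, res2)
})
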