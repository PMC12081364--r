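test_that("time after dose resets at each dosing occasion", {
  sim <- simulate_cohort(n = 8, seed = 701)   # two courses, 504 h apart
  gt <- gof_table(final_model_spec(), data = sim,
                  estimates = final_truth())
  expect_true(all(gt$TAD >= 0))
  # split 1 h + 11 h infusions form one occasion: a 36 h sample is TAD 36
  expect_true(all(gt$TAD[gt$TIME < 500] == gt$TIME[gt$TIME < 500]))
  # second-course samples reset against the 504 h course start
  late <- gt$TIME >= 500
  expect_equal(gt$TAD[late], gt$TIME[late] - 504)
  expect_true(all(gt$TAD %in% c(36, 48, 60, 72)))
})

test_that("noise-free goodness-of-fit reproduces the data", {
  sim <- simulate_cohort(n = 8, design = quick_design(), seed = 702,
                         omega = c(cl = 0, vc = 0),
                         error = error_model("proportional",
                                             sigma_prop = 0))
  est <- final_truth()
  est[c("omega_cl", "omega_vc")] <- 1e-6
  gt <- gof_table(final_model_spec(), data = sim, estimates = est)
  expect_equal(gt$IPRED, gt$DV, tolerance = 1e-6)
  expect_equal(gt$PRED, gt$DV, tolerance = 1e-8)
  expect_equal(nrow(gt), sum(sim$events$EVID == 0))
})

test_that("bootstrap resampling is reproducible and degenerate on one subject", {
  rich <- study_design(n_courses = 2, retention = rep(1, 7))
  sim <- simulate_cohort(n = 1, design = rich, seed = 703)
  spec <- model_spec(covariates = NULL, iiv = c(),
                     estimate = c(cl = TRUE, vc = FALSE, q = FALSE,
                                  vp = FALSE),
                     init = c(cl = 10, vc = 72.04, q = 1.08, vp = 94.94))
  ctrl <- fit_control(compute_se = FALSE)
  b1 <- bootstrap_fit(spec, sim, n_runs = 6, seed = 1, control = ctrl)
  b2 <- bootstrap_fit(spec, sim, n_runs = 6, seed = 1, control = ctrl)
  expect_equal(b1$summary, b2$summary, tolerance = 1e-12)
  # every resample of a single subject is the same dataset
  width <- b1$summary$ci_hi - b1$summary$ci_lo
  expect_lt(max(width[b1$summary$parameter == "theta_cl"]), 1e-6)
  expect_lte(b1$n_success, b1$n_runs)
})

test_that("bootstrap medians agree with the maximum-likelihood fit", {
  fe0 <- fixed_effects(beta_egfr_cl = 0, beta_bw_cl = 0, beta_tbil_cl = 0,
                       beta_alb_cl = 0, beta_blm_cl = 0, beta_bw_vc = 0)
  sim <- simulate_cohort(n = 30, design = quick_design(), fe = fe0,
                         seed = 704)
  spec <- base_model_spec()
  fit <- nlme_fit(spec, sim, control = fit_control(compute_se = TRUE))
  bs <- bootstrap_fit(spec, sim, n_runs = 30, seed = 2,
                      control = fit_control(compute_se = FALSE,
                                            rel_tol = 1e-7),
                      fit = fit)
  med <- bs$summary$median[bs$summary$parameter == "theta_cl"]
  ci <- fit$table[fit$table$parameter == "theta_cl",
                  c("ci_lo", "ci_hi")]
  expect_gte(med, ci$ci_lo)
  expect_lte(med, ci$ci_hi)
})

test_that("VPC bands collapse to the deterministic profile without noise", {
  sim <- simulate_cohort(n = 20, design = quick_design(), seed = 705,
                         omega = c(cl = 0, vc = 0),
                         error = error_model("proportional",
                                             sigma_prop = 0))
  est <- final_truth()
  est[c("omega_cl", "omega_vc")] <- 1e-8
  est["sigma_prop"] <- 1e-8
  v <- vpc(final_model_spec(), est, sim, n_sim = 100, seed = 3)
  expect_lt(max(v$table$sim_hi - v$table$sim_lo), 1e-6)
  expect_equal(v$table$observed, v$table$sim_med, tolerance = 1e-5)
})

test_that("VPC is seed-reproducible and internally consistent", {
  sim <- simulate_cohort(n = 100, design = quick_design(), seed = 706)
  est <- final_truth()
  v1 <- vpc(final_model_spec(), est, sim, n_sim = 120, seed = 4)
  v2 <- vpc(final_model_spec(), est, sim, n_sim = 120, seed = 4)
  expect_identical(v1$table, v2$table)
  # observed percentiles are the plain empirical percentiles per bin
  obs <- sim$events[sim$events$EVID == 0, ]
  for (b in unique(v1$table$tad)) {
    sel <- abs(obs$TIME - b) < 1e-9
    expect_equal(v1$table$observed[v1$table$tad == b],
                 unname(quantile(obs$DV[sel], c(0.05, 0.5, 0.95))))
  }
  # percentile ordering within every bin
  w <- reshape(v1$table[, c("bin", "percentile", "observed")],
               idvar = "bin", timevar = "percentile", direction = "wide")
  expect_true(all(w$observed.5 <= w$observed.50 &
                    w$observed.50 <= w$observed.95))
})

test_that("VPC covers the observed median when the model is true", {
  sim <- simulate_cohort(n = 200, seed = 707)
  v <- vpc(final_model_spec(), final_truth(), sim, n_sim = 300, seed = 5)
  med <- v$table[v$table$percentile == 50, ]
  covered <- mean(med.ok <- med$observed >= med$sim_lo &
                    med$observed <= med$sim_hi)
  expect_gte(covered, 0.8)
})

test_that("NPDE is reproducible and invariant to subject relabeling", {
  sim <- simulate_cohort(n = 60, seed = 708)
  est <- final_truth()
  n1 <- npde(final_model_spec(), est, sim, n_sim = 300, seed = 6)
  n2 <- npde(final_model_spec(), est, sim, n_sim = 300, seed = 6)
  expect_identical(n1$npde, n2$npde)
  expect_true(all(is.finite(n1$npde)))
  expect_true(all(c(n1$p_wilcoxon, n1$p_variance, n1$p_shapiro) >= 0 &
                    c(n1$p_wilcoxon, n1$p_variance, n1$p_shapiro) <= 1))
  # permuting the subject blocks leaves the pooled NPDE unchanged (each
  # subject's simulation stream is keyed to its id, not its position)
  ids <- unique(sim$events$ID)
  ev2 <- do.call(rbind, lapply(rev(ids), function(i)
    sim$events[sim$events$ID == i, ]))
  n3 <- npde(final_model_spec(), est, ev2, n_sim = 300, seed = 6)
  expect_equal(sort(n3$npde), sort(n1$npde), tolerance = 1e-10)
})

test_that("NPDE is null-calibrated and flags a misspecified clearance", {
  sim <- simulate_cohort(n = 200, seed = 709)
  est <- final_truth()
  nd <- npde(final_model_spec(), est, sim, n_sim = 600, seed = 7)
  expect_lt(abs(nd$mean), 0.1)
  expect_gt(nd$variance, 0.85)
  expect_lt(nd$variance, 1.15)
  bad <- est
  bad["theta_cl"] <- est["theta_cl"] * 2
  nd_bad <- npde(final_model_spec(), bad, sim, n_sim = 600, seed = 7)
  expect_lt(nd_bad$p_wilcoxon, 0.05)
})

test_that("diagnostic plots build without error", {
  sim <- simulate_cohort(n = 20, design = quick_design(), seed = 710)
  est <- final_truth()
  gt <- gof_table(final_model_spec(), data = sim, estimates = est)
  expect_s3_class(plot_gof(gt), "ggplot")
  v <- vpc(final_model_spec(), est, sim, n_sim = 100, seed = 8)
  expect_s3_class(plot_vpc(v), "ggplot")
  nd <- npde(final_model_spec(), est, sim, n_sim = 120, seed = 8)
  expect_s3_class(plot_npde(nd), "ggplot")
})
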