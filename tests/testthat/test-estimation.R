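# a small two-course cohort reused by several fits below
small_sim <- local({
  simulate_cohort(n = 60, seed = 301)
})

test_that("information criteria reproduce the printed model comparison", {
  ic <- information_criteria(10421.315, 11, 5470)
  expect_equal(ic$aic, 10443.315)
  expect_equal(ic$bic, 10515.99, tolerance = 0.01 / 10515.99)
  expect_equal(information_criteria(0, 1, 1), list(aic = 2, bic = 0))
  expect_error(information_criteria(10, 0, 5), ">= 1")
})

test_that("event CSV round-trips through the dialect contract", {
  sim <- simulate_cohort(n = 6, design = quick_design(), seed = 55)
  path <- tempfile(fileext = ".csv")
  write_event_csv(sim$events, path)
  header <- readLines(path, n = 1)
  expect_identical(header, "ID,TIME,EVID,AMT,DUR,DV,BQL,EGFR,BW,TBIL,ALB,BLM")
  back <- read_event_csv(path)
  expect_equal(back, sim$events, tolerance = 1e-12)
  # a second write of the same object is byte-identical
  path2 <- tempfile(fileext = ".csv")
  write_event_csv(sim$events, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("the event validator reports offending rows", {
  sim <- simulate_cohort(n = 3, design = quick_design(), seed = 56)
  ev <- sim$events
  bad <- ev
  bad$DV[bad$EVID == 1][1] <- 5
  expect_error(validate_events(bad), "dose rows must not.*rows [0-9]+")
  bad <- ev
  bad$DV[bad$EVID == 0][2] <- NA
  expect_error(validate_events(bad), "observation rows need a DV")
  bad <- ev
  bad$EVID[1] <- 2L
  expect_error(validate_events(bad), "EVID")
  bad <- ev
  bad$TIME[nrow(bad)] <- 0  # breaks within-subject ordering
  expect_error(validate_events(bad), "sorted within subject")
  bad <- ev[, -3]
  expect_error(validate_events(bad), "lacks columns")
})

test_that("without random effects the objective is the exact Gaussian -2LL", {
  sim <- simulate_cohort(n = 1, design = quick_design(), seed = 77,
                         omega = c(cl = 0, vc = 0),
                         error = error_model("additive", sigma_add = 0.05))
  spec <- model_spec(covariates = NULL, iiv = c(), error = "additive")
  tr <- sim$truth
  est <- c(theta_cl = tr$tcl, theta_vc = tr$tvc, theta_q = 1.08,
           theta_vp = 94.94, sigma_add = 0.05)
  obs <- sim$events[sim$events$EVID == 0, ]
  segs <- build_regimen(tr$bsa, sim$design, 0)
  pred <- conc_profile(pk_params(tr$tcl, tr$tvc, 1.08, 94.94), segs,
                       obs$TIME)$conc
  manual <- sum(log(2 * pi * 0.05^2) + (obs$DV - pred)^2 / 0.05^2)
  expect_equal(nlme_ofv(spec, est, sim), manual, tolerance = 1e-8)
})

test_that("the approximate marginal likelihood tracks a quadrature oracle", {
  sim <- simulate_cohort(n = 25, design = quick_design(), seed = 88)
  spec <- final_model_spec()
  truth <- final_truth()
  pert <- truth
  pert["theta_cl"] <- truth["theta_cl"] * 1.5
  d_foce <- nlme_ofv(spec, pert, sim) - nlme_ofv(spec, truth, sim)
  d_exact <- gh_quad_ofv(spec, pert, sim) - gh_quad_ofv(spec, truth, sim)
  expect_gt(d_exact, 10)  # a 25% clearance shift is strongly resolved
  expect_lt(abs(d_foce - d_exact) / abs(d_exact), 0.15)
})

test_that("objective is invariant to subject ordering", {
  sim <- simulate_cohort(n = 15, design = quick_design(), seed = 91)
  spec <- final_model_spec()
  est <- final_truth()
  o1 <- nlme_ofv(spec, est, sim)
  ids <- unique(sim$events$ID)
  perm <- rev(ids)
  ev2 <- do.call(rbind, lapply(perm, function(i)
    sim$events[sim$events$ID == i, ]))
  o2 <- nlme_ofv(spec, est, ev2)
  expect_equal(o1, o2, tolerance = 1e-8)
})

test_that("noise-free predictions reproduce the data and zero the modes", {
  sim <- simulate_cohort(n = 10, design = quick_design(), seed = 92,
                         omega = c(cl = 0, vc = 0),
                         error = error_model("proportional",
                                             sigma_prop = 0))
  spec <- final_model_spec()
  est <- final_truth()
  est[c("omega_cl", "omega_vc")] <- 1e-6
  pr <- nlme_predict(spec, est, sim)
  expect_equal(pr$PRED, pr$DV, tolerance = 1e-8)
  expect_equal(pr$IPRED, pr$DV, tolerance = 1e-6)
})

test_that("predictions on a frozen fixture are stable", {
  p <- final_truth()
  segs <- build_regimen(1.42, study_design(), 0:1)
  cc <- conc_profile(pk_params(12.88, 72.04, 1.08, 94.94), segs,
                     c(36, 48, 60, 72, 540, 552))$conc
  expect_equal(cc,
               c(0.367653139535239, 0.196577357585535, 0.161069245939620,
                 0.140900343308891, 0.368713449008706, 0.197512754789284),
               tolerance = 1e-8)
})

test_that("CWRES reduces to the scaled residual without random effects", {
  sim <- simulate_cohort(n = 4, design = quick_design(), seed = 95,
                         omega = c(cl = 0, vc = 0),
                         error = error_model("additive", sigma_add = 0.1))
  spec <- model_spec(covariates = NULL, iiv = c(), error = "additive")
  tr <- sim$truth
  est <- c(theta_cl = 12.88, theta_vc = 72.04, theta_q = 1.08,
           theta_vp = 94.94, sigma_add = 0.1)
  # typical parameters here are subject-independent (no covariates)
  pr <- nlme_predict(spec, est, sim)
  expect_equal(pr$CWRES, (pr$DV - pr$PRED) / 0.1, tolerance = 1e-10)
  # deterministic
  expect_identical(pr$CWRES, nlme_predict(spec, est, sim)$CWRES)
})

test_that("CWRES is calibrated on data simulated from the model", {
  # the dataset-level CWRES mean is dominated by the cohort-mean random
  # effect (standard error ~ 1/sqrt(n_subjects)), so the calibration is
  # checked on a large cohort
  sim <- simulate_cohort(n = 2000, design = quick_design(), seed = 96)
  cw <- cwres(final_model_spec(), final_truth(), sim)
  expect_gte(length(cw), 2000)
  expect_true(all(is.finite(cw)))
  expect_lt(abs(mean(cw)), 0.05)
  expect_lt(abs(sd(cw) - 1), 0.1)
})

test_that("zero-noise data started at truth is recovered almost exactly", {
  fe0 <- fixed_effects(beta_egfr_cl = 0, beta_bw_cl = 0, beta_tbil_cl = 0,
                       beta_alb_cl = 0, beta_blm_cl = 0, beta_bw_vc = 0)
  sim <- simulate_cohort(n = 25, design = quick_design(), seed = 97,
                         fe = fe0, omega = c(cl = 0, vc = 0),
                         error = error_model("proportional",
                                             sigma_prop = 1e-6))
  spec <- model_spec(covariates = NULL, iiv = c(), error = "proportional",
                     init = c(cl = 12.88, vc = 72.04, q = 1.08,
                              vp = 94.94),
                     sigma_init = c(prop = 1e-4, add = 1))
  fit <- nlme_fit(spec, sim, control = fit_control(compute_se = FALSE))
  expect_equal(unname(fit$estimates["theta_cl"]), 12.88,
               tolerance = 1e-4)
  expect_equal(unname(fit$estimates["theta_vc"]), 72.04,
               tolerance = 1e-4)
})

test_that("fits expose the information-criteria identities and modes", {
  spec <- base_model_spec()
  fit <- nlme_fit(spec, small_sim,
                  control = fit_control(compute_se = TRUE))
  expect_true(fit$converged)
  expect_identical(fit$aic, fit$ofv + 2 * fit$p)
  expect_identical(fit$bic, fit$ofv + fit$p * log(fit$n_obs))
  expect_equal(fit$p, 5L)  # theta_cl, theta_vc, omega x2, sigma
  # confidence intervals contain their point estimates
  tab <- fit$table[!fit$table$fixed & !fit$table$boundary, ]
  expect_true(all(tab$ci_lo <= tab$estimate & tab$estimate <= tab$ci_hi))
  expect_true(all(is.finite(tab$se)))
  expect_equal(dim(fit$eta), c(60L, 2L))
  expect_true(all(abs(fit$shrinkage) < 1))
  expect_output(print(fit), "OFV")
})

test_that("the optimum survives a profile perturbation check", {
  spec <- base_model_spec()
  fit <- nlme_fit(spec, small_sim,
                  control = fit_control(compute_se = FALSE))
  pd <- mtxppk:::prepare_data(small_sim, spec)
  xd <- mtxppk:::covariate_design(spec, pd)
  for (par in c("theta_cl", "theta_vc", "omega_cl", "sigma_prop")) {
    for (fct in c(0.8, 1.2)) {
      est <- fit$estimates
      est[par] <- est[par] * fct
      o <- mtxppk:::foce_call(spec, est, pd, xd)$ofv
      expect_gte(o, fit$ofv - 1e-3)
    }
  }
})

test_that("a one-compartment spec fits two-compartment data worse", {
  spec2 <- base_model_spec()
  fit2 <- nlme_fit(spec2, small_sim,
                   control = fit_control(compute_se = FALSE))
  spec1 <- model_spec(structural = "one_cmt", covariates = NULL)
  fit1 <- nlme_fit(spec1, small_sim,
                   control = fit_control(compute_se = FALSE))
  expect_gt(fit1$ofv, fit2$ofv)
})

test_that("refitting self-simulated data scatters around the estimates", {
  spec <- base_model_spec()
  fit <- nlme_fit(spec, small_sim,
                  control = fit_control(compute_se = FALSE))
  fe_hat <- fixed_effects(theta_cl = fit$estimates[["theta_cl"]],
                          theta_vc = fit$estimates[["theta_vc"]],
                          beta_egfr_cl = 0, beta_bw_cl = 0,
                          beta_tbil_cl = 0, beta_alb_cl = 0,
                          beta_blm_cl = 0, beta_bw_vc = 0)
  omg <- c(cl = fit$estimates[["omega_cl"]],
           vc = fit$estimates[["omega_vc"]])
  err <- error_model("proportional",
                     sigma_prop = fit$estimates[["sigma_prop"]])
  re <- vapply(1:10, function(s) {
    sim2 <- simulate_cohort(n = 60, design = quick_design(), fe = fe_hat,
                            omega = omg, error = err, seed = 500 + s)
    f2 <- nlme_fit(spec, sim2, init = fit$estimates,
                   control = fit_control(compute_se = FALSE))
    f2$estimates[["theta_cl"]]
  }, numeric(1))
  expect_lt(abs(mean(re) / fit$estimates[["theta_cl"]] - 1), 0.05)
})
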