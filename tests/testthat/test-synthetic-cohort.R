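test_that("Mosteller BSA matches the study medians and extremes", {
  expect_equal(bsa_mosteller(155, 47), 1.42, tolerance = 0.005 / 1.42)
  expect_equal(bsa_mosteller(3600, 1), 1.0)
  expect_equal(bsa_mosteller(103, 14), 0.633, tolerance = 0.002 / 0.633)
  expect_error(bsa_mosteller(-1, 50), "positive")
})

test_that("bedside Schwartz eGFR follows the conversion arithmetic", {
  expect_equal(egfr_schwartz_bedside(155, 62), 91.3,
               tolerance = 0.2 / 91.3)
  expect_equal(egfr_schwartz_bedside(103, 62), 60.7,
               tolerance = 0.2 / 60.7)
  # halving creatinine exactly doubles the estimate
  expect_equal(egfr_schwartz_bedside(140, 31),
               2 * egfr_schwartz_bedside(140, 62))
  expect_error(egfr_schwartz_bedside(155, 0), "positive")
})

test_that("2021 CKD-EPI eGFR follows the race-free refit", {
  expect_equal(egfr_ckdepi_2021(62, 30, "female"), 119.0,
               tolerance = 0.5 / 119)
  # at the kappa knot both piecewise terms equal one
  scr_knot <- 0.9 * 88.4
  expect_equal(egfr_ckdepi_2021(scr_knot, 40, "male"),
               142 * 0.9938^40)
  # recomputed directly from the formula (142 * (scr/kappa)^-1.2 *
  # 0.9938^age * 1.012 at scr above the knot)
  expect_equal(egfr_ckdepi_2021(100, 48, "female"),
               142 * (100 / 88.4 / 0.7)^(-1.2) * 0.9938^48 * 1.012,
               tolerance = 1e-12)
  expect_error(egfr_ckdepi_2021(62, 10, "female"), "adult")
})

test_that("sampled cohorts hit the study medians, ranges and mix", {
  cov <- sample_covariates(505, seed = 20)
  expect_true(all(cov$age >= 3 & cov$age <= 48))
  expect_true(all(cov$bw >= 14 & cov$bw <= 121))
  expect_true(all(cov$height >= 103 & cov$height <= 194))
  expect_true(all(cov$egfr >= 41.57 & cov$egfr <= 446.22))
  expect_true(all(cov$tbil >= 3.40 & cov$tbil <= 78.50))
  expect_true(all(cov$alb >= 30.60 & cov$alb <= 52.30))
  expect_true(all(cov$blm %in% c(0, 1)))
  expect_equal(cov$bsa, bsa_mosteller(cov$height, cov$bw))
  expect_gt(median(cov$bw), 47 * 0.95)
  expect_lt(median(cov$bw), 47 * 1.05)
  big <- sample_covariates(2000, seed = 21)
  for (v in c(age = 14, height = 155, bw = 47, scr = 62, egfr = 102.2,
              tbil = 15.3, alb = 40.9)) {
    nm <- names(which(c(age = 14, height = 155, bw = 47, scr = 62,
                        egfr = 102.2, tbil = 15.3, alb = 40.9) == v))[1]
    expect_lt(abs(median(big[[nm]]) / v - 1), 0.05, label = nm)
  }
  expect_equal(mean(big$blm), 0.5867, tolerance = 0.03 / 0.5867)
  expect_equal(mean(big$age < 18), 0.733, tolerance = 0.05)
  one <- sample_covariates(1, seed = 22)
  expect_equal(nrow(one), 1L)
  expect_error(sample_covariates(0), "positive")
  # children use Schwartz, adults CKD-EPI
  kid <- big[big$age < 18, ][1, ]
  expect_equal(kid$egfr, egfr_schwartz_bedside(kid$height, kid$scr))
  ad <- big[big$age >= 18, ][1, ]
  expect_equal(ad$egfr, egfr_ckdepi_2021(ad$scr, ad$age, ad$sex))
})

test_that("the regimen splits 1.3 g/m2 one-third / two-thirds", {
  segs <- build_regimen(1.42, study_design(), course_index = 0)
  total <- dose_grams_to_umol(1.3 * 1.42)
  expect_equal(sum(segs$amount), total)
  expect_equal(segs$amount, c(total / 3, 2 * total / 3))
  expect_equal(segs$start_h, c(0, 1))
  expect_equal(segs$duration_h, c(1, 11))
  # the segment amounts correspond to 0.6153 g and 1.2307 g
  expect_equal(segs$amount * 454.44 / 1e6, c(0.6153, 1.2307),
               tolerance = 1e-3)
  # linearity in BSA
  segs2 <- build_regimen(2 * 1.42, study_design(), course_index = 0)
  expect_equal(segs2$amount, 2 * segs$amount)
  # course shift
  seg_c1 <- build_regimen(1.42, study_design(course_interval_h = 504),
                          course_index = 1)
  expect_equal(seg_c1$start_h, c(504, 505))
})

test_that("simulated cohorts are reproducible and structurally sound", {
  s1 <- simulate_cohort(n = 40, seed = 9)
  s2 <- simulate_cohort(n = 40, seed = 9)
  expect_identical(s1, s2)
  s3 <- simulate_cohort(n = 40, seed = 10)
  expect_false(identical(s1$events, s3$events))
  expect_equal(nrow(s1$truth), 40L)
  obs <- s1$events[s1$events$EVID == 0, ]
  expect_true(all(table(obs$ID) >= 1))
  expect_setequal(unique(s1$events$ID), 1:40)
  validate_events(s1$events)
  expect_true(all(obs$BQL[obs$DV < 0.3] == 1))
  expect_true(all(obs$BQL[obs$DV >= 0.3] == 0))
})

test_that("noise-free simulation equals the typical-value prediction", {
  sim <- simulate_cohort(n = 12, seed = 14, omega = c(cl = 0, vc = 0),
                         error = error_model("proportional",
                                             sigma_prop = 0))
  obs <- sim$events[sim$events$EVID == 0, ]
  for (id in unique(obs$ID)) {
    tr <- sim$truth[sim$truth$id == id, ]
    segs <- build_regimen(tr$bsa, sim$design, course_index = 0:1)
    p <- pk_params(tr$tcl, tr$tvc, 1.08, 94.94)
    pred <- conc_profile(p, segs, obs$TIME[obs$ID == id])$conc
    expect_equal(obs$DV[obs$ID == id], pred)
  }
})

test_that("sample retention matches the design probabilities", {
  sim <- simulate_cohort(n = 505, seed = 33)
  obs <- sim$events[sim$events$EVID == 0, ]
  # fraction of subjects retaining the 60 h sample of the first course
  frac60 <- mean(vapply(split(obs$TIME, obs$ID),
                        function(t) any(abs(t - 60) < 1e-9), logical(1)))
  expect_equal(frac60, 0.2653, tolerance = 0.04 / 0.2653)
  frac36 <- mean(vapply(split(obs$TIME, obs$ID),
                        function(t) any(abs(t - 36) < 1e-9), logical(1)))
  expect_equal(frac36, 1)
  expect_false(any(abs(obs$TIME - 84) < 1e-9))
})

test_that("simulated between-subject variability matches omega", {
  sim <- simulate_cohort(n = 505, seed = 34)
  resid <- log(sim$truth$cl) - log(sim$truth$tcl)
  expect_lt(abs(sd(resid) - 0.30), 0.03)
  expect_lt(abs(mean(resid)), 0.05)
})
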