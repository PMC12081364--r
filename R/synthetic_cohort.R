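#' Mosteller body surface area
#'
#' \code{sqrt(height * weight / 3600)}.
#'
#' @param height_cm Height, cm (positive).
#' @param bw_kg Body weight, kg (positive).
#' @return BSA, m2.
#' @examples
#' bsa_mosteller(155, 47)   # 1.42 m2
#' @export
bsa_mosteller <- function(height_cm, bw_kg) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0) ||
      any(!is.finite(bw_kg)) || any(bw_kg <= 0))
    stop("height and weight must be positive", call. = FALSE)
  sqrt(height_cm * bw_kg / 3600)
}

#' Bedside Schwartz eGFR (children)
#'
#' \code{0.413 * height / Scr[mg/dL]}, with serum creatinine supplied in
#' umol/L and converted by the factor 88.4.
#'
#' @param height_cm Height, cm.
#' @param scr_umol Serum creatinine, umol/L.
#' @return eGFR, mL/min/1.73 m2.
#' @export
egfr_schwartz_bedside <- function(height_cm, scr_umol) {
  if (any(!is.finite(height_cm)) || any(height_cm <= 0) ||
      any(!is.finite(scr_umol)) || any(scr_umol <= 0))
    stop("height and creatinine must be positive", call. = FALSE)
  0.413 * height_cm / (scr_umol / 88.4)
}

#' 2021 race-free CKD-EPI eGFR (adults)
#'
#' \code{142 * min(Scr/k, 1)^a * max(Scr/k, 1)^(-1.200) * 0.9938^age *
#' 1.012[female]}, with k = 0.7 (female) / 0.9 (male) and a = -0.241 /
#' -0.302, creatinine in mg/dL (converted from umol/L by 88.4).
#'
#' @param scr_umol Serum creatinine, umol/L.
#' @param age_y Age in years (>= 18).
#' @param sex "female" or "male" (vectorized).
#' @return eGFR, mL/min/1.73 m2.
#' @export
egfr_ckdepi_2021 <- function(scr_umol, age_y, sex) {
  if (any(!is.finite(scr_umol)) || any(scr_umol <= 0))
    stop("creatinine must be positive", call. = FALSE)
  if (any(age_y < 18))
    stop("the CKD-EPI equation applies to adults (age >= 18); ",
         "use egfr_schwartz_bedside() for children", call. = FALSE)
  sex <- match.arg(as.character(sex), c("female", "male"),
                   several.ok = TRUE)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  scr_mg <- scr_umol / 88.4
  r <- scr_mg / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age_y *
    ifelse(female, 1.012, 1)
}

#' Study design: dosing regimen and sampling schedule
#'
#' The protocol emulated by the cohort generator: 1.3 g/m2 methotrexate per
#' course, one third infused over 1 h and the remainder over the following
#' 11 h; serum samples drawn from 24 h after the end of the infusion
#' (i.e. 36 h after dose start) every 12 h up to 108 h, with per-time
#' retention probabilities reflecting how often late samples were actually
#' available; assay lower limit of quantitation 0.3 umol/L.
#'
#' @param dose_per_bsa Dose, g per m2 of body surface area.
#' @param bolus_fraction Fraction given in the initial short infusion.
#' @param bolus_duration_h,infusion_duration_h Durations of the two
#'   segments, h.
#' @param sample_times_h Nominal sampling times after dose start, h.
#' @param retention Per-time probabilities that the sample exists
#'   (in [0, 1], non-increasing).
#' @param n_courses Courses per subject.
#' @param course_interval_h Spacing between course starts, h.
#' @param lloq Lower limit of quantitation, umol/L.
#' @return A list of class \code{study_design}.
#' @export
study_design <- function(dose_per_bsa = 1.3, bolus_fraction = 1 / 3,
                         bolus_duration_h = 1, infusion_duration_h = 11,
                         sample_times_h = c(36, 48, 60, 72, 84, 96, 108),
                         retention = c(1, 0.5307, 0.2653, 0.0139, 0, 0, 0),
                         n_courses = 2, course_interval_h = 504,
                         lloq = 0.3) {
  if (bolus_fraction <= 0 || bolus_fraction >= 1)
    stop("'bolus_fraction' must lie in (0, 1)", call. = FALSE)
  if (length(retention) != length(sample_times_h))
    stop("'retention' must match 'sample_times_h' in length", call. = FALSE)
  if (any(retention < 0) || any(retention > 1))
    stop("retention probabilities must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(rev(retention)))
    stop("retention probabilities must be non-increasing over time",
         call. = FALSE)
  if (dose_per_bsa <= 0 || n_courses < 1)
    stop("invalid design", call. = FALSE)
  structure(list(dose_per_bsa = dose_per_bsa,
                 bolus_fraction = bolus_fraction,
                 bolus_duration_h = bolus_duration_h,
                 infusion_duration_h = infusion_duration_h,
                 sample_times_h = sample_times_h, retention = retention,
                 n_courses = n_courses,
                 course_interval_h = course_interval_h, lloq = lloq),
            class = "study_design")
}

# truncated normal / lognormal draws via inverse-CDF (exact, vectorized)
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
rtlnorm <- function(n, mlog, slog, lo, hi) {
  plo <- stats::plnorm(lo, mlog, slog)
  phi <- stats::plnorm(hi, mlog, slog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), mlog, slog)
}

# Age-indexed location parameters of the covariate generator.  These are
# the growth-curve anchors tuned so that cohort medians land on the study
# medians (see the methods vignette); the study reported only median
# (range) per covariate, so any marginal hitting those is admissible.
cohort_anchors <- function() {
  list(p_female = 357 / 505, p_child = 0.733, p_blm = 0.5867,
       child_age_mean = 12.9, child_age_sd = 3.6,
       adult_age_rate = 1 / 8,
       height_at3 = 104, height_at15 = 160.5, height_sd = 6,
       bmi_at3 = 15.6, bmi_slope = 0.34, bmi_cap_age = 20, bmi_sdlog = 0.17,
       scr_at3 = 25.5, scr_slope = 3.17, scr_cap_age = 18, scr_sdlog = 0.40,
       tbil_med = 15.3, tbil_sdlog = 0.50,
       alb_mean = 40.9, alb_sd = 3.6)
}

#' Sample a synthetic covariate cohort
#'
#' Draws subject profiles (sex, age, height, weight, creatinine, eGFR,
#' bilirubin, albumin, bleomycin co-medication, BSA) emulating the study
#' population: 73.3 percent children, bleomycin in 58.67 percent, covariate
#' medians at the study medians and all values inside the study ranges.
#' Age drives height, body-mass index and creatinine through simple growth
#' anchors so pediatric profiles are coherent; eGFR is computed from
#' creatinine, height and age by the bedside Schwartz equation for children
#' and the 2021 CKD-EPI equation for adults.
#'
#' @param n Number of subjects (>= 1).
#' @param seed Optional integer seed (uses the current RNG stream when
#'   NULL).
#' @return A data.frame with one row per subject: \code{id}, \code{sex},
#'   \code{age}, \code{height}, \code{bw}, \code{bmi}, \code{bsa},
#'   \code{scr}, \code{egfr}, \code{tbil}, \code{alb}, \code{blm}.
#' @export
sample_covariates <- function(n, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive count", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  a <- cohort_anchors()
  sex <- ifelse(stats::runif(n) < a$p_female, "female", "male")
  child <- stats::runif(n) < a$p_child
  age <- numeric(n)
  nc <- sum(child)
  age[child] <- rtnorm(nc, a$child_age_mean, a$child_age_sd, 3, 17.999)
  lo <- stats::pexp(0, a$adult_age_rate)
  hi <- stats::pexp(30, a$adult_age_rate)
  age[!child] <- 18 + stats::qexp(lo + stats::runif(n - nc) * (hi - lo),
                                  a$adult_age_rate)
  hmean <- a$height_at3 + (a$height_at15 - a$height_at3) *
    (pmin(age, 15) - 3) / 12
  height <- rtnorm(n, hmean, a$height_sd, 103, 194)
  bmi_med <- a$bmi_at3 + a$bmi_slope * (pmin(age, a$bmi_cap_age) - 3)
  bmi <- rtlnorm(n, log(bmi_med), a$bmi_sdlog, 11.14, 36.53)
  bw <- pmin(pmax(bmi * (height / 100)^2, 14), 121)
  scr_med <- a$scr_at3 + a$scr_slope * (pmin(age, a$scr_cap_age) - 3)
  scr <- rtlnorm(n, log(scr_med), a$scr_sdlog, 9, 147)
  egfr <- numeric(n)
  compute_egfr <- function(i, s) {
    if (age[i] < 18) egfr_schwartz_bedside(height[i], s)
    else egfr_ckdepi_2021(s, age[i], sex[i])
  }
  for (i in seq_len(n)) {
    e <- compute_egfr(i, scr[i])
    tries <- 0L
    while ((e < 41.57 || e > 446.22) && tries < 100L) {
      scr[i] <- rtlnorm(1, log(scr_med[i]), a$scr_sdlog, 9, 147)
      e <- compute_egfr(i, scr[i])
      tries <- tries + 1L
    }
    if (e < 41.57 || e > 446.22) {  # pathological draw: move scr to bound
      dir <- if (e < 41.57) -1 else 1
      for (k in 1:60) {
        scr[i] <- scr[i] * (1 - dir * 0.05)
        e <- compute_egfr(i, scr[i])
        if (e >= 41.57 && e <= 446.22) break
      }
    }
    egfr[i] <- e
  }
  tbil <- rtlnorm(n, log(a$tbil_med), a$tbil_sdlog, 3.40, 78.50)
  alb <- rtnorm(n, a$alb_mean, a$alb_sd, 30.60, 52.30)
  blm <- as.integer(stats::runif(n) < a$p_blm)
  data.frame(id = seq_len(n), sex = sex, age = age, height = height,
             bw = bw, bmi = bmi, bsa = bsa_mosteller(height, bw), scr = scr,
             egfr = egfr, tbil = tbil, alb = alb, blm = blm)
}

#' Build the infusion regimen for one or more courses
#'
#' Total amount is \code{dose_per_bsa * bsa} grams converted to micromoles;
#' the bolus fraction runs over the first hour of the course and the
#' remainder over the following 11 h (defaults).  \code{course_index}
#' shifts the segments by whole course intervals.
#'
#' @param bsa Body surface area, m2 (positive).
#' @param design A \code{\link{study_design}}.
#' @param course_index 0-based course index, or a vector of indices to get
#'   the full multi-course history.
#' @return An \code{\link{infusion_segments}} table.
#' @examples
#' build_regimen(1.42, study_design(), course_index = 0)
#' @export
build_regimen <- function(bsa, design = study_design(), course_index = 0) {
  if (!is.finite(bsa) || bsa <= 0) stop("'bsa' must be positive",
                                        call. = FALSE)
  total <- dose_grams_to_umol(design$dose_per_bsa * bsa)
  starts <- durs <- amts <- numeric(0)
  for (ci in course_index) {
    off <- ci * design$course_interval_h
    starts <- c(starts, off, off + design$bolus_duration_h)
    durs <- c(durs, design$bolus_duration_h, design$infusion_duration_h)
    amts <- c(amts, total * design$bolus_fraction,
              total * (1 - design$bolus_fraction))
  }
  infusion_segments(starts, durs, amts)
}

#' Simulate a synthetic study cohort
#'
#' Generates a complete event-record dataset emulating the study: sampled
#' covariates, per-subject log-normal random effects on CL and Vc, the
#' split-infusion regimen scaled by BSA, nominal post-dose sampling thinned
#' by the design retention probabilities, and residual error applied to the
#' model-predicted concentrations.  Observations below the assay limit of
#' quantitation are flagged (\code{BQL = 1}) but retained with their
#' simulated values.  Every subject keeps at least one observation.
#'
#' @param n Number of subjects.
#' @param design \code{\link{study_design}}.
#' @param fe \code{\link{fixed_effects}} used as simulation truth.
#' @param omega Named log-scale SDs of the random effects,
#'   \code{c(cl = , vc = )}; 0 switches a random effect off.
#' @param error \code{\link{error_model}}.
#' @param seed Integer seed; the full dataset is reproducible from it.
#' @param ref \code{\link{reference_medians}}.
#' @return A list of class \code{simulated_cohort} with \code{events}
#'   (event records, see \code{\link{read_event_csv}} for the column
#'   contract) and \code{truth} (one row per subject with covariates, eta
#'   draws and true individual parameters).
#' @export
simulate_cohort <- function(n = 505, design = study_design(),
                            fe = fixed_effects(),
                            omega = c(cl = 0.30, vc = 0.32),
                            error = error_model("proportional",
                                                sigma_prop = 0.37),
                            seed = 1, ref = reference_medians()) {
  if (length(design$sample_times_h) == 0)
    stop("empty sampling design", call. = FALSE)
  set.seed(seed)
  cov <- sample_covariates(n)
  om_cl <- if ("cl" %in% names(omega)) omega[["cl"]] else 0
  om_vc <- if ("vc" %in% names(omega)) omega[["vc"]] else 0
  eta_cl <- stats::rnorm(n, 0, om_cl)
  eta_vc <- stats::rnorm(n, 0, om_vc)
  ev <- vector("list", n)
  truth <- cov
  truth$eta_cl <- eta_cl
  truth$eta_vc <- eta_vc
  truth$cl <- truth$vc <- truth$tcl <- truth$tvc <- numeric(n)
  for (i in seq_len(n)) {
    ci <- cov[i, ]
    tcl <- typical_cl(ci, fe, ref)
    tvc <- typical_vc(ci, fe, ref)
    ip <- pk_params(cl = tcl * exp(eta_cl[i]), vc = tvc * exp(eta_vc[i]),
                    q = fe$q_fixed, vp = fe$vp_fixed)
    truth$tcl[i] <- tcl
    truth$tvc[i] <- tvc
    truth$cl[i] <- ip$cl
    truth$vc[i] <- ip$vc
    segs <- build_regimen(ci$bsa, design,
                          course_index = seq_len(design$n_courses) - 1)
    nom <- as.vector(outer(design$sample_times_h,
                           (seq_len(design$n_courses) - 1) *
                             design$course_interval_h, `+`))
    keepp <- rep(design$retention, design$n_courses)
    keep <- stats::runif(length(nom)) < keepp
    if (!any(keep)) keep[1] <- TRUE
    tobs <- sort(nom[keep])
    pred <- conc_profile(ip, segs, tobs)$conc
    dv <- apply_error(pred, error)
    dose_rows <- data.frame(ID = ci$id, TIME = segs$start_h, EVID = 1L,
                            AMT = segs$amount, DUR = segs$duration_h,
                            DV = NA_real_, BQL = NA_integer_)
    obs_rows <- data.frame(ID = ci$id, TIME = tobs, EVID = 0L,
                           AMT = NA_real_, DUR = NA_real_, DV = dv,
                           BQL = as.integer(dv < design$lloq))
    sub <- rbind(dose_rows, obs_rows)
    sub <- sub[order(sub$TIME, -sub$EVID), ]
    sub$EGFR <- ci$egfr
    sub$BW <- ci$bw
    sub$TBIL <- ci$tbil
    sub$ALB <- ci$alb
    sub$BLM <- ci$blm
    ev[[i]] <- sub
  }
  events <- do.call(rbind, ev)
  rownames(events) <- NULL
  structure(list(events = events, truth = truth, design = design, fe = fe,
                 omega = c(cl = om_cl, vc = om_vc), error = error,
                 seed = seed),
            class = "simulated_cohort")
}
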