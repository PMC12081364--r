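# Independent numerical oracle: integrates the compartment mass-balance
# ODEs piecewise between input discontinuities with a constant infusion
# rate on each piece, so the stiff solver never steps across a jump.
ode_conc_oracle <- function(params, segments, times, rtol = 1e-10,
                            atol = 1e-12) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  p <- params
  ncmt <- if (!is.null(p$q2) && p$q2 > 0) 3L else 2L
  k10 <- p$cl / p$vc
  k12 <- p$q / p$vc
  k21 <- if (p$q > 0) p$q / p$vp else 0
  k13 <- if (ncmt == 3L) p$q2 / p$vc else 0
  k31 <- if (ncmt == 3L) p$q2 / p$vp2 else 0
  rhs <- function(t, y, parms) {
    list(c(parms$rate - (k10 + k12 + k13) * y[1] + k21 * y[2] + k31 * y[3],
           k12 * y[1] - k21 * y[2],
           k13 * y[1] - k31 * y[3]))
  }
  brk <- sort(unique(c(0, segments$start_h,
                       segments$start_h + segments$duration_h, times)))
  state <- c(0, 0, 0)
  out_c <- setNames(numeric(length(times)), NULL)
  for (i in seq_len(length(brk) - 1)) {
    t0 <- brk[i]
    t1 <- brk[i + 1]
    mid <- (t0 + t1) / 2
    rate <- sum(segments$rate[segments$start_h < mid &
                                mid < segments$start_h +
                                  segments$duration_h])
    sol <- deSolve::lsoda(state, c(t0, t1), rhs, list(rate = rate),
                          rtol = rtol, atol = atol)
    state <- as.numeric(sol[nrow(sol), -1])
    hit <- which(abs(times - t1) < 1e-12)
    if (length(hit)) out_c[hit] <- state[1] / p$vc
  }
  if (any(abs(times) < 1e-12)) out_c[abs(times) < 1e-12] <- 0
  out_c
}

# Exact marginal -2 log-likelihood for the two-compartment proportional /
# additive error model with eta on CL and Vc, by dense (non-adaptive)
# Gauss-Hermite quadrature.  Brute-force oracle for the FOCE objective.
gh_quad_ofv <- function(spec, est, data, nq = 41) {
  pd <- mtxppk:::prepare_data(data, spec)
  xd <- mtxppk:::covariate_design(spec, pd)
  ty <- mtxppk:::subject_typicals(spec, est, pd, xd)
  i1 <- seq_len(nq - 1)
  b <- sqrt(i1 / 2)
  A <- matrix(0, nq, nq)
  A[cbind(i1, i1 + 1)] <- b
  A[cbind(i1 + 1, i1)] <- b
  e <- eigen(A, symmetric = TRUE)
  z <- e$values * sqrt(2)
  w <- e$vectors[1, ]^2
  om <- c(est[["omega_cl"]], est[["omega_vc"]])
  sg_p <- if ("sigma_prop" %in% names(est)) est[["sigma_prop"]] else 0
  sg_a <- if ("sigma_add" %in% names(est)) est[["sigma_add"]] else 0
  total <- 0
  for (i in seq_len(pd$n_sub)) {
    o0 <- pd$cpp$obs_ptr[i] + 1L
    o1 <- pd$cpp$obs_ptr[i + 1L]
    s0 <- pd$cpp$seg_ptr[i] + 1L
    s1 <- pd$cpp$seg_ptr[i + 1L]
    y <- pd$cpp$y[o0:o1]
    grid <- expand.grid(a = z * om[1], b = z * om[2])
    wts <- as.vector(outer(w, w))
    pars <- cbind(ty$tcl[i] * exp(grid$a), ty$tvc[i] * exp(grid$b),
                  ty$tq[i], ty$tvp[i], 0, 0)
    f <- mtxppk:::cpp_conc_profile_multi(pd$cpp$tobs[o0:o1],
                                         pd$cpp$ss[s0:s1],
                                         pd$cpp$sd[s0:s1],
                                         pd$cpp$sr[s0:s1], pars, 2L)
    v <- sg_a^2 + sg_p^2 * f^2
    ll <- rowSums(stats::dnorm(matrix(y, nrow(f), ncol(f), byrow = TRUE),
                               f, sqrt(v), log = TRUE))
    m <- max(ll)
    total <- total - 2 * log(sum(wts * exp(ll - m))) - 2 * m
  }
  total
}

# Published final-model estimate vector in the estimator's naming.
final_truth <- function() {
  c(theta_cl = 12.88, theta_vc = 72.04, theta_q = 1.08, theta_vp = 94.94,
    beta_cl_egfr = 0.23, beta_cl_bw = 0.39, beta_cl_blm = 0.08,
    beta_cl_tbil = -0.05, beta_cl_alb = -0.18, beta_vc_bw = 0.31,
    omega_cl = 0.30, omega_vc = 0.32, sigma_prop = 0.37)
}

# Table 3 95% confidence intervals of the final model (used by the
# parameter-recovery acceptance checks).
final_ci <- function() {
  list(theta_cl = c(12.49, 13.26), theta_vc = c(70.00, 74.09),
       beta_cl_egfr = c(0.17, 0.29), beta_cl_bw = c(0.32, 0.46),
       beta_vc_bw = c(0.24, 0.39), beta_cl_blm = c(0.05, 0.10),
       sigma_prop = c(0.36, 0.38))
}

# Small one-course design for fast fits in unit tests.
quick_design <- function(...) study_design(n_courses = 1, ...)
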