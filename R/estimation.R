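#' Specify a nonlinear mixed-effects model
#'
#' Defines the structural model (one-, two- or three-compartment infusion
#' kinetics), the covariate map on CL and Vc, which parameters carry
#' exponential inter-individual variability, and the residual-error family.
#' Continuous covariates enter as powers of their median-standardized
#' values; binary covariates as a log-scale shift — the two functional
#' forms of the final model.
#'
#' @param structural "two_cmt" (default), "one_cmt" or "three_cmt".
#' @param covariates A data.frame with columns \code{param} ("cl"/"vc"),
#'   \code{cov} (lower-case covariate name matching an upper-case dataset
#'   column), \code{form} ("power" or "exponential"), and optionally
#'   \code{init} (coefficient start value, default 0) and \code{group}
#'   (mutually exclusive candidate group label, default NA).  NULL for a
#'   covariate-free model.
#' @param iiv Named log-scale SD start values for the random effects, a
#'   subset of \code{c(cl=, vc=, q=, vp=)}.  Omitted parameters carry no
#'   random effect.
#' @param error Residual-error family.
#' @param init Named start values for the disposition parameters.
#' @param estimate Named logicals: which disposition parameters are
#'   estimated (the others stay fixed at \code{init}).
#' @param sigma_init Start values for the residual SDs
#'   (\code{c(prop =, add =)}).
#' @param ref \code{\link{reference_medians}} used for standardization;
#'   covariates without a reference median are standardized to the dataset
#'   median at fit time.
#' @param lloq Assay lower limit of quantitation, umol/L.
#' @param censored_lloq If TRUE, observations flagged below the limit enter
#'   the likelihood as left-censored; by default they enter as ordinary
#'   values, mirroring the assay practice of reporting them.
#' @param agq_nodes Nodes per random-effect dimension of the adaptive
#'   Gauss-Hermite refinement of the conditional (Laplace) marginal
#'   likelihood; 1 gives the pure Laplace approximation.  The default 3
#'   removes most of the Laplace bias of the proportional-error model at
#'   this design's sparse sampling (see the methods vignette).
#' @return A list of class \code{ppk_spec}.
#' @seealso \code{\link{base_model_spec}}, \code{\link{final_model_spec}}
#' @export
model_spec <- function(structural = c("two_cmt", "one_cmt", "three_cmt"),
                       covariates = NULL,
                       iiv = c(cl = 0.3, vc = 0.3),
                       error = c("proportional", "additive", "combined"),
                       init = c(cl = 10, vc = 50, q = 1.08, vp = 94.94,
                                q2 = 0.5, vp2 = 50),
                       estimate = c(cl = TRUE, vc = TRUE, q = FALSE,
                                    vp = FALSE, q2 = FALSE, vp2 = FALSE),
                       sigma_init = c(prop = 0.3, add = 1),
                       ref = reference_medians(), lloq = 0.3,
                       censored_lloq = FALSE, agq_nodes = 3) {
  structural <- match.arg(structural)
  error <- match.arg(error)
  covariates <- normalize_covariates(covariates)
  base_init <- c(cl = 10, vc = 50, q = 1.08, vp = 94.94, q2 = 0.5, vp2 = 50)
  base_init[names(init)] <- init
  base_est <- c(cl = TRUE, vc = TRUE, q = FALSE, vp = FALSE, q2 = FALSE,
                vp2 = FALSE)
  base_est[names(estimate)] <- estimate
  if (any(base_init[c("cl", "vc", "q", "vp")] <= 0))
    stop("disposition start values must be positive", call. = FALSE)
  if (length(iiv)) {
    if (!all(names(iiv) %in% c("cl", "vc", "q", "vp")))
      stop("iiv names must be among cl, vc, q, vp", call. = FALSE)
    if (any(iiv <= 0))
      stop("iiv start values must be positive (omit a name to drop its ",
           "random effect)", call. = FALSE)
  }
  if (!any(base_est) && is.null(covariates))
    stop("at least one parameter must be estimated", call. = FALSE)
  structure(list(structural = structural, covariates = covariates,
                 iiv = iiv, error = error, init = base_init,
                 estimate = base_est, sigma_init = sigma_init, ref = ref,
                 lloq = lloq, censored_lloq = censored_lloq,
                 agq_nodes = agq_nodes),
            class = "ppk_spec")
}

normalize_covariates <- function(covariates) {
  if (is.null(covariates) || (is.data.frame(covariates) &&
                              nrow(covariates) == 0))
    return(data.frame(param = character(0), cov = character(0),
                      form = character(0), init = numeric(0),
                      group = character(0), stringsAsFactors = FALSE))
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (!all(c("param", "cov", "form") %in% names(covariates)))
    stop("'covariates' needs columns param, cov, form", call. = FALSE)
  if (!all(covariates$param %in% c("cl", "vc")))
    stop("covariates are supported on 'cl' and 'vc'", call. = FALSE)
  if (!all(covariates$form %in% c("power", "exponential")))
    stop("covariate form must be 'power' or 'exponential'", call. = FALSE)
  if (is.null(covariates$init)) covariates$init <- 0
  if (is.null(covariates$group)) covariates$group <- NA_character_
  if (anyDuplicated(covariates[, c("param", "cov")]))
    stop("duplicate covariate terms", call. = FALSE)
  covariates
}

#' Covariate-free base model
#'
#' Two-compartment structural model with exponential IIV on CL and Vc,
#' proportional residual error, Q and Vp fixed.
#' @param ... Passed on to \code{\link{model_spec}}.
#' @export
base_model_spec <- function(...) model_spec(covariates = NULL, ...)

#' Final-model structure
#'
#' The published covariate structure: eGFR, BW, bleomycin, TBIL and ALB on
#' CL; BW on Vc; exponential IIV on CL and Vc; proportional residual error;
#' Q and Vp fixed at 1.08 L/h and 94.94 L.  Start values are generic (not
#' the published estimates) unless overridden.
#' @param ... Passed on to \code{\link{model_spec}}.
#' @export
final_model_spec <- function(...) {
  covs <- data.frame(
    param = c("cl", "cl", "cl", "cl", "cl", "vc"),
    cov = c("egfr", "bw", "blm", "tbil", "alb", "bw"),
    form = c("power", "power", "exponential", "power", "power", "power"),
    stringsAsFactors = FALSE)
  model_spec(covariates = covs, ...)
}

# ---- internal parameter table ---------------------------------------------

spec_partable <- function(spec) {
  rows <- list()
  disp <- c("cl", "vc", "q", "vp")
  if (spec$structural == "three_cmt") disp <- c(disp, "q2", "vp2")
  for (p in disp)
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0("theta_", p), kind = "theta", target = p,
                 cov = NA_character_, trans = "log",
                 init = unname(spec$init[p]),
                 est = unname(spec$estimate[p]), stringsAsFactors = FALSE)
  cv <- spec$covariates
  if (nrow(cv))
    for (i in seq_len(nrow(cv)))
      rows[[length(rows) + 1L]] <-
        data.frame(name = paste0("beta_", cv$param[i], "_", cv$cov[i]),
                   kind = "beta", target = cv$param[i], cov = cv$cov[i],
                   trans = "id", init = cv$init[i], est = TRUE,
                   stringsAsFactors = FALSE)
  for (p in intersect(c("cl", "vc", "q", "vp"), names(spec$iiv)))
    rows[[length(rows) + 1L]] <-
      data.frame(name = paste0("omega_", p), kind = "omega", target = p,
                 cov = NA_character_, trans = "log",
                 init = unname(spec$iiv[p]), est = TRUE,
                 stringsAsFactors = FALSE)
  if (spec$error %in% c("proportional", "combined"))
    rows[[length(rows) + 1L]] <-
      data.frame(name = "sigma_prop", kind = "sigma", target = "prop",
                 cov = NA_character_, trans = "log",
                 init = unname(spec$sigma_init["prop"]), est = TRUE,
                 stringsAsFactors = FALSE)
  if (spec$error %in% c("additive", "combined"))
    rows[[length(rows) + 1L]] <-
      data.frame(name = "sigma_add", kind = "sigma", target = "add",
                 cov = NA_character_, trans = "log",
                 init = unname(spec$sigma_init["add"]), est = TRUE,
                 stringsAsFactors = FALSE)
  do.call(rbind, rows)
}

#' Default estimate vector of a model specification
#'
#' Named start values (natural scale) in the order the estimator uses.
#' Useful as the \code{estimates} argument of \code{\link{nlme_ofv}},
#' \code{\link{nlme_predict}} and the simulation-based diagnostics.
#' @param spec A \code{\link{model_spec}}.
#' @return Named numeric vector.
#' @export
spec_estimates <- function(spec) {
  pt <- spec_partable(spec)
  stats::setNames(pt$init, pt$name)
}

# ---- dataset preparation ---------------------------------------------------

prepare_data <- function(events, spec) {
  if (inherits(events, "simulated_cohort")) events <- events$events
  validate_events(events)
  ids <- unique(events$ID)
  y <- tobs <- ss <- sd_ <- sr <- numeric(0)
  cens <- integer(0)
  obs_ptr <- seg_ptr <- 0L
  covlist <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sub <- events[events$ID == ids[k], ]
    ob <- sub[sub$EVID == 0L, ]
    dd <- sub[sub$EVID == 1L, ]
    if (nrow(ob) == 0L)
      stop("subject ", ids[k], " has no observations", call. = FALSE)
    if (nrow(dd) == 0L)
      stop("subject ", ids[k], " has no dose events", call. = FALSE)
    y <- c(y, ob$DV)
    tobs <- c(tobs, ob$TIME)
    cens <- c(cens, ifelse(is.na(ob$BQL), 0L, ob$BQL))
    ss <- c(ss, dd$TIME)
    sd_ <- c(sd_, dd$DUR)
    sr <- c(sr, dd$AMT / dd$DUR)
    obs_ptr <- c(obs_ptr, length(y))
    seg_ptr <- c(seg_ptr, length(ss))
    covlist[[k]] <- sub[1, setdiff(names(sub), EVENT_COLS[1:7]),
                        drop = FALSE]
  }
  cov <- do.call(rbind, covlist)
  names(cov) <- tolower(names(cov))
  rownames(cov) <- NULL
  list(cpp = list(y = y, tobs = tobs, cens = as.integer(cens),
                  obs_ptr = as.integer(obs_ptr), ss = ss, sd = sd_,
                  sr = sr, seg_ptr = as.integer(seg_ptr)),
       cov = cov, ids = ids, n_obs = length(y), n_sub = length(ids))
}

# Design matrices of the log-scale covariate model: one column per beta,
# power terms log(x/ref), binary terms the raw indicator.
covariate_design <- function(spec, pd) {
  cv <- spec$covariates
  out <- list(cl = NULL, vc = NULL,
              cl_names = character(0), vc_names = character(0))
  if (!nrow(cv)) return(out)
  for (p in c("cl", "vc")) {
    rows <- cv[cv$param == p, , drop = FALSE]
    if (!nrow(rows)) next
    X <- matrix(0, pd$n_sub, nrow(rows))
    for (j in seq_len(nrow(rows))) {
      cname <- rows$cov[j]
      if (!cname %in% names(pd$cov))
        stop("covariate '", cname, "' not found in the dataset",
             call. = FALSE)
      x <- pd$cov[[cname]]
      if (rows$form[j] == "power") {
        refv <- if (cname %in% names(spec$ref)) spec$ref[[cname]]
                else stats::median(x)
        if (any(x <= 0))
          stop("non-positive values of covariate '", cname, "'",
               call. = FALSE)
        X[, j] <- log(x / refv)
      } else {
        X[, j] <- x
      }
    }
    out[[p]] <- X
    out[[paste0(p, "_names")]] <- paste0("beta_", p, "_", rows$cov)
  }
  out
}

ncmt_code <- function(structural)
  switch(structural, one_cmt = 1L, two_cmt = 2L, three_cmt = 3L)

# Per-subject typical disposition parameters at a given estimate vector.
subject_typicals <- function(spec, est, pd, xd) {
  n <- pd$n_sub
  ltcl <- rep(log(est[["theta_cl"]]), n)
  ltvc <- rep(log(est[["theta_vc"]]), n)
  if (!is.null(xd$cl)) ltcl <- ltcl + as.vector(xd$cl %*% est[xd$cl_names])
  if (!is.null(xd$vc)) ltvc <- ltvc + as.vector(xd$vc %*% est[xd$vc_names])
  q2 <- if ("theta_q2" %in% names(est)) est[["theta_q2"]] else 0
  vp2 <- if ("theta_vp2" %in% names(est)) est[["theta_vp2"]] else 0
  list(tcl = exp(ltcl), tvc = exp(ltvc),
       tq = rep(if (spec$structural == "one_cmt") 0 else est[["theta_q"]],
                n),
       tvp = rep(est[["theta_vp"]], n),
       tq2 = rep(q2, n), tvp2 = rep(vp2, n))
}

eta_map <- function(spec) {
  present <- intersect(c("cl", "vc", "q", "vp"), names(spec$iiv))
  as.integer(match(present, c("cl", "vc", "q", "vp")) - 1L)
}

sigma_of <- function(est) {
  c(add = if ("sigma_add" %in% names(est)) est[["sigma_add"]] else 0,
    prop = if ("sigma_prop" %in% names(est)) est[["sigma_prop"]] else 0)
}

omega_of <- function(spec, est) {
  present <- intersect(c("cl", "vc", "q", "vp"), names(spec$iiv))
  unname(est[paste0("omega_", present)])
}

# Gauss-Hermite nodes/weights for the N(0,1) weight (Golub-Welsch).
gh_nodes <- function(n) {
  if (n <= 1) return(list(z = 0, w = 1))
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(z = e$values * sqrt(2), w = e$vectors[1, ]^2)
}

foce_call <- function(spec, est, pd, xd, eta0 = NULL, detail = FALSE) {
  ty <- subject_typicals(spec, est, pd, xd)
  em <- eta_map(spec)
  if (is.null(eta0)) eta0 <- matrix(0, pd$n_sub, length(em))
  agq <- if (is.null(spec$agq_nodes)) 3L else spec$agq_nodes
  gh <- gh_nodes(agq)
  cpp_foce(pd$cpp, ty$tcl, ty$tvc, ty$tq, ty$tvp, ty$tq2, ty$tvp2,
           ncmt_code(spec$structural), em, omega_of(spec, est),
           sigma_of(est)[["add"]], sigma_of(est)[["prop"]], spec$lloq,
           spec$censored_lloq, eta0, detail, gh$z, gh$w)
}

#' FOCE objective function value
#'
#' Minus twice the approximate log marginal likelihood of the dataset under
#' the model, computed per subject by a Laplace approximation at the
#' conditional mode of the random effects with the Gauss-Newton curvature
#' and residual variance evaluated at the conditional prediction
#' (FOCE with interaction).  With no random effects this is the exact
#' Gaussian -2 log-likelihood.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param estimates Named estimate vector (see
#'   \code{\link{spec_estimates}}).
#' @param data Event-record data.frame or \code{\link{simulate_cohort}}
#'   result.
#' @return The objective function value (scalar).
#' @export
nlme_ofv <- function(spec, estimates, data) {
  pd <- prepare_data(data, spec)
  xd <- covariate_design(spec, pd)
  res <- foce_call(spec, estimates, pd, xd)
  if (!res$ok || !is.finite(res$ofv))
    stop("non-finite likelihood at the supplied estimates", call. = FALSE)
  res$ofv
}

#' Information criteria from an objective function value
#'
#' \code{aic = ofv + 2p}, \code{bic = ofv + p log(n)} with p the number of
#' estimated parameters and n the number of observations.
#'
#' @param ofv Objective function value (-2 log-likelihood).
#' @param p Number of estimated parameters (>= 1).
#' @param n Number of observations (>= 1).
#' @return A list with \code{aic} and \code{bic}.
#' @examples
#' information_criteria(10421.315, 11, 5470)
#' @export
information_criteria <- function(ofv, p, n) {
  if (p < 1 || n < 1) stop("p and n must be >= 1", call. = FALSE)
  list(aic = ofv + 2 * p, bic = ofv + p * log(n))
}

#' Control settings for \code{\link{nlme_fit}}
#'
#' @param compute_se Compute standard errors from the numerically
#'   differentiated curvature at the optimum (adds roughly 2 p^2 objective
#'   evaluations).
#' @param iter_max,eval_max Outer optimizer budgets (per round).
#' @param rel_tol Outer relative convergence tolerance on the objective.
#' @param omega_floor Estimated random-effect SDs below this value are
#'   reported as 0 with a boundary flag.
#' @param grad_step Finite-difference step of the outer gradient, on the
#'   transformed (log for scale parameters) scale.
#' @param grad_tol Max-norm of the final gradient below which a
#'   "false convergence" stop from the line search is accepted as
#'   converged.
#' @param restarts Maximum optimizer restarts when the stop looks
#'   premature.
#' @export
fit_control <- function(compute_se = TRUE, iter_max = 300, eval_max = 2000,
                        rel_tol = 1e-8, omega_floor = 1e-4,
                        grad_step = 1e-3, grad_tol = 0.5, restarts = 2) {
  list(compute_se = compute_se, iter_max = iter_max, eval_max = eval_max,
       rel_tol = rel_tol, omega_floor = omega_floor,
       grad_step = grad_step, grad_tol = grad_tol, restarts = restarts)
}

#' Fit a population model by FOCE
#'
#' Maximizes the approximate marginal likelihood over the fixed effects,
#' covariate coefficients, random-effect SDs and residual SDs.  Scale
#' parameters are log-transformed during the search so they stay positive;
#' covariate coefficients are unconstrained.  Standard errors and 95
#' percent confidence intervals come from the inverse curvature of the
#' objective at the optimum (delta method back to the natural scale).
#' Non-convergence is flagged on the result, not thrown.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param data Event records or a \code{\link{simulate_cohort}} result.
#' @param init Optional named vector overriding the spec's start values
#'   (e.g. a previous fit's estimates for a warm start).
#' @param seed Integer; fixed for reproducibility of any randomized
#'   restart (the search itself is deterministic).
#' @param control \code{\link{fit_control}}.
#' @return An object of class \code{ppk_fit}: estimate table, \code{ofv},
#'   \code{aic}, \code{bic}, per-subject random-effect modes, shrinkage,
#'   convergence flag.
#' @export
nlme_fit <- function(spec, data, init = NULL, seed = 1,
                     control = fit_control()) {
  set.seed(seed)
  pd <- prepare_data(data, spec)
  xd <- covariate_design(spec, pd)
  pt <- spec_partable(spec)
  start <- stats::setNames(pt$init, pt$name)
  if (!is.null(init)) {
    common <- intersect(names(init), names(start))
    start[common] <- init[common]
  }
  free <- pt$est
  trans <- pt$trans
  to_trans <- function(v) ifelse(trans == "log", log(v), v)
  from_trans <- function(v) ifelse(trans == "log", exp(v), v)
  full <- to_trans(start)
  state <- new.env(parent = emptyenv())
  state$eta <- matrix(0, pd$n_sub, length(eta_map(spec)))
  objfn <- function(pfree) {
    full[free] <- pfree
    est <- stats::setNames(from_trans(full), pt$name)
    res <- foce_call(spec, est, pd, xd, eta0 = state$eta)
    if (!is.finite(res$ofv) || !res$ok) return(1e10)
    state$eta <- res$eta
    res$ofv
  }
  # Central-difference gradient on the transformed scale.  The explicit
  # step (default 1e-3) is much larger than the residual noise of the
  # warm-started inner optimization, which nlminb's own tiny internal
  # steps would otherwise amplify into spurious gradients.
  gradfn <- function(pfree) {
    vapply(seq_along(pfree), function(k) {
      pp <- pm <- pfree
      pp[k] <- pp[k] + control$grad_step
      pm[k] <- pm[k] - control$grad_step
      (objfn(pp) - objfn(pm)) / (2 * control$grad_step)
    }, numeric(1))
  }
  lower <- rep(-Inf, sum(free))
  lower[pt$kind[free] %in% c("omega", "sigma")] <- log(1e-5)
  p_cur <- full[free]
  opt <- NULL
  for (round in seq_len(1 + control$restarts)) {
    opt <- stats::nlminb(p_cur, objfn, gradient = gradfn, lower = lower,
                         control = list(iter.max = control$iter_max,
                                        eval.max = control$eval_max,
                                        rel.tol = control$rel_tol))
    moved <- max(abs(opt$par - p_cur)) > 1e-7
    p_cur <- opt$par
    if (opt$convergence == 0 || !moved) break
  }
  full[free] <- p_cur
  est <- stats::setNames(from_trans(full), pt$name)
  converged <- opt$convergence == 0
  if (!converged) {
    # line-search stops ("false convergence") at a flat gradient are fine
    gmax <- max(abs(gradfn(p_cur)))
    if (is.finite(gmax) && gmax < control$grad_tol) converged <- TRUE
  }
  boundary <- pt$kind == "omega" & est < control$omega_floor
  est[boundary] <- 0
  se <- rse <- lo <- hi <- rep(NA_real_, nrow(pt))
  if (control$compute_se) {
    H <- try(pracma::hessian(objfn, opt$par), silent = TRUE)
    covt <- if (!inherits(H, "try-error"))
      try(2 * solve(H), silent = TRUE) else H
    if (!inherits(covt, "try-error") && all(diag(covt) > 0)) {
      se_t <- sqrt(diag(covt))
      k <- 1L
      for (i in which(free)) {
        if (trans[i] == "log") {
          se[i] <- est[i] * se_t[k]
          lo[i] <- est[i] * exp(-1.96 * se_t[k])
          hi[i] <- est[i] * exp(1.96 * se_t[k])
        } else {
          se[i] <- se_t[k]
          lo[i] <- est[i] - 1.96 * se_t[k]
          hi[i] <- est[i] + 1.96 * se_t[k]
        }
        k <- k + 1L
      }
      rse <- 100 * se / abs(est)
    } else {
      warning("curvature not positive definite; standard errors unavailable")
    }
  }
  detail <- foce_call(spec, est, pd, xd, eta0 = state$eta, detail = TRUE)
  em <- eta_map(spec)
  eta <- detail$eta
  colnames(eta) <- c("cl", "vc", "q", "vp")[em + 1L]
  omg <- omega_of(spec, est)
  shrink <- if (length(em))
    stats::setNames(1 - apply(eta, 2, stats::sd) / pmax(omg, 1e-12),
                    colnames(eta)) else numeric(0)
  p <- sum(free)
  ic <- information_criteria(detail$ofv, p, pd$n_obs)
  tab <- data.frame(parameter = pt$name, estimate = unname(est), se = se,
                    rse_pct = rse, ci_lo = lo, ci_hi = hi,
                    fixed = !pt$est, boundary = boundary,
                    stringsAsFactors = FALSE)
  structure(list(spec = spec, estimates = est, table = tab,
                 ofv = detail$ofv, aic = ic$aic, bic = ic$bic,
                 n_obs = pd$n_obs, n_subjects = pd$n_sub, p = p,
                 eta = eta, shrinkage = shrink, converged = converged,
                 boundary = any(boundary), data = if (inherits(data,
                   "simulated_cohort")) data$events else data,
                 opt = list(iterations = opt$iterations,
                            evaluations = opt$evaluations,
                            message = opt$message)),
            class = "ppk_fit")
}

#' @export
print.ppk_fit <- function(x, ...) {
  cat("Population PK fit (FOCE)\n")
  cat(sprintf("  subjects: %d   observations: %d   estimated parameters: %d\n",
              x$n_subjects, x$n_obs, x$p))
  cat(sprintf("  OFV: %.3f   AIC: %.3f   BIC: %.3f   converged: %s\n",
              x$ofv, x$aic, x$bic, x$converged))
  print(transform(x$table, estimate = signif(estimate, 4),
                  se = signif(se, 3), rse_pct = signif(rse_pct, 3),
                  ci_lo = signif(ci_lo, 4), ci_hi = signif(ci_hi, 4)),
        row.names = FALSE)
  if (length(x$shrinkage))
    cat("  eta shrinkage:",
        paste(sprintf("%s %.1f%%", names(x$shrinkage),
                      100 * x$shrinkage), collapse = ", "), "\n")
  invisible(x)
}

#' Population and individual predictions
#'
#' PRED evaluates the structural model at the typical (covariate-adjusted)
#' parameters; IPRED at the conditional modes of the random effects.
#'
#' @param spec A \code{\link{model_spec}} (or a \code{ppk_fit}, in which
#'   case its spec, estimates and data are used).
#' @param estimates Named estimate vector; ignored when \code{spec} is a
#'   fit.
#' @param data Event records; ignored when \code{spec} is a fit, unless
#'   supplied.
#' @return data.frame with ID, TIME, DV, PRED, IPRED, CWRES.
#' @export
nlme_predict <- function(spec, estimates = NULL, data = NULL) {
  if (inherits(spec, "ppk_fit")) {
    if (is.null(data)) data <- spec$data
    estimates <- spec$estimates
    spec <- spec$spec
  }
  pd <- prepare_data(data, spec)
  xd <- covariate_design(spec, pd)
  ty <- subject_typicals(spec, estimates, pd, xd)
  em <- eta_map(spec)
  res <- cpp_cwres(pd$cpp, ty$tcl, ty$tvc, ty$tq, ty$tvp, ty$tq2, ty$tvp2,
                   ncmt_code(spec$structural), em, omega_of(spec, estimates),
                   sigma_of(estimates)[["add"]],
                   sigma_of(estimates)[["prop"]], spec$lloq,
                   spec$censored_lloq,
                   matrix(0, pd$n_sub, length(em)))
  data.frame(ID = rep(pd$ids, diff(pd$cpp$obs_ptr)), TIME = pd$cpp$tobs,
             DV = pd$cpp$y, PRED = res$pred, IPRED = res$ipred,
             CWRES = res$cwres)
}

#' Conditional weighted residuals
#'
#' FOCE-linearized residuals: the observation minus the conditional
#' prediction corrected back to eta = 0, scaled by the square root of the
#' linearized total variance (random-effect gradient term plus residual
#' variance at the conditional prediction).  Under a correct model they are
#' approximately standard normal.
#'
#' @inheritParams nlme_predict
#' @return Numeric vector, one value per observation row.
#' @export
cwres <- function(spec, estimates = NULL, data = NULL) {
  nlme_predict(spec, estimates, data)$CWRES
}

# Simulate replicate observation vectors at the observed design.
# Returns an n_obs x n_sim matrix; rows follow the dataset observation
# order.  Each subject's replicate stream is seeded from (seed, subject
# id), so the simulated ensemble — and the NPDE built from it — does not
# depend on the order subjects appear in the dataset.
simulate_observations <- function(spec, estimates, pd, xd, n_sim, seed) {
  ty <- subject_typicals(spec, estimates, pd, xd)
  em <- eta_map(spec)
  omg <- omega_of(spec, estimates)
  sig <- sigma_of(estimates)
  out <- matrix(NA_real_, pd$n_obs, n_sim)
  ncmt <- ncmt_code(spec$structural)
  for (i in seq_len(pd$n_sub)) {
    set.seed(as.integer((as.numeric(seed) * 131071 +
                           as.numeric(pd$ids[i]) * 524287) %% 2147483647))
    o0 <- pd$cpp$obs_ptr[i] + 1L
    o1 <- pd$cpp$obs_ptr[i + 1L]
    s0 <- pd$cpp$seg_ptr[i] + 1L
    s1 <- pd$cpp$seg_ptr[i + 1L]
    pars <- matrix(rep(c(ty$tcl[i], ty$tvc[i], ty$tq[i], ty$tvp[i],
                         ty$tq2[i], ty$tvp2[i]), each = n_sim), n_sim, 6)
    for (k in seq_along(em))
      pars[, em[k] + 1L] <- pars[, em[k] + 1L] *
        exp(stats::rnorm(n_sim, 0, omg[k]))
    f <- cpp_conc_profile_multi(pd$cpp$tobs[o0:o1], pd$cpp$ss[s0:s1],
                                pd$cpp$sd[s0:s1], pd$cpp$sr[s0:s1], pars,
                                ncmt)
    nobs <- o1 - o0 + 1L
    eps_p <- if (sig[["prop"]] > 0)
      pmax(matrix(stats::rnorm(n_sim * nobs, 0, sig[["prop"]]), n_sim),
           -0.999) else 0
    eps_a <- if (sig[["add"]] > 0)
      matrix(stats::rnorm(n_sim * nobs, 0, sig[["add"]]), n_sim) else 0
    out[o0:o1, ] <- t(f * (1 + eps_p) + eps_a)
  }
  out
}
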