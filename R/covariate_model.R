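#' Reference medians for covariate standardization
#'
#' Continuous covariates enter the model standardized to the study medians:
#' eGFR 102.2 mL/min/1.73m2, body weight 47 kg, total bilirubin 15.3 umol/L,
#' albumin 40.9 g/L.
#'
#' @param egfr,bw,tbil,alb Reference medians (positive).
#' @return A list of class \code{reference_medians}.
#' @export
reference_medians <- function(egfr = 102.2, bw = 47, tbil = 15.3,
                              alb = 40.9) {
  vals <- c(egfr = egfr, bw = bw, tbil = tbil, alb = alb)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("reference medians must be positive", call. = FALSE)
  structure(as.list(vals), class = "reference_medians")
}

#' Final-model fixed effects
#'
#' Typical values and covariate coefficients of the final clearance and
#' central-volume equations:
#' \deqn{CL = \theta_{CL} (eGFR/102.2)^{0.23} (BW/47)^{0.39} e^{BLM}
#'       (TBIL/15.3)^{-0.05} (ALB/40.9)^{-0.18}}
#' with BLM = 0.08 under bleomycin co-medication and 0 otherwise, and
#' \deqn{V_c = \theta_{V_c} (BW/47)^{0.31}.}
#' Q and Vp are fixed (no covariates, no inter-individual variability).
#'
#' @param theta_cl Typical clearance, L/h.
#' @param theta_vc Typical central volume, L.
#' @param beta_egfr_cl,beta_bw_cl,beta_tbil_cl,beta_alb_cl Power exponents on
#'   median-standardized continuous covariates in the CL equation.
#' @param beta_blm_cl Log-scale shift applied when bleomycin is co-given.
#' @param beta_bw_vc Power exponent of body weight in the Vc equation.
#' @param q_fixed Inter-compartmental clearance, L/h (fixed).
#' @param vp_fixed Peripheral volume, L (fixed).
#' @return A list of class \code{fixed_effects}.
#' @export
fixed_effects <- function(theta_cl = 12.88, theta_vc = 72.04,
                          beta_egfr_cl = 0.23, beta_bw_cl = 0.39,
                          beta_tbil_cl = -0.05, beta_alb_cl = -0.18,
                          beta_blm_cl = 0.08, beta_bw_vc = 0.31,
                          q_fixed = 1.08, vp_fixed = 94.94) {
  pos <- c(theta_cl = theta_cl, theta_vc = theta_vc, q_fixed = q_fixed,
           vp_fixed = vp_fixed)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("theta_cl, theta_vc, q_fixed, vp_fixed must be positive",
         call. = FALSE)
  structure(list(theta_cl = theta_cl, theta_vc = theta_vc,
                 beta_egfr_cl = beta_egfr_cl, beta_bw_cl = beta_bw_cl,
                 beta_tbil_cl = beta_tbil_cl, beta_alb_cl = beta_alb_cl,
                 beta_blm_cl = beta_blm_cl, beta_bw_vc = beta_bw_vc,
                 q_fixed = q_fixed, vp_fixed = vp_fixed),
            class = "fixed_effects")
}

check_covrec <- function(cov) {
  need <- c("egfr", "bw", "tbil", "alb", "blm")
  miss <- setdiff(need, names(cov))
  if (length(miss))
    stop("covariate record lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cont <- unlist(cov[c("egfr", "bw", "tbil", "alb")])
  if (any(!is.finite(cont)) || any(cont <= 0))
    stop("continuous covariates must be positive", call. = FALSE)
  if (!all(cov$blm %in% c(0, 1)))
    stop("'blm' must be 0 or 1", call. = FALSE)
  invisible(cov)
}

#' Typical clearance from covariates
#'
#' Evaluates the clearance covariate equation: continuous covariates enter
#' as powers of their median-standardized values, bleomycin as a log-scale
#' shift.  At the reference medians with no bleomycin the result is exactly
#' \code{fe$theta_cl}.
#'
#' @param cov A list/row with \code{egfr}, \code{bw}, \code{tbil},
#'   \code{alb} (positive) and \code{blm} (0/1).
#' @param fe \code{\link{fixed_effects}}.
#' @param ref \code{\link{reference_medians}}.
#' @return Typical clearance, L/h.
#' @examples
#' typical_cl(list(egfr = 102.2, bw = 47, tbil = 15.3, alb = 40.9, blm = 0),
#'            fixed_effects(), reference_medians())
#' @export
typical_cl <- function(cov, fe = fixed_effects(), ref = reference_medians()) {
  check_covrec(cov)
  fe$theta_cl *
    (cov$egfr / ref$egfr)^fe$beta_egfr_cl *
    (cov$bw / ref$bw)^fe$beta_bw_cl *
    exp(cov$blm * fe$beta_blm_cl) *
    (cov$tbil / ref$tbil)^fe$beta_tbil_cl *
    (cov$alb / ref$alb)^fe$beta_alb_cl
}

#' Typical central volume from covariates
#'
#' @inheritParams typical_cl
#' @return Typical central volume, L.
#' @export
typical_vc <- function(cov, fe = fixed_effects(), ref = reference_medians()) {
  if (any(!is.finite(cov$bw)) || any(cov$bw <= 0))
    stop("'bw' must be positive", call. = FALSE)
  fe$theta_vc * (cov$bw / ref$bw)^fe$beta_bw_vc
}

#' Individual disposition parameters
#'
#' Applies exponential inter-individual variability to the typical values:
#' \code{cl = typical_cl * exp(eta_cl)}, \code{vc = typical_vc * exp(eta_vc)};
#' Q and Vp are carried over fixed.
#'
#' @inheritParams typical_cl
#' @param eta Named numeric with \code{eta_cl} and \code{eta_vc} (log-scale
#'   deviations; 0 returns the typical subject).
#' @return A \code{\link{pk_params}} object.
#' @export
individual_params <- function(cov, fe = fixed_effects(),
                              eta = c(eta_cl = 0, eta_vc = 0),
                              ref = reference_medians()) {
  eta <- as.list(eta)
  e_cl <- if (is.null(eta$eta_cl)) 0 else eta$eta_cl
  e_vc <- if (is.null(eta$eta_vc)) 0 else eta$eta_vc
  pk_params(cl = typical_cl(cov, fe, ref) * exp(e_cl),
            vc = typical_vc(cov, fe, ref) * exp(e_vc),
            q = fe$q_fixed, vp = fe$vp_fixed)
}

#' Residual error model
#'
#' One of the three residual-variability families: additive
#' (\code{obs = pred + e}), proportional (\code{obs = pred * (1 + e)}) or
#' combined (\code{obs = pred * (1 + e1) + e2}), each \code{e ~ N(0, s^2)}.
#' The final model uses the proportional form with \code{sigma_prop = 0.37}.
#'
#' @param kind "additive", "proportional" or "combined".
#' @param sigma_add Additive SD, umol/L.
#' @param sigma_prop Proportional SD (fraction).
#' @param prop_floor Lower truncation of proportional draws; defaults to
#'   -0.999 so simulated concentrations cannot flip sign.
#' @return A list of class \code{error_model}.
#' @export
error_model <- function(kind = c("proportional", "additive", "combined"),
                        sigma_add = 0, sigma_prop = 0.37,
                        prop_floor = -0.999) {
  kind <- match.arg(kind)
  if (sigma_add < 0 || sigma_prop < 0)
    stop("sigmas must be non-negative", call. = FALSE)
  if (kind == "additive" && sigma_add == 0 && sigma_prop > 0)
    sigma_prop <- 0
  structure(list(kind = kind, sigma_add = sigma_add,
                 sigma_prop = sigma_prop, prop_floor = prop_floor),
            class = "error_model")
}

#' Apply residual error to predicted concentrations
#'
#' Draws (or accepts) standard-normal-scaled residuals and applies the error
#' family of \code{err}.  Proportional draws are truncated at
#' \code{err$prop_floor} so a finite prediction can never change sign;
#' additive draws are left untouched (negative simulated values are retained
#' and handled by the estimation likelihood).
#'
#' @param pred Predicted concentrations, umol/L (non-negative).
#' @param err An \code{\link{error_model}}.
#' @param eps Optional residual draws. For "combined", a two-column matrix
#'   (proportional, additive); otherwise a vector the length of \code{pred}.
#'   When missing, draws are taken from the current RNG stream.
#' @return Observed concentrations, umol/L.
#' @export
apply_error <- function(pred, err, eps = NULL) {
  if (!inherits(err, "error_model"))
    stop("'err' must be an error_model", call. = FALSE)
  if (any(pred < 0 & is.finite(pred)))
    stop("'pred' must be non-negative", call. = FALSE)
  n <- length(pred)
  if (err$kind == "additive") {
    e <- if (is.null(eps)) stats::rnorm(n, 0, err$sigma_add)
         else eps * 1  # supplied on the natural scale
    return(pred + e)
  }
  if (err$kind == "proportional") {
    e <- if (is.null(eps)) stats::rnorm(n, 0, err$sigma_prop) else eps * 1
    e <- pmax(e, err$prop_floor)
    return(pred * (1 + e))
  }
  # combined
  if (is.null(eps)) {
    e1 <- stats::rnorm(n, 0, err$sigma_prop)
    e2 <- stats::rnorm(n, 0, err$sigma_add)
  } else {
    eps <- as.matrix(eps)
    e1 <- eps[, 1]
    e2 <- eps[, 2]
  }
  e1 <- pmax(e1, err$prop_floor)
  pred * (1 + e1) + e2
}

#' Load a model configuration file
#'
#' Reads fixed effects, inter-individual variability and residual error from
#' a YAML configuration.  The configuration shipped with the package
#' (\code{system.file("extdata", "final_model.yaml", package = "mtxppk")})
#' encodes the final-model estimates and is the default everywhere a fitted
#' model is simulated from.
#'
#' @param path Path to a YAML file; defaults to the shipped final model.
#' @return A list with \code{fe} (\code{\link{fixed_effects}}),
#'   \code{omega} (named log-scale SDs), \code{error}
#'   (\code{\link{error_model}}) and \code{ref}
#'   (\code{\link{reference_medians}}).
#' @export
load_model_config <- function(path = system.file("extdata",
                                                 "final_model.yaml",
                                                 package = "mtxppk")) {
  cfg <- yaml::read_yaml(path)
  fe <- do.call(fixed_effects, cfg$fixed_effects)
  ref <- if (is.null(cfg$reference_medians)) reference_medians()
         else do.call(reference_medians, cfg$reference_medians)
  omega <- unlist(cfg$omega)
  err <- do.call(error_model, cfg$error)
  list(fe = fe, omega = omega, error = err, ref = ref)
}
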