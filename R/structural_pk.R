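#' Disposition parameters of a mammillary compartment model
#'
#' Bundles the four (optionally six) disposition parameters of a one-, two-
#' or three-compartment model with first-order elimination from the central
#' compartment: clearance \code{cl} (L/h), central volume \code{vc} (L),
#' inter-compartmental clearance \code{q} (L/h) and peripheral volume
#' \code{vp} (L).  \code{q = 0} degenerates to a one-compartment model;
#' supplying \code{q2}/\code{vp2} adds a second peripheral compartment.
#'
#' @param cl Clearance, L/h. Must be positive.
#' @param vc Central compartment volume, L. Must be positive.
#' @param q Inter-compartmental clearance, L/h. Non-negative.
#' @param vp Peripheral compartment volume, L. Must be positive.
#' @param q2,vp2 Second-peripheral-compartment parameters (L/h, L); both 0
#'   for the standard two-compartment model.
#' @return An object of class \code{pk_params}.
#' @examples
#' pk_params(cl = 12.88, vc = 72.04, q = 1.08, vp = 94.94)
#' @export
pk_params <- function(cl, vc, q = 0, vp = 1, q2 = 0, vp2 = 0) {
  if (!is.numeric(cl) || length(cl) != 1L || !is.finite(cl) || cl <= 0)
    stop("'cl' must be a single positive number", call. = FALSE)
  if (!is.numeric(vc) || length(vc) != 1L || !is.finite(vc) || vc <= 0)
    stop("'vc' must be a single positive number", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q < 0)
    stop("'q' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(vp) || length(vp) != 1L || !is.finite(vp) || vp <= 0)
    stop("'vp' must be a single positive number", call. = FALSE)
  if (q2 < 0 || (q2 > 0 && vp2 <= 0))
    stop("'q2' must be non-negative and 'vp2' positive when q2 > 0",
         call. = FALSE)
  structure(list(cl = cl, vc = vc, q = q, vp = vp, q2 = q2, vp2 = vp2),
            class = "pk_params")
}

#' Micro rate constants and hybrid exponents
#'
#' Converts clearance/volume disposition parameters to the micro constants
#' \code{k10 = cl/vc}, \code{k12 = q/vc}, \code{k21 = q/vp} and the hybrid
#' exponents \code{alpha >= beta}, the roots of
#' \eqn{s^2 - (k10+k12+k21)s + k10 k21 = 0}.  For \code{q = 0} the model is
#' one-compartment and \code{beta = 0}.
#'
#' @param params A \code{\link{pk_params}} object (two-compartment; `q2` must
#'   be zero).
#' @return A list with elements \code{k10}, \code{k12}, \code{k21},
#'   \code{alpha}, \code{beta} (all 1/h).
#' @examples
#' micro_constants(pk_params(12.88, 72.04, 1.08, 94.94))
#' @export
micro_constants <- function(params) {
  params <- as_pk_params(params)
  if (params$q2 > 0)
    stop("micro_constants() is defined for the two-compartment model",
         call. = FALSE)
  k10 <- params$cl / params$vc
  k12 <- params$q / params$vc
  k21 <- params$q / params$vp
  s <- k10 + k12 + k21
  pr <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * pr, 0))
  list(k10 = k10, k12 = k12, k21 = k21,
       alpha = (s + disc) / 2, beta = (s - disc) / 2)
}

as_pk_params <- function(x) {
  if (inherits(x, "pk_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(pk_params(cl = x$cl, vc = x$vc,
                     q = if (is.null(x$q)) 0 else x$q,
                     vp = if (is.null(x$vp)) 1 else x$vp,
                     q2 = if (is.null(x$q2)) 0 else x$q2,
                     vp2 = if (is.null(x$vp2)) 0 else x$vp2))
  }
  stop("cannot interpret 'params' as pk_params", call. = FALSE)
}

#' Constant-rate infusion segments
#'
#' A dosing history as a table of constant-rate intravenous infusion
#' segments.  Amounts are in micromoles so central concentrations come out
#' in umol/L when volumes are in litres.
#'
#' @param start_h Segment start times, h after time zero (non-negative).
#' @param duration_h Infusion durations, h (positive).
#' @param amount Infused amounts, umol (positive).
#' @return A data.frame of class \code{infusion_segments}, sorted by start
#'   time, with a \code{rate} column (umol/h).
#' @export
infusion_segments <- function(start_h, duration_h, amount) {
  n <- length(start_h)
  if (length(duration_h) != n || length(amount) != n)
    stop("segment fields must have equal length", call. = FALSE)
  if (n == 0L) {
    out <- data.frame(start_h = numeric(0), duration_h = numeric(0),
                      amount = numeric(0), rate = numeric(0))
    class(out) <- c("infusion_segments", "data.frame")
    return(out)
  }
  if (any(!is.finite(start_h)) || any(start_h < 0))
    stop("segment start times must be non-negative", call. = FALSE)
  if (any(!is.finite(duration_h)) || any(duration_h <= 0))
    stop("segment durations must be positive", call. = FALSE)
  if (any(!is.finite(amount)) || any(amount <= 0))
    stop("segment amounts must be positive", call. = FALSE)
  o <- order(start_h)
  out <- data.frame(start_h = start_h[o], duration_h = duration_h[o],
                    amount = amount[o], rate = amount[o] / duration_h[o])
  class(out) <- c("infusion_segments", "data.frame")
  out
}

#' Central-compartment concentration profile
#'
#' Evaluates the closed-form concentration of the central compartment under
#' superposition of constant-rate infusion segments.  The analytic
#' polyexponential solution is used (during- and post-infusion branches),
#' which is exactly linear in dose and in the superposition of segments.
#'
#' @param params \code{\link{pk_params}} (or coercible list).
#' @param segments An \code{\link{infusion_segments}} table (may be empty).
#' @param times Non-negative, non-decreasing evaluation times, h.
#' @return A data.frame with columns \code{time} (h) and \code{conc}
#'   (umol/L).
#' @examples
#' p <- pk_params(12.88, 72.04, 1.08, 94.94)
#' seg <- infusion_segments(0, 1, 100)
#' conc_profile(p, seg, times = c(0.5, 1, 6, 24))
#' @export
conc_profile <- function(params, segments, times) {
  params <- as_pk_params(params)
  if (!inherits(segments, "infusion_segments"))
    segments <- infusion_segments(segments$start_h, segments$duration_h,
                                  segments$amount)
  if (any(!is.finite(times)) || any(times < 0))
    stop("'times' must be finite and non-negative", call. = FALSE)
  if (is.unsorted(times))
    stop("'times' must be non-decreasing", call. = FALSE)
  ncmt <- if (params$q2 > 0) 3L else if (params$q > 0) 2L else 1L
  conc <- cpp_conc_profile(as.numeric(times), segments$start_h,
                           segments$duration_h, segments$rate,
                           unlist(params[c("cl", "vc", "q", "vp",
                                           "q2", "vp2")]),
                           ncmt)
  data.frame(time = as.numeric(times), conc = conc)
}

#' Convert a methotrexate dose from grams to micromoles
#'
#' Doses are prescribed in g/m2 while assay concentrations are umol/L;
#' amounts are therefore carried in micromoles internally.
#'
#' @param dose_g Dose in grams (non-negative).
#' @param mw Molar mass, g/mol. Default 454.44 (methotrexate free acid).
#' @return Amount in micromoles.
#' @examples
#' dose_grams_to_umol(1)      # 2200.5 umol
#' @export
dose_grams_to_umol <- function(dose_g, mw = 454.44) {
  if (any(!is.finite(dose_g)) || any(dose_g < 0))
    stop("'dose_g' must be non-negative", call. = FALSE)
  if (!is.numeric(mw) || mw <= 0)
    stop("'mw' must be positive", call. = FALSE)
  dose_g * 1e6 / mw
}
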