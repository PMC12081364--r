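# Time after dose: dose rows within a subject are grouped into occasions
# (a dose starting during or at the end of the previous infusion continues
# the same occasion, so the 1 h + 11 h split counts as one dose); TAD is
# the time since the start of the most recent occasion.
tad_of <- function(events) {
  tad <- numeric(nrow(events))
  for (id in unique(events$ID)) {
    idx <- which(events$ID == id)
    sub <- events[idx, ]
    dose <- sub[sub$EVID == 1L, ]
    occ_start <- numeric(0)
    occ_end <- -Inf
    for (j in seq_len(nrow(dose))) {
      if (dose$TIME[j] > occ_end + 1e-9) occ_start <- c(occ_start,
                                                        dose$TIME[j])
      occ_end <- max(occ_end, dose$TIME[j] + dose$DUR[j])
    }
    for (k in seq_along(idx)) {
      starts <- occ_start[occ_start <= sub$TIME[k] + 1e-9]
      tad[idx[k]] <- if (length(starts)) sub$TIME[k] - max(starts) else NA
    }
  }
  tad
}

#' Goodness-of-fit table
#'
#' Per-observation DV, PRED, IPRED, CWRES and time after dose (TAD, time
#' since the start of the most recent dosing occasion — the split 1 h +
#' 11 h infusion counts as one occasion).
#'
#' @param fit A \code{ppk_fit}, or a \code{\link{model_spec}} together with
#'   \code{estimates}.
#' @param data Event records; taken from the fit when omitted.
#' @param estimates Named estimate vector when \code{fit} is a spec.
#' @return data.frame with ID, TIME, TAD, DV, PRED, IPRED, CWRES.
#' @export
gof_table <- function(fit, data = NULL, estimates = NULL) {
  if (inherits(fit, "ppk_fit")) {
    if (is.null(data)) data <- fit$data
    pr <- nlme_predict(fit, data = data)
  } else {
    pr <- nlme_predict(fit, estimates, data)
  }
  if (inherits(data, "simulated_cohort")) data <- data$events
  obs <- data[data$EVID == 0L, ]
  tad <- tad_of(data)[data$EVID == 0L]
  cbind(pr[, c("ID", "TIME")], TAD = tad,
        pr[, c("DV", "PRED", "IPRED", "CWRES")])
}

#' Nonparametric bootstrap of a model fit
#'
#' Resamples subjects (the hierarchical unit) with replacement to the
#' original subject count, refits the model on each replicate
#' (warm-started from the original estimates), and summarizes the
#' replicate estimates by their median and 2.5/97.5 percentiles.  Failed
#' replicates are counted and excluded from the percentiles.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param data Event records or simulated cohort.
#' @param n_runs Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (resampling is fully reproducible).
#' @param control \code{\link{fit_control}}.
#' @param fit Optional fit of \code{spec} on \code{data} used for warm
#'   starts (computed when NULL).
#' @return list of class \code{ppk_bootstrap}: \code{summary} (median and
#'   percentiles per parameter), \code{replicates} (per-run estimates),
#'   \code{n_success}, \code{n_runs}.
#' @export
bootstrap_fit <- function(spec, data, n_runs = 1000, seed = 1,
                          control = fit_control(compute_se = FALSE),
                          fit = NULL) {
  if (n_runs < 1) stop("'n_runs' must be >= 1", call. = FALSE)
  if (inherits(data, "simulated_cohort")) data <- data$events
  validate_events(data)
  if (is.null(fit)) fit <- nlme_fit(spec, data, control = control)
  ids <- unique(data$ID)
  set.seed(seed)
  subtabs <- split(data, data$ID)
  reps <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    take <- sample(as.character(ids), length(ids), replace = TRUE)
    newdat <- do.call(rbind, lapply(seq_along(take), function(k) {
      d <- subtabs[[take[k]]]
      d$ID <- k
      d
    }))
    rownames(newdat) <- NULL
    f <- fit_or_fail(spec, newdat, init = fit$estimates,
                     control = control)
    reps[[r]] <- if (!is.null(f) && f$converged) f$estimates else NULL
  }
  ok <- !vapply(reps, is.null, logical(1))
  if (!any(ok)) stop("all bootstrap replicates failed", call. = FALSE)
  mat <- do.call(rbind, reps[ok])
  summ <- data.frame(parameter = colnames(mat),
                     median = apply(mat, 2, stats::median),
                     ci_lo = apply(mat, 2, stats::quantile, 0.025),
                     ci_hi = apply(mat, 2, stats::quantile, 0.975),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(summary = summ, replicates = mat, n_success = sum(ok),
                 n_runs = n_runs, original = fit$estimates),
            class = "ppk_bootstrap")
}

#' Visual predictive check
#'
#' Simulates replicate datasets at the observed design (same subjects,
#' covariates, doses and sampling times), and compares the observed 5th,
#' 50th and 95th concentration percentiles per time-after-dose bin with the
#' 95 percent confidence band of the same percentiles across simulations.
#' Bins default to the exact nominal sampling times.
#'
#' @param spec A \code{\link{model_spec}}.
#' @param estimates Named estimate vector.
#' @param data Event records or simulated cohort.
#' @param n_sim Number of simulated replicates (>= 100).
#' @param seed Integer seed.
#' @param bins Optional numeric break points on TAD; by default each
#'   distinct observed TAD is its own bin.
#' @return list of class \code{ppk_vpc} with per-bin observed percentiles
#'   and simulated confidence bands.
#' @export
vpc <- function(spec, estimates, data, n_sim = 500, seed = 1,
                bins = NULL) {
  if (n_sim < 100) stop("'n_sim' must be >= 100", call. = FALSE)
  if (inherits(data, "simulated_cohort")) data <- data$events
  pd <- prepare_data(data, spec)
  xd <- covariate_design(spec, pd)
  sims <- simulate_observations(spec, estimates, pd, xd, n_sim, seed)
  tad <- tad_of(data)[data$EVID == 0L]
  binid <- if (is.null(bins)) factor(round(tad, 6))
           else cut(tad, breaks = bins, include.lowest = TRUE)
  y <- pd$cpp$y
  qs <- c(0.05, 0.5, 0.95)
  out <- list()
  for (b in levels(binid)) {
    sel <- which(binid == b)
    if (!length(sel)) {
      warning("empty VPC bin ", b, " dropped")
      next
    }
    obs_q <- stats::quantile(y[sel], qs, names = FALSE)
    # percentile of each simulated replicate, then band across replicates
    sim_q <- apply(sims[sel, , drop = FALSE], 2, stats::quantile, qs,
                   names = FALSE)
    band <- apply(sim_q, 1, stats::quantile, c(0.025, 0.5, 0.975),
                  names = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      bin = b, tad = stats::median(tad[sel]), n = length(sel),
      percentile = c(5, 50, 95), observed = obs_q,
      sim_lo = band[1, ], sim_med = band[2, ], sim_hi = band[3, ],
      stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, out), n_sim = n_sim, seed = seed),
            class = "ppk_vpc")
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates \code{n_sim} replicate observation vectors
#' from the model, decorrelates both the observed and the simulated
#' vectors with the inverse lower-triangular Cholesky factor of the
#' empirical simulated covariance, and computes each observation's rank
#' fraction within its decorrelated simulated ensemble (continuity-adjusted
#' by 1/(2 n_sim) to avoid 0 and 1).  The standard-normal quantiles of
#' those fractions are the NPDE; under a correct model they are standard
#' normal.  Three global tests are run on the pooled NPDE: Wilcoxon
#' signed-rank for mean zero, a two-sided chi-square variance test against
#' 1 ("Fisher's variance test"), and Shapiro-Wilk for normality (on a
#' fixed-seed subsample of at most 5000 values).
#'
#' @inheritParams vpc
#' @param n_sim Number of Monte Carlo replicates (default 1000).
#' @return list of class \code{ppk_npde}: \code{npde} per observation,
#'   \code{mean}, \code{variance}, \code{p_wilcoxon}, \code{p_variance},
#'   \code{p_shapiro}, and the observation table (ID, TIME, TAD, PRED).
#' @export
npde <- function(spec, estimates, data, n_sim = 1000, seed = 1) {
  if (n_sim < 100) stop("'n_sim' must be >= 100", call. = FALSE)
  if (inherits(data, "simulated_cohort")) data <- data$events
  pd <- prepare_data(data, spec)
  xd <- covariate_design(spec, pd)
  sims <- simulate_observations(spec, estimates, pd, xd, n_sim, seed)
  npde_v <- numeric(pd$n_obs)
  for (i in seq_len(pd$n_sub)) {
    o0 <- pd$cpp$obs_ptr[i] + 1L
    o1 <- pd$cpp$obs_ptr[i + 1L]
    E <- sims[o0:o1, , drop = FALSE]        # n_i x n_sim
    m <- rowMeans(E)
    Ec <- E - m
    V <- tcrossprod(Ec) / (n_sim - 1)
    L <- tryCatch(t(chol(V)), error = function(e) {
      warning("singular simulated covariance for subject ", pd$ids[i],
              "; ridge-regularized")
      t(chol(V + diag(1e-8 + 1e-6 * mean(diag(V)), nrow(V))))
    })
    ystar <- forwardsolve(L, pd$cpp$y[o0:o1] - m)
    Estar <- forwardsolve(L, Ec)
    r <- rowSums(Estar < ystar)
    # rank fraction, pulled off 0 and 1 by the half-count adjustment
    pde <- pmin(pmax(r / n_sim, 0.5 / n_sim), 1 - 0.5 / n_sim)
    npde_v[o0:o1] <- stats::qnorm(pde)
  }
  wil <- stats::wilcox.test(npde_v, mu = 0, exact = FALSE)
  n <- length(npde_v)
  s2 <- stats::var(npde_v)
  stat <- (n - 1) * s2
  p_var <- 2 * min(stats::pchisq(stat, n - 1),
                   stats::pchisq(stat, n - 1, lower.tail = FALSE))
  p_var <- min(p_var, 1)
  sub <- if (n > 5000) {
    set.seed(seed + 1L)
    sample(npde_v, 5000)
  } else npde_v
  sw <- stats::shapiro.test(sub)
  tad <- tad_of(data)[data$EVID == 0L]
  ty <- subject_typicals(spec, estimates, pd, xd)
  em <- eta_map(spec)
  pred <- cpp_pred(pd$cpp, ty$tcl, ty$tvc, ty$tq, ty$tvp, ty$tq2, ty$tvp2,
                   ncmt_code(spec$structural), em,
                   matrix(0, pd$n_sub, length(em)))
  structure(list(npde = npde_v, mean = mean(npde_v), variance = s2,
                 p_wilcoxon = wil$p.value, p_variance = p_var,
                 p_shapiro = sw$p.value,
                 table = data.frame(ID = rep(pd$ids, diff(pd$cpp$obs_ptr)),
                                    TIME = pd$cpp$tobs, TAD = tad,
                                    PRED = pred, NPDE = npde_v),
                 n_sim = n_sim, seed = seed),
            class = "ppk_npde")
}

#' @export
print.ppk_npde <- function(x, ...) {
  cat(sprintf(paste0("NPDE (%d simulations): mean %.4f, variance %.4f\n",
                     "  Wilcoxon p = %.4g, variance-test p = %.4g, ",
                     "Shapiro-Wilk p = %.4g\n"),
              x$n_sim, x$mean, x$variance, x$p_wilcoxon, x$p_variance,
              x$p_shapiro))
  invisible(x)
}

# ---- plots -----------------------------------------------------------------

#' Goodness-of-fit panels
#'
#' DV vs PRED, CWRES vs PRED, CWRES vs TAD and a CWRES normal Q-Q panel.
#'
#' @param gof A \code{\link{gof_table}} result.
#' @return A ggplot object (faceted panels).
#' @export
plot_gof <- function(gof) {
  long <- rbind(
    data.frame(panel = "DV vs PRED", x = gof$PRED, y = gof$DV),
    data.frame(panel = "CWRES vs PRED", x = gof$PRED, y = gof$CWRES),
    data.frame(panel = "CWRES vs TAD", x = gof$TAD, y = gof$CWRES),
    data.frame(panel = "CWRES Q-Q",
               x = stats::qnorm(stats::ppoints(length(gof$CWRES)))[
                 order(order(gof$CWRES))],
               y = gof$CWRES))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::theme_bw() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' VPC ribbon plot
#'
#' @param x A \code{\link{vpc}} result.
#' @return A ggplot object.
#' @export
plot_vpc <- function(x) {
  tab <- x$table
  tab$percentile <- factor(tab$percentile)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$tad,
                                    group = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo,
                                      ymax = .data$sim_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim_med),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed),
                       colour = "firebrick") +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "time after dose (h)",
                  y = "concentration (umol/L)")
}

#' NPDE diagnostic panels
#'
#' Histogram with the standard-normal density, normal Q-Q panel, and NPDE
#' against TAD and against the population prediction.
#'
#' @param x A \code{\link{npde}} result.
#' @return A ggplot object.
#' @export
plot_npde <- function(x) {
  tab <- x$table
  long <- rbind(
    data.frame(panel = "NPDE vs TAD", x = tab$TAD, y = tab$NPDE),
    data.frame(panel = "NPDE vs PRED", x = tab$PRED, y = tab$NPDE),
    data.frame(panel = "Q-Q",
               x = stats::qnorm(stats::ppoints(length(tab$NPDE)))[
                 order(order(tab$NPDE))],
               y = tab$NPDE))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::theme_bw() +
    ggplot2::labs(x = NULL, y = "NPDE")
}
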