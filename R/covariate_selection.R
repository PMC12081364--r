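#' Likelihood-ratio thresholds of the stepwise search
#'
#' Chi-square (1 df) critical values used for covariate selection: an OFV
#' decrease of at least 6.64 (P < 0.01) admits a covariate in the forward
#' phase; a covariate is retained in the backward phase only if its removal
#' increases the OFV by more than 10.83 (P < 0.001).
#'
#' @return Named vector \code{c(forward = 6.64, backward = 10.83)}.
#' @export
lrt_thresholds <- function() c(forward = 6.64, backward = 10.83)

# canonical tie-break order for equal OFV drops
CANONICAL_COVS <- c("egfr", "bw", "blm", "tbil", "alb")

candidate_rank <- function(cov) {
  r <- match(cov, CANONICAL_COVS)
  ifelse(is.na(r), length(CANONICAL_COVS) + rank(cov, ties.method = "min"),
         r)
}

#' Candidate covariate for the stepwise search
#'
#' @param cov Lower-case covariate name (matching an upper-case dataset
#'   column).
#' @param param Target parameter, "cl" or "vc".
#' @param form "power" (continuous, median-standardized) or "exponential"
#'   (binary indicator).
#' @param group Optional label; candidates sharing a group are mutually
#'   exclusive (collinear alternatives such as body weight vs body surface
#'   area), and at most one member can enter the model.
#' @return One-row data.frame.
#' @export
candidate_covariate <- function(cov, param = c("cl", "vc"),
                                form = c("power", "exponential"),
                                group = NA_character_) {
  data.frame(cov = cov, param = match.arg(param), form = match.arg(form),
             group = group, stringsAsFactors = FALSE)
}

add_covariate <- function(spec, cand) {
  cv <- rbind(spec$covariates,
              data.frame(param = cand$param, cov = cand$cov,
                         form = cand$form, init = 0, group = cand$group,
                         stringsAsFactors = FALSE))
  spec$covariates <- cv
  spec
}

drop_covariate <- function(spec, param, cov) {
  cv <- spec$covariates
  spec$covariates <- cv[!(cv$param == param & cv$cov == cov), ,
                        drop = FALSE]
  spec
}

step_record <- function(phase, action, ofv_before, ofv_after, decision) {
  data.frame(phase = phase, action = action, ofv_before = ofv_before,
             ofv_after = ofv_after, delta = ofv_after - ofv_before,
             decision = decision, stringsAsFactors = FALSE)
}

fit_or_fail <- function(spec, data, init, control) {
  tryCatch(nlme_fit(spec, data, init = init, control = control),
           error = function(e) NULL)
}

#' One forward-inclusion step
#'
#' Fits the current model extended by each eligible candidate (warm-started
#' from the current estimates) and accepts the candidate with the largest
#' OFV decrease, provided the decrease reaches the forward threshold 6.64.
#' Candidates whose mutually-exclusive group is already represented in the
#' model are skipped; a failed candidate fit is recorded and the search
#' continues.  Ties in the OFV drop (within 1e-6) are broken by the
#' canonical covariate order (eGFR, BW, BLM, TBIL, ALB, then
#' alphabetically).
#'
#' @param spec Current \code{\link{model_spec}}.
#' @param candidates data.frame of \code{\link{candidate_covariate}} rows.
#' @param data Event records or simulated cohort.
#' @param fit Optional current fit (re-fitted when NULL).
#' @param control \code{\link{fit_control}}.
#' @return list(accepted = one-row candidate or NULL, records, spec, fit).
#' @export
forward_step <- function(spec, candidates, data, fit = NULL,
                         control = fit_control(compute_se = FALSE)) {
  if (is.null(fit)) fit <- nlme_fit(spec, data, control = control)
  records <- list()
  if (is.null(candidates) || nrow(candidates) == 0)
    return(list(accepted = NULL, records = empty_records(), spec = spec,
                fit = fit))
  cv <- spec$covariates
  in_model <- paste(cv$param, cv$cov)
  groups_in <- stats::na.omit(unique(cv$group))
  trial <- list()
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    key <- paste(cand$param, cand$cov)
    if (key %in% in_model) next
    if (!is.na(cand$group) && cand$group %in% groups_in) next
    sp2 <- add_covariate(spec, cand)
    f2 <- fit_or_fail(sp2, data, init = fit$estimates, control = control)
    act <- paste0("add ", cand$cov, " on ", cand$param)
    if (is.null(f2) || !is.finite(f2$ofv)) {
      records[[length(records) + 1L]] <-
        step_record("forward", act, fit$ofv, NA_real_, "failed")
      next
    }
    records[[length(records) + 1L]] <-
      step_record("forward", act, fit$ofv, f2$ofv,
                  if (f2$ofv - fit$ofv <= -lrt_thresholds()[["forward"]])
                    "eligible" else "reject")
    trial[[length(trial) + 1L]] <- list(cand = cand, fit = f2, spec = sp2)
  }
  records <- if (length(records)) do.call(rbind, records)
             else empty_records()
  drops <- vapply(trial, function(tr) fit$ofv - tr$fit$ofv, numeric(1))
  ok <- which(drops >= lrt_thresholds()[["forward"]])
  if (!length(ok))
    return(list(accepted = NULL, records = records, spec = spec,
                fit = fit))
  best_drop <- max(drops[ok])
  tied <- ok[drops[ok] >= best_drop - 1e-6]
  covs <- vapply(trial[tied], function(tr) tr$cand$cov, character(1))
  pick <- tied[order(candidate_rank(covs))][1]
  records$decision[records$decision == "eligible"] <- "reject"
  act <- paste0("add ", trial[[pick]]$cand$cov, " on ",
                trial[[pick]]$cand$param)
  records$decision[records$action == act] <- "accept"
  list(accepted = trial[[pick]]$cand, records = records,
       spec = trial[[pick]]$spec, fit = trial[[pick]]$fit)
}

empty_records <- function() {
  data.frame(phase = character(0), action = character(0),
             ofv_before = numeric(0), ofv_after = numeric(0),
             delta = numeric(0), decision = character(0),
             stringsAsFactors = FALSE)
}

#' One backward-elimination step
#'
#' Refits the model with each included covariate removed.  A covariate is
#' retained only if its removal increases the OFV by more than 10.83;
#' otherwise the least-supported covariate (smallest increase) is removed.
#'
#' @inheritParams forward_step
#' @return list(removed = one-row covariate or NULL, records, spec, fit).
#' @export
backward_step <- function(spec, data, fit = NULL,
                          control = fit_control(compute_se = FALSE)) {
  if (is.null(fit)) fit <- nlme_fit(spec, data, control = control)
  cv <- spec$covariates
  if (!nrow(cv))
    return(list(removed = NULL, records = empty_records(), spec = spec,
                fit = fit))
  records <- list()
  trial <- list()
  for (i in seq_len(nrow(cv))) {
    sp2 <- drop_covariate(spec, cv$param[i], cv$cov[i])
    f2 <- fit_or_fail(sp2, data, init = fit$estimates, control = control)
    act <- paste0("remove ", cv$cov[i], " on ", cv$param[i])
    if (is.null(f2) || !is.finite(f2$ofv)) {
      records[[length(records) + 1L]] <-
        step_record("backward", act, fit$ofv, NA_real_, "failed")
      next
    }
    kept <- f2$ofv - fit$ofv > lrt_thresholds()[["backward"]]
    records[[length(records) + 1L]] <-
      step_record("backward", act, fit$ofv, f2$ofv,
                  if (kept) "retain" else "removable")
    trial[[length(trial) + 1L]] <- list(i = i, fit = f2, spec = sp2)
  }
  records <- do.call(rbind, records)
  rises <- vapply(trial, function(tr) tr$fit$ofv - fit$ofv, numeric(1))
  rem <- which(rises <= lrt_thresholds()[["backward"]])
  if (!length(rem))
    return(list(removed = NULL, records = records, spec = spec,
                fit = fit))
  least <- rem[which.min(rises[rem])]
  i <- trial[[least]]$i
  act <- paste0("remove ", cv$cov[i], " on ", cv$param[i])
  records$decision[records$decision == "removable"] <- "retain"
  records$decision[records$action == act] <- "remove"
  list(removed = cv[i, c("param", "cov")], records = records,
       spec = trial[[least]]$spec, fit = trial[[least]]$fit)
}

#' Full stepwise covariate search
#'
#' Alternates forward-inclusion steps until no candidate reaches the 6.64
#' threshold, then backward-elimination steps until every remaining
#' covariate's removal raises the OFV by more than 10.83.  The returned
#' trail is a complete ordered audit of every trial fit (model number,
#' action, OFV before/after, delta, decision).
#'
#' @inheritParams forward_step
#' @return list(spec = final \code{\link{model_spec}}, fit = final fit,
#'   trail = data.frame audit).
#' @export
run_stepwise <- function(spec, candidates, data,
                         control = fit_control(compute_se = FALSE)) {
  fit <- nlme_fit(spec, data, control = control)
  trail <- list()
  model_no <- 1L
  trail[[1]] <- data.frame(model = 1L, phase = "base",
                           action = "base model", ofv_before = NA_real_,
                           ofv_after = fit$ofv, delta = NA_real_,
                           decision = "start", stringsAsFactors = FALSE)
  repeat {
    st <- forward_step(spec, candidates, data, fit = fit,
                       control = control)
    if (nrow(st$records)) {
      st$records$model <- model_no + seq_len(nrow(st$records))
      model_no <- model_no + nrow(st$records)
      trail[[length(trail) + 1L]] <- st$records
    }
    if (is.null(st$accepted)) break
    spec <- st$spec
    fit <- st$fit
  }
  repeat {
    st <- backward_step(spec, data, fit = fit, control = control)
    if (nrow(st$records)) {
      st$records$model <- model_no + seq_len(nrow(st$records))
      model_no <- model_no + nrow(st$records)
      trail[[length(trail) + 1L]] <- st$records
    }
    if (is.null(st$removed)) break
    spec <- st$spec
    fit <- st$fit
  }
  trail <- do.call(rbind, lapply(trail, function(d)
    d[, c("model", "phase", "action", "ofv_before", "ofv_after", "delta",
          "decision")]))
  rownames(trail) <- NULL
  list(spec = spec, fit = fit, trail = trail)
}

#' Write a stepwise trail to CSV
#'
#' @param trail The \code{trail} component of \code{\link{run_stepwise}}.
#' @param path Destination path.
#' @export
write_stepwise_csv <- function(trail, path) {
  utils::write.csv(trail, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
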