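# Counterfactual exposure-free survivor curve and cumulative effect ratios.

# per-subject log blip sum  sum_j A_j v_j(t)' psi_j  at a single time t,
# vectorised over subjects (handles irregular grids).
.logblip_all <- function(d, pm, t) {
  out <- numeric(d$n)
  Sf <- d$Sfull
  K <- d$K
  for (j in 0:K) {
    contrib <- numeric(d$n)
    for (m in j:K) {
      coefm <- pm[j + 1L, m + 1L]
      if (is.na(coefm) || coefm == 0) next
      len <- pmin(t, Sf[, m + 2L]) - Sf[, m + 1L]
      len[len < 0] <- 0
      contrib <- contrib + coefm * len
    }
    out <- out + d$A[, j + 1L] * contrib
  }
  out
}

#' Counterfactual exposure-free survivor curve
#'
#' Estimates \eqn{P\{T(0) \ge t\}}, the survival function that would have
#' applied had every exposure been set to zero, by the plug-in average
#' \deqn{n^{-1} \sum_i R_i(t) \prod_{j=0}^{K}
#'       \exp\{A_{ji} v_j(t)^\top \hat\psi_j\},}
#' optionally with the at-risk indicator inversely weighted by an estimated
#' censoring survival probability.
#'
#' Because the model is additive on the hazard scale the estimate is not
#' constrained to be monotone or bounded by one; violations are counted and
#' reported via attributes rather than silently clipped.
#'
#' @param data An `sncstm_data` object.
#' @param psi A `psi_matrix` of fitted (or true) blip parameters; all
#'   upper-triangular entries must be present.
#' @param times Evaluation grid; defaults to the observed event times
#'   pooled with a uniform grid of `grid_points` points over
#'   `[0, admin_end]`. Times beyond the administrative end are dropped with
#'   a warning.
#' @param censor_weights Optional `censoring_weight_fit` (see
#'   [fit_censoring_weights()]); `TRUE` fits one with defaults.
#' @param grid_points Size of the uniform part of the default grid.
#' @return A data frame of class `survivor_curve` with columns `time` and
#'   `estimate`, and attributes `n_above_one` and `n_nonmonotone`.
#' @export
counterfactual_survival <- function(data, psi, times = NULL,
                                    censor_weights = NULL,
                                    grid_points = 200L) {
  d <- as_sncstm_data(data)
  pm <- psi_values(psi)
  if (anyNA(pm[upper.tri(pm, diag = TRUE)])) {
    stop("psi has missing entries; a complete parameter set is required",
         call. = FALSE)
  }
  aend <- max(d$admin_end)
  if (is.null(times)) {
    times <- sort(unique(c(0, d$time[d$event == 1L],
                           seq(0, aend, length.out = grid_points))))
  } else {
    drop <- times > aend
    if (any(drop)) {
      warning(sprintf("%d evaluation time(s) beyond the administrative end dropped",
                      sum(drop)), call. = FALSE)
      times <- times[!drop]
    }
    times <- sort(unique(times))
  }
  cw <- NULL
  if (isTRUE(censor_weights)) cw <- fit_censoring_weights(d)
  else if (inherits(censor_weights, "censoring_weight_fit")) cw <- censor_weights
  est <- vapply(times, function(t) {
    R <- as.numeric(d$time >= t)
    w <- exp(.logblip_all(d, pm, t))
    if (!is.null(cw)) {
      Lam <- numeric(d$n)
      for (m in 0:d$K) {
        len <- pmin(t, d$Sfull[, m + 2L]) - d$Sfull[, m + 1L]
        len[len < 0] <- 0
        Lam <- Lam + cw$lambda[, m + 1L] * len
      }
      w <- w * exp(pmin(Lam, cw$cap))
    }
    mean(R * w)
  }, numeric(1))
  out <- data.frame(time = times, estimate = est)
  class(out) <- c("survivor_curve", "data.frame")
  attr(out, "n_above_one") <- sum(est > 1 + 1e-12)
  attr(out, "n_nonmonotone") <- sum(diff(est) > 1e-12)
  out
}

#' @export
print.survivor_curve <- function(x, ...) {
  cat(sprintf("<survivor_curve: %d time points, S(0)=%.3f, S(max)=%.3f>\n",
              nrow(x), x$estimate[1], x$estimate[nrow(x)]))
  if (attr(x, "n_above_one") > 0) {
    cat(sprintf("  note: %d estimate(s) exceed 1 (additive-hazard model limitation)\n",
                attr(x, "n_above_one")))
  }
  if (attr(x, "n_nonmonotone") > 0) {
    cat(sprintf("  note: %d increasing step(s); the curve is not forced monotone\n",
                attr(x, "n_nonmonotone")))
  }
  invisible(x)
}

#' Cumulative effect ratio over a survival horizon
#'
#' With annual visits, \eqn{\exp\{-\sum_{l=k}^{k+m-1} \psi_k(l)\}} is the
#' multiplicative effect of one unit of exposure at visit \eqn{k} on the
#' probability of surviving at least \eqn{m} further years, given survival
#' to visit \eqn{k} (later exposures held at zero). Ratios multiply across
#' horizons: `ratio(k, m) = ratio(k, m-1) * exp(-psi_k(k+m-1))`.
#'
#' @param psi A `psi_matrix`, or a per-lag numeric vector
#'   \eqn{(\psi(0), \dots)} from a constrained fit. With effect
#'   modification, a list of coefficient vectors per lag may be given
#'   together with matching `Z`.
#' @param k Visit index (default 0).
#' @param m Horizon in visits (\eqn{m \ge 1}).
#' @param Z Optional list of effect-modifier vectors \eqn{Z_k(l)}
#'   (intercept-first) matching a list-valued `psi`.
#' @return A positive number.
#' @export
cumulative_effect_ratio <- function(psi, k = 0L, m = 1L, Z = NULL) {
  stopifnot(m >= 1L)
  if (is.list(psi)) {
    if (is.null(Z)) Z <- lapply(psi, function(p) c(1, rep(0, length(p) - 1L)))
    stopifnot(length(Z) >= m)
    tot <- sum(vapply(seq_len(m), function(i) sum(psi[[i]] * Z[[i]]), numeric(1)))
    return(exp(-tot))
  }
  if (inherits(psi, "psi_matrix") || is.matrix(psi)) {
    ls <- k:(k + m - 1L)
    vals <- unclass(psi)[k + 1L, ls + 1L]
  } else {
    vals <- psi[seq_len(m)]
  }
  if (anyNA(vals)) stop("psi entries for lags 0..m-1 are required", call. = FALSE)
  exp(-sum(vals))
}

#' Crude person-time death rates and one-year survival ratio
#'
#' A descriptive (confounding-ignorant) summary of the kind used to motivate
#' a causal analysis: death rates per person-year in the treated and
#' untreated person-time, and the ratio of the implied one-year survival
#' probabilities \eqn{(1 - r_1)/(1 - r_0)}.
#'
#' @param deaths_treated,py_treated Deaths and person-years while treated.
#' @param deaths_untreated,py_untreated Deaths and person-years while
#'   untreated.
#' @return List with `rate_treated`, `rate_untreated` and
#'   `one_year_survival_ratio`.
#' @export
#' @examples
#' crude_rate_summary(74, 3930, 63, 8450)
crude_rate_summary <- function(deaths_treated, py_treated,
                               deaths_untreated, py_untreated) {
  r1 <- deaths_treated / py_treated
  r0 <- deaths_untreated / py_untreated
  list(
    rate_treated = r1,
    rate_untreated = r0,
    one_year_survival_ratio = (1 - r1) / (1 - r0)
  )
}
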