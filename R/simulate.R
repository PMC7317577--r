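# Known-truth data-generating process: Gaussian confounders and exposures
# with feedback, a piecewise-constant additive hazard, optional exponential
# random censoring, and regular or irregular visit grids.

#' Define a simulation scenario
#'
#' The default scenario has `K = 3` follow-up visits after baseline and two
#' time-varying confounders generated as
#' \eqn{L_0 \sim N(0, \Sigma)},
#' \eqn{A_0 \sim N(3 + (0.2, 0.1)^\top L_0, 0.9^2)},
#' \eqn{L_k \sim N(\Omega L_{k-1} + (0.1, 0.05) A_{k-1}, \Sigma)} and
#' \eqn{A_k \sim N(3 + (0.1, 0.05)^\top L_k, 0.7^2)} for \eqn{k \ge 1}, with
#' \eqn{\Sigma = [0.5, 0.2; 0.2, 0.5]} and \eqn{\Omega = [0.2, 0.2; 0.1, 0.1]}.
#' The hazard between visits \eqn{k} and \eqn{k+1} is constant at
#' \deqn{0.34 + (0.03, 0.03)^\top L_k - 0.04 A_k - 0.0145 A_{k-1}
#'       - 0.0055 A_{k-2} - 0.00245 A_{k-3},}
#' lagged terms entering only once available. Follow-up is administratively
#' censored at time 4; random censoring, when enabled, is exponential with
#' mean 5, independent of everything else. Visits are at times
#' \eqn{0, 1, \dots, K} in the regular regime; in the irregular regime the
#' inter-visit gaps are i.i.d. uniform on `irregular_gap` (drawn at
#' baseline, independently of the covariates).
#'
#' @param n Number of subjects.
#' @param K Number of follow-up visits (visits `0:K`).
#' @param Sigma Confounder innovation covariance (p x p, positive definite).
#' @param Omega Confounder autoregression matrix (p x p).
#' @param a0_intercept,a0_loadings,a0_sd Baseline exposure model:
#'   \eqn{A_0 \sim N(}`a0_intercept` + `a0_loadings`\eqn{^\top L_0},
#'   `a0_sd`\eqn{^2)}.
#' @param a_intercept,a_loadings,a_sd Follow-up exposure model (`k >= 1`).
#' @param L_exposure_loadings Effect of \eqn{A_{k-1}} on the mean of
#'   \eqn{L_k}.
#' @param hazard_intercept,hazard_L Baseline-hazard intercept and confounder
#'   loadings.
#' @param hazard_lags Exposure lag coefficients \eqn{d_0, \dots, d_K} in the
#'   hazard (lag \eqn{m} multiplies \eqn{A_{k-m}}).
#' @param visit_regime `"regular"` or `"irregular"`.
#' @param irregular_gap Range of the uniform inter-visit gaps (before
#'   `time_scale` is applied).
#' @param censoring `"none"` or `"exponential"`.
#' @param censoring_mean Mean of the exponential random censoring time.
#' @param admin_end Administrative censoring time.
#' @param time_scale Multiplier applied to all visit gaps (use 1/4 together
#'   with `admin_end = 1` for the short-follow-up variant). The hazard
#'   coefficients are per unit time and are not rescaled.
#' @param a0_nl,haz0_nl Optional model-misspecification hooks used by the
#'   double-robustness scenarios: coefficients on the centred square of the
#'   first baseline confounder, added to the mean of \eqn{A_0} and to the
#'   hazard of the first interval, respectively.
#' @param seed Default seed used by [simulate_dataset()] when no seed is
#'   passed explicitly.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n = 1000L,
                          K = 3L,
                          Sigma = matrix(c(0.5, 0.2, 0.2, 0.5), 2L),
                          Omega = matrix(c(0.2, 0.1, 0.2, 0.1), 2L),
                          a0_intercept = 3, a0_loadings = c(0.2, 0.1), a0_sd = 0.9,
                          a_intercept = 3, a_loadings = c(0.1, 0.05), a_sd = 0.7,
                          L_exposure_loadings = c(0.1, 0.05),
                          hazard_intercept = 0.34,
                          hazard_L = c(0.03, 0.03),
                          hazard_lags = c(-0.04, -0.0145, -0.0055, -0.00245),
                          visit_regime = c("regular", "irregular"),
                          irregular_gap = c(0.5, 1.5),
                          censoring = c("none", "exponential"),
                          censoring_mean = 5,
                          admin_end = 4,
                          time_scale = 1,
                          a0_nl = 0,
                          haz0_nl = 0,
                          seed = NULL) {
  visit_regime <- match.arg(visit_regime)
  censoring <- match.arg(censoring)
  p <- nrow(Sigma)
  stopifnot(isSymmetric(unname(Sigma)), nrow(Omega) == p, ncol(Omega) == p,
            length(a0_loadings) == p, length(a_loadings) == p,
            length(L_exposure_loadings) == p, length(hazard_L) == p,
            admin_end > 0, hazard_intercept > 0, time_scale > 0)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("Sigma must be positive definite", call. = FALSE)
  if (length(hazard_lags) < K + 1L) {
    hazard_lags <- c(hazard_lags, rep(0, K + 1L - length(hazard_lags)))
  }
  structure(
    list(
      n = as.integer(n), K = as.integer(K), p = p,
      Sigma = Sigma, Omega = Omega,
      a0_intercept = a0_intercept, a0_loadings = a0_loadings, a0_sd = a0_sd,
      a_intercept = a_intercept, a_loadings = a_loadings, a_sd = a_sd,
      L_exposure_loadings = L_exposure_loadings,
      hazard_intercept = hazard_intercept, hazard_L = hazard_L,
      hazard_lags = hazard_lags[seq_len(K + 1L)],
      visit_regime = visit_regime, irregular_gap = irregular_gap,
      censoring = censoring, censoring_mean = censoring_mean,
      admin_end = admin_end, time_scale = time_scale,
      a0_nl = a0_nl, haz0_nl = haz0_nl,
      seed = seed
    ),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec: n=%d, K=%d, %s visits, censoring=%s, admin end %g>\n",
    x$n, x$K, x$visit_regime, x$censoring, x$admin_end
  ))
  invisible(x)
}

#' Simulate a dataset from a scenario
#'
#' Failure times are drawn exactly by exponential inversion within each
#' inter-visit interval (the hazard is constant there given the covariates);
#' no time discretisation is involved. Covariates at visits the subject does
#' not reach are zero, matching the convention enforced by
#' [validate_dataset()]. In the rare event that the linear hazard predictor
#' is negative it is truncated at zero and the number of truncations is
#' recorded in the `"hazard_truncations"` attribute of the result.
#'
#' Randomness is laid out per subject: each subject consumes a fixed block
#' of the random stream, so enlarging `n` extends the dataset without
#' changing the subjects already drawn.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return An `sncstm_data` object with attributes `"seed"` and
#'   `"hazard_truncations"`.
#' @export
simulate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(seed)) stop("a seed is required (in the spec or as an argument)",
                          call. = FALSE)
  n <- spec$n; K <- spec$K; p <- spec$p
  n_normal <- (K + 1L) * p + (K + 1L)          # L innovations, A innovations
  n_other <- (K + 1L) + 1L + K                 # interval exponentials, censor, gaps
  n_draws <- n_normal + n_other

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  U <- matrix(stats::runif(n_draws * n), nrow = n_draws)

  row <- 0L
  take <- function(m) {
    out <- U[row + seq_len(m), , drop = FALSE]
    row <<- row + m
    out
  }
  ZL <- stats::qnorm(take((K + 1L) * p))       # (K+1)p x n
  ZA <- stats::qnorm(take(K + 1L))             # (K+1) x n
  Eint <- -log(take(K + 1L))                   # unit exponentials per interval
  Ucens <- drop(take(1L))
  Ugap <- take(K)                              # K x n (unused when regular)

  # visit times
  if (spec$visit_regime == "regular") {
    S <- matrix(rep(spec$time_scale * (0:K), each = n), n, K + 1L)
  } else {
    gaps <- spec$time_scale *
      (spec$irregular_gap[1] + diff(spec$irregular_gap) * t(Ugap))   # n x K
    S <- if (K == 1L) cbind(0, gaps) else cbind(0, t(apply(gaps, 1L, cumsum)))
  }
  Sfull <- cbind(S, spec$admin_end)

  cholS <- chol(spec$Sigma)
  A <- matrix(0, n, K + 1L)
  L <- array(0, dim = c(n, p, K + 1L))
  haz <- matrix(0, n, K + 1L)
  n_trunc <- 0L
  sq1 <- NULL                                   # centred L01^2, for DR hooks
  for (k in 0:K) {
    Zk <- t(ZL[k * p + seq_len(p), , drop = FALSE]) %*% cholS   # n x p
    if (k == 0L) {
      Lk <- Zk
      mu <- spec$a0_intercept + drop(Lk %*% spec$a0_loadings)
      sq1 <- Lk[, 1L]^2 - spec$Sigma[1L, 1L]
      if (spec$a0_nl != 0) mu <- mu + spec$a0_nl * sq1
      Ak <- mu + spec$a0_sd * ZA[1L, ]
    } else {
      Lk <- L[, , k] %*% t(spec$Omega) +
        outer(A[, k], spec$L_exposure_loadings) + Zk
      Ak <- spec$a_intercept + drop(Lk %*% spec$a_loadings) +
        spec$a_sd * ZA[k + 1L, ]
    }
    L[, , k + 1L] <- Lk
    A[, k + 1L] <- Ak
    h <- spec$hazard_intercept + drop(Lk %*% spec$hazard_L)
    for (m in 0:min(k, K)) h <- h + spec$hazard_lags[m + 1L] * A[, k - m + 1L]
    if (k == 0L && spec$haz0_nl != 0) h <- h + spec$haz0_nl * sq1
    n_trunc <- n_trunc + sum(h < 0)
    haz[, k + 1L] <- pmax(h, 0)
  }

  # exact within-interval exponential inversion
  Tfail <- rep(Inf, n)
  for (k in 0:K) {
    len <- Sfull[, k + 2L] - Sfull[, k + 1L]
    hk <- haz[, k + 1L]
    hit <- is.infinite(Tfail) & (Eint[k + 1L, ] < hk * len)
    Tfail[hit] <- Sfull[hit, k + 1L] + Eint[k + 1L, hit] / hk[hit]
  }

  Cens <- if (spec$censoring == "exponential") {
    -spec$censoring_mean * log(Ucens)
  } else {
    rep(Inf, n)
  }
  time <- pmin(Tfail, Cens, spec$admin_end)
  event <- as.integer(is.finite(Tfail) & Tfail < Cens & Tfail < spec$admin_end)

  # zero-fill visits not reached
  for (k in 0:K) {
    gone <- S[, k + 1L] >= time
    if (any(gone)) {
      A[gone, k + 1L] <- 0
      L[gone, , k + 1L] <- 0
    }
  }

  out <- new_sncstm_data(
    ids = as.character(seq_len(n)),
    A = A, L = L, S = S,
    admin_end = rep(spec$admin_end, n),
    time = time, event = event
  )
  attr(out, "seed") <- as.integer(seed %% .Machine$integer.max)
  attr(out, "hazard_truncations") <- n_trunc
  out
}

#' True blip parameters of a scenario
#'
#' For the Gaussian linear data-generating process the blip parameters are
#' available in closed form: the same-interval effect equals the hazard's
#' lag-0 exposure coefficient, and the lag-\eqn{m} effect (\eqn{m \ge 1})
#' equals the lag-\eqn{m} hazard coefficient plus the confounder-mediated
#' path \eqn{c_L^\top \Omega^{m-1} c_A}, where \eqn{c_L} are the hazard's
#' confounder loadings and \eqn{c_A} is the effect of the previous exposure
#' on the confounder mean. (Mediation through later exposures is removed by
#' the blip's definition; mediation through later confounders is not.) With
#' the default coefficients this gives
#' \eqn{\psi(0) = -0.04}, \eqn{\psi(1) = -0.01},
#' \eqn{\psi(2) = -0.00415} and \eqn{\psi(3) = -0.002045}; effects are
#' common across visits, so the constraint
#' \eqn{\psi_k(k+m) = \psi_{k'}(k'+m)} holds.
#'
#' @param spec A [scenario_spec()].
#' @param allow_partial If the scenario carries a baseline-hazard
#'   perturbation (`haz0_nl != 0`), only \eqn{\psi_0(0)} is exactly the
#'   stated value; set `allow_partial = TRUE` to obtain the matrix anyway.
#' @return A `psi_matrix`.
#' @export
true_psi <- function(spec, allow_partial = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (spec$haz0_nl != 0 && !allow_partial) {
    stop("truth beyond psi_0(0) is not derivable when the baseline hazard is ",
         "perturbed; use allow_partial = TRUE for the unperturbed values",
         call. = FALSE)
  }
  K <- spec$K
  lags <- numeric(K + 1L)
  lags[1L] <- spec$hazard_lags[1L]
  Om <- diag(spec$p)
  for (m in seq_len(K)) {
    lags[m + 1L] <- spec$hazard_lags[m + 1L] +
      drop(crossprod(spec$hazard_L, Om %*% spec$L_exposure_loadings))
    Om <- Om %*% spec$Omega
  }
  psi_matrix(K, lags)
}

#' Define a double-robustness scenario
#'
#' Produces a variant of a base scenario in which exactly one side of the
#' nuisance specification used by the G-estimators is deliberately wrong for
#' the first-interval parameter \eqn{\psi_0(0)}:
#' \describe{
#'   \item{`"A"`}{the exposure model is wrong: the generator adds a centred
#'     quadratic confounder term to the mean of \eqn{A_0}, which the default
#'     linear design \eqn{H_0 = (1, L_0)} omits; the counterfactual hazard
#'     of the first interval remains linear in \eqn{H_0}, so the
#'     outcome-model side holds.}
#'   \item{`"B"`}{the outcome side is wrong: the generator adds a centred
#'     quadratic confounder term to the first-interval hazard, while the
#'     exposure models remain exactly linear, so the exposure side holds.}
#'   \item{`"both"`}{both perturbations at once — the negative control, under
#'     which no consistency guarantee applies.}
#'   \item{`"none"`}{the unmodified base scenario.}
#' }
#' In every arm the true \eqn{\psi_0(0)} equals the base scenario's value
#' (the exposure coefficients of the hazard are untouched).
#'
#' @param misspecified Which side is wrong.
#' @param base Base [scenario_spec()].
#' @param a_strength Coefficient of the quadratic term in the exposure mean.
#' @param b_strength Coefficient of the quadratic term in the hazard.
#' @return A `dr_scenario_spec` object (a `scenario_spec` plus metadata).
#' @export
dr_scenario_spec <- function(misspecified = c("A", "B", "both", "none"),
                             base = scenario_spec(),
                             a_strength = 0.3,
                             b_strength = 0.1) {
  misspecified <- match.arg(misspecified)
  spec <- base
  if (misspecified %in% c("A", "both")) spec$a0_nl <- a_strength
  if (misspecified %in% c("B", "both")) spec$haz0_nl <- b_strength
  spec$misspecified <- misspecified
  class(spec) <- c("dr_scenario_spec", class(base))
  spec
}

#' Simulate a dataset from a double-robustness scenario
#'
#' @param spec A [dr_scenario_spec()].
#' @param seed Integer seed.
#' @return An `sncstm_data` object; the attribute `"misspecified"` records
#'   which nuisance side the estimator's default specification gets wrong.
#' @export
simulate_dr_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "dr_scenario_spec"))
  out <- simulate_dataset(spec, seed = seed)
  attr(out, "misspecified") <- spec$misspecified
  out
}
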