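# Exposure-model ("Model A_k") machinery: pseudo-individual expansion,
# shifted-intercept GLM fits, dispersion, working models for stabilised
# weights, and inverse-probability-of-censoring weights.

#' Expand a dataset into pseudo-individuals for one interval
#'
#' For each of `grid_size` equally spaced times \eqn{t} over
#' \eqn{[S_l, S_{l+1}]} (both endpoints included), every subject still at
#' risk (\eqn{T \ge t}) contributes a copy ("pseudo-individual") carrying
#' the grid time as a covariate \eqn{Q = t}. Fitting a GLM of the exposure
#' on \eqn{(H_k, Q - S_l)} over these rows turns the survival condition
#' into an intercept shift that is linear in time.
#'
#' With irregular visit grids the expansion is per subject, over that
#' subject's own interval \eqn{[S_{l,i}, S_{l+1,i}]}.
#'
#' @param data An `sncstm_data` object (or coercible via
#'   [as_sncstm_data()]).
#' @param l Interval index (`0 <= l <= K`).
#' @param grid_size Number of grid times (default 10, minimum 2).
#' @return A data frame with columns `subject` (row index into `data`),
#'   `id`, `Q` (the grid time) and `s` (`Q - S_l`), flagged with attribute
#'   `"empty"` when no subject is at risk at \eqn{S_l}.
#' @export
expand_pseudo <- function(data, l, grid_size = 10L) {
  d <- as_sncstm_data(data)
  stopifnot(l >= 0L, l <= d$K, grid_size >= 2L)
  gr <- .grid_rows(d, l, as.integer(grid_size))
  out <- data.frame(
    subject = gr$idx,
    id = d$id[gr$idx],
    Q = d$Sfull[gr$idx, l + 1L] + gr$s,
    s = gr$s,
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) {
    warning(sprintf("no subject at risk at the start of interval %d", l),
            call. = FALSE)
    attr(out, "empty") <- TRUE
  }
  out
}

#' Fit the shifted-intercept exposure GLM for a visit pair
#'
#' Fits \eqn{g\{E(A_k \mid \bar A_{k-1}, \bar L_k, Q)\} =
#' \alpha_{k0}^\top H_k + \alpha_k(l) (Q - S_l)} to the pseudo-individuals
#' of interval \eqn{l}, with blip weights \eqn{w_k(Q)} built from previously
#' estimated parameters (`psi`). The slope \eqn{\alpha_k(l)} estimates
#' \eqn{-\psi_k(l)\phi_k}, and the fitted mean function
#' \eqn{\hat e_k(l)(\cdot, t)} is the exposure nuisance used by the
#' G-estimators.
#'
#' @inheritParams expand_pseudo
#' @param k Exposure visit index (`k <= l`).
#' @param design A [nuisance_design()].
#' @param config An [estimator_config()].
#' @param psi A `psi_matrix` supplying the entries \eqn{\psi_j(m)}
#'   (\eqn{k < j \le m \le l}) needed by the weights; the all-zero default
#'   gives unit weights, appropriate for \eqn{l = k}.
#' @return An object of class `nuisance_fit` with elements `alpha0`,
#'   `alpha_kl`, `phi`, `predict` (a function `(subject_index, t)` returning
#'   \eqn{\hat e_k(l)}), and `n_pseudo`.
#' @export
fit_shifted_glm <- function(data, k, l, design = nuisance_design(),
                            config = estimator_config(),
                            psi = NULL) {
  d <- as_sncstm_data(data)
  stopifnot(k >= 0L, k <= l, l <= d$K)
  if (is.null(psi)) psi <- psi_matrix(d$K, 0)
  pm <- psi_values(psi)
  H <- check_H(design$H(d, k))
  stab <- if (config$stabilized || config$center_later) .stab_means(d, k, design) else NULL
  cw <- if (config$censoring_weights) {
    .cw_components(fit_censoring_weights(d, design, floor = config$cw_floor), d)
  } else NULL
  nu <- .pair_nuisance(d, k, l, pm, H, design, config, cw = cw, stab = stab)
  if (!isTRUE(nu$ok)) {
    stop(sprintf("degenerate fit for pair (%d,%d): %s", k, l, nu$reason),
         call. = FALSE)
  }
  phi <- .dispersion(d, k, H, design$link)
  Sl <- d$Sfull[, l + 1L]
  linkinv <- if (design$link == "identity") identity else stats::plogis
  eta0 <- nu$eta0
  akl <- nu$akl
  structure(
    list(
      k = k, l = l,
      alpha0 = nu$alpha0, alpha_kl = akl, phi = phi,
      link = design$link,
      predict = function(subject, t) linkinv(eta0[subject] + akl * (t - Sl[subject])),
      e0 = nu$e0, n_pseudo = nu$n_pseudo
    ),
    class = "nuisance_fit"
  )
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat(sprintf(
    "<nuisance_fit (k=%d, l=%d): alpha_k(l)=%.5g, phi=%.5g, %d pseudo rows>\n",
    x$k, x$l, x$alpha_kl, x$phi, x$n_pseudo
  ))
  invisible(x)
}

#' Estimate the exposure-model dispersion \eqn{\phi_k}
#'
#' Fits Model \eqn{A_k} (the GLM of \eqn{A_k} on \eqn{H_k}) to the subjects
#' at risk at visit \eqn{k}. For the identity link the dispersion is the
#' residual sum of squares divided by the residual degrees of freedom; for
#' the logit link it is 1 (canonical binomial dispersion).
#'
#' @inheritParams fit_shifted_glm
#' @return A single positive number.
#' @export
estimate_dispersion <- function(data, k, design = nuisance_design()) {
  d <- as_sncstm_data(data)
  stopifnot(k >= 0L, k <= d$K)
  H <- check_H(design$H(d, k))
  .dispersion(d, k, H, design$link)
}

#' Fit a working model \eqn{C_j(k)} for a later exposure
#'
#' Estimates \eqn{E(A_j \mid \bar A_{k-1}, \bar L_k, T \ge S_j)} by a GLM of
#' \eqn{A_j} on the `C_builder` design over the subjects at risk at visit
#' \eqn{j}. Only stabilised weights use this model; it does not need to be
#' correctly specified for the blip estimators to remain consistent.
#'
#' @inheritParams fit_shifted_glm
#' @param j Later visit index (`j > k`).
#' @return List with `fitted` (length-`n` vector of fitted means) and
#'   `coefficients`.
#' @export
fit_working_C <- function(data, j, k, design = nuisance_design()) {
  d <- as_sncstm_data(data)
  stopifnot(j > k, j <= d$K, k >= 0L)
  sm <- .stab_means(d, k, design)
  list(fitted = sm[[j]], j = j, k = k)
}

#' Estimate inverse-probability-of-censoring weights
#'
#' Fits a piecewise-constant censoring-hazard model: within each
#' inter-visit interval the hazard of (non-administrative) censoring is
#' \eqn{\lambda_{l}(x) = \exp(\beta_l^\top x)} with covariates given by the
#' design's `cw_builder` (default: intercept, current exposure, current
#' confounders), estimated by a Poisson regression of the censoring
#' indicator with the log time at risk in the interval as offset. Estimated
#' censoring survival probabilities \eqn{\hat P(C \ge t)} are products of
#' the interval pieces; weights are their reciprocals, truncated at
#' `1 / floor`.
#'
#' When a dataset contains no non-administrative censoring events the
#' weights are identically 1.
#'
#' @inheritParams fit_shifted_glm
#' @param floor Lower truncation for the censoring survival probability.
#' @return An object of class `censoring_weight_fit` with a
#'   `weight(subject, t)` function and per-interval hazard matrices.
#' @export
fit_censoring_weights <- function(data, design = nuisance_design(),
                                  floor = 0.05) {
  d <- as_sncstm_data(data)
  K <- d$K
  n <- d$n
  lambda <- matrix(0, n, K + 1L)
  censored <- d$event == 0L & d$time < d$admin_end
  for (l in 0:K) {
    Sl <- d$Sfull[, l + 1L]
    Sl1 <- d$Sfull[, l + 2L]
    rs <- which(d$time > Sl)
    if (length(rs) == 0L) next
    y <- as.integer(censored[rs] & d$time[rs] < Sl1[rs])
    if (sum(y) == 0L) next
    pt <- pmin(d$time[rs], Sl1[rs]) - Sl[rs]
    X <- design$cw(d, l)
    if (length(rs) <= ncol(X)) {
      # fall back to the crude interval hazard
      lam <- sum(y) / sum(pt)
      lambda[, l + 1L] <- lam
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(X[rs, , drop = FALSE], y, family = stats::poisson(),
                     offset = log(pt))
    )
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    lambda[, l + 1L] <- exp(drop(X %*% cf))
  }
  gaps <- d$Sfull[, -1L, drop = FALSE] - d$Sfull[, -(K + 2L), drop = FALSE]
  Lambda0 <- matrix(0, n, K + 1L)
  if (K >= 1L) {
    for (l in 1:K) {
      Lambda0[, l + 1L] <- Lambda0[, l] + lambda[, l] * gaps[, l]
    }
  }
  cap <- log(1 / floor)
  truncated <- any(Lambda0 > cap)
  if (truncated) {
    warning("censoring weights truncated at 1/floor", call. = FALSE)
    Lambda0 <- pmin(Lambda0, cap)
  }
  Sfull <- d$Sfull
  wfun <- function(subject, t) {
    # cumulative censoring hazard at t, interval by interval
    Lam <- 0
    for (m in 0:K) {
      len <- max(0, min(t, Sfull[subject, m + 2L]) - Sfull[subject, m + 1L])
      Lam <- Lam + lambda[subject, m + 1L] * len
    }
    exp(min(Lam, cap))
  }
  structure(
    list(lambda = lambda, Lambda0 = Lambda0, cap = cap,
         truncated = truncated, floor = floor, weight = wfun),
    class = "censoring_weight_fit"
  )
}

# interval-linear components consumed by .logw_coefs
.cw_components <- function(cwfit, d) {
  list(lambda = cwfit$lambda, Lambda0 = cwfit$Lambda0)
}
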