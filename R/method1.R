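# Estimator 1: sequential pseudo-individual GLM fits. psi_k(l) is estimated
# as -alpha_k(l) / phi_k, where alpha_k(l) is the time slope of the
# shifted-intercept exposure GLM for interval l, weighted by blip weights
# built from the previously estimated parameters (lags are processed in
# increasing order, so everything a pair needs is available when it is fit).

#' Estimate the SNCSTM by the pseudo-individual GLM method (method 1)
#'
#' For each visit pair \eqn{(k, l)} in order of increasing lag
#' \eqn{m = l - k}, the exposure \eqn{A_k} is regressed on
#' \eqn{(H_k, Q - S_l)} over the pseudo-individuals of interval \eqn{l},
#' with rows weighted by blip weights \eqn{w_k(Q)} (computed from the
#' already-estimated shorter-lag parameters) and, optionally, stabilised
#' and/or censoring weights. The blip parameter is recovered as
#' \eqn{\hat\psi_k(l) = -\hat\alpha_k(l) / \hat\phi_k}.
#'
#' Under the common-lag constraint the pseudo-individual tables of all
#' pairs with the same lag are stacked into one GLM with pair-specific
#' covariate blocks and a shared slope: substituting
#' \eqn{\alpha_k(l) = -\psi(m)\,\phi_k} turns the shared parameter into the
#' coefficient of the covariate \eqn{-\hat\phi_k (Q - S_l)}, and rows are
#' additionally weighted by \eqn{1/\hat\phi_k} so that pairs contribute
#' with inverse-variance weights.
#'
#' If a pair's fit is degenerate (empty risk set, singular design) its entry
#' is left `NA` with a warning, and downstream weights treat it as zero.
#'
#' @param data An `sncstm_data` object or anything [as_sncstm_data()]
#'   accepts.
#' @param design A [nuisance_design()].
#' @param config An [estimator_config()]; `config$constrained` selects the
#'   common-lag fit.
#' @return An object of class `sncstm_fit` with elements `psi` (a
#'   `psi_matrix`), `method`, `constrained`, `lags` (per-lag estimates, for
#'   constrained fits), `phi`, `alpha`, and `diagnostics`.
#' @export
#' @examples
#' spec <- scenario_spec(n = 300, seed = 1)
#' fit <- estimate_method1(simulate_dataset(spec))
#' fit$psi
estimate_method1 <- function(data, design = nuisance_design(),
                             config = estimator_config()) {
  d <- as_sncstm_data(data)
  K <- d$K
  Hs <- lapply(0:K, function(k) check_H(design$H(d, k)))
  phis <- vapply(0:K, function(k) .dispersion(d, k, Hs[[k + 1L]], design$link),
                 numeric(1))
  stabs <- if (config$stabilized || config$center_later) {
    lapply(0:K, function(k) .stab_means(d, k, design))
  } else NULL
  cw <- if (config$censoring_weights) {
    .cw_components(fit_censoring_weights(d, design, floor = config$cw_floor), d)
  } else NULL

  psi <- matrix(NA_real_, K + 1L, K + 1L)
  alpha <- matrix(NA_real_, K + 1L, K + 1L)
  npseudo <- matrix(NA_integer_, K + 1L, K + 1L)
  failures <- character(0)
  lags <- NULL

  if (!config$constrained) {
    for (pr in .pair_order(K, config$max_lag)) {
      k <- pr[["k"]]; l <- pr[["l"]]
      nu <- .pair_nuisance(d, k, l, psi, Hs[[k + 1L]], design, config,
                           cw = cw, stab = if (is.null(stabs)) NULL else stabs[[k + 1L]])
      if (!isTRUE(nu$ok)) {
        warning(sprintf("method 1: pair (%d,%d) skipped (%s)", k, l, nu$reason),
                call. = FALSE)
        failures <- c(failures, sprintf("(%d,%d): %s", k, l, nu$reason))
        next
      }
      alpha[k + 1L, l + 1L] <- nu$akl
      npseudo[k + 1L, l + 1L] <- nu$n_pseudo
      psi[k + 1L, l + 1L] <- -nu$akl / phis[k + 1L]
    }
  } else {
    mx <- if (is.null(config$max_lag)) K else min(config$max_lag, K)
    lags <- rep(NA_real_, mx + 1L)
    for (m in 0:mx) {
      ks <- 0:(K - m)
      qks <- vapply(ks, function(k) ncol(Hs[[k + 1L]]), integer(1))
      offs <- c(0L, cumsum(qks))
      blocks <- vector("list", length(ks))
      for (ii in seq_along(ks)) {
        k <- ks[ii]; l <- k + m
        lw <- .logw_coefs(d, k, l, psi,
                          stab = if (is.null(stabs)) NULL else stabs[[k + 1L]],
                          stabilized = config$stabilized,
                          center_later = config$center_later, cw = cw)
        gr <- .grid_rows(d, l, config$grid_size)
        if (length(gr$idx) == 0L) next
        blocks[[ii]] <- list(
          k = k, idx = gr$idx, s = gr$s,
          w = exp(lw$C0[gr$idx] + lw$bw[gr$idx] * gr$s) / phis[k + 1L],
          y = d$A[gr$idx, k + 1L]
        )
      }
      keep <- !vapply(blocks, is.null, logical(1))
      blocks <- blocks[keep]
      if (length(blocks) == 0L) {
        warning(sprintf("method 1: no data for lag %d", m), call. = FALSE)
        next
      }
      N <- sum(vapply(blocks, function(b) length(b$y), integer(1)))
      X <- matrix(0, N, sum(qks) + 1L)
      y <- numeric(N)
      w <- numeric(N)
      at <- 0L
      for (ii in seq_along(blocks)) {
        b <- blocks[[ii]]
        rows <- at + seq_along(b$y)
        kk <- b$k
        jj <- which(ks == kk)
        X[rows, offs[jj] + seq_len(qks[jj])] <- Hs[[kk + 1L]][b$idx, , drop = FALSE]
        X[rows, sum(qks) + 1L] <- -phis[kk + 1L] * b$s
        y[rows] <- b$y
        w[rows] <- b$w
        at <- at + length(b$y)
      }
      cf <- if (design$link == "identity") {
        .wls(X, y, w)
      } else {
        suppressWarnings(stats::glm.fit(X, y, weights = w,
                                        family = stats::binomial()))$coefficients
      }
      pm_hat <- cf[sum(qks) + 1L]
      if (is.na(pm_hat)) {
        warning(sprintf("method 1: degenerate constrained fit at lag %d", m),
                call. = FALSE)
        failures <- c(failures, sprintf("lag %d: singular pooled design", m))
        next
      }
      lags[m + 1L] <- pm_hat
      for (k in ks) psi[k + 1L, k + m + 1L] <- pm_hat
    }
  }

  new_sncstm_fit(
    psi = psi, K = K, method = "1", constrained = config$constrained,
    lags = lags, phi = phis, alpha = alpha,
    diagnostics = list(n_pseudo = npseudo, failures = failures),
    design = design, config = config, n = d$n
  )
}

#' @rdname estimate_method1
#' @export
estimate_method1_constrained <- function(data, design = nuisance_design(),
                                         config = estimator_config()) {
  config$constrained <- TRUE
  estimate_method1(data, design, config)
}

# common result container -----------------------------------------------

new_sncstm_fit <- function(psi, K, method, constrained, lags = NULL,
                           phi = NULL, alpha = NULL, pieces = NULL,
                           diagnostics = list(), design = NULL, config = NULL,
                           n = NA_integer_) {
  pm <- psi_matrix(K)
  pm[upper.tri(pm, diag = TRUE)] <- psi[upper.tri(psi, diag = TRUE)]
  structure(
    list(psi = pm, method = method, constrained = constrained, lags = lags,
         phi = phi, alpha = alpha, pieces = pieces,
         diagnostics = diagnostics, design = design, config = config, n = n),
    class = "sncstm_fit"
  )
}

#' @export
print.sncstm_fit <- function(x, ...) {
  cat(sprintf(
    "SNCSTM fit (method %s%s, n = %d)\n", x$method,
    if (x$constrained) ", constrained" else "", x$n
  ))
  if (x$constrained && !is.null(x$lags)) {
    cat("Per-lag effects (native scale):\n")
    print(round(stats::setNames(x$lags, paste0("lag", seq_along(x$lags) - 1L)), 5))
  }
  cat("psi estimates (native scale):\n")
  print(round(unclass(x$psi), 5))
  cat("tabulation scale (-10 * psi):\n")
  print(round(table_scale(x$psi), 3))
  invisible(x)
}

#' @export
coef.sncstm_fit <- function(object, ...) {
  psi_flatten(object$psi)
}
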