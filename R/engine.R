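# Internal computational core shared by the three estimators.
#
# Notation used throughout: for a visit pair (k, l) with k <= l, s denotes
# time since the interval start, s = t - S_l. On [S_l, S_{l+1}) the log blip
# weight is linear in s,
#   log w_k(t) = C0_i + bw_i * s,
# with C0 collecting the completed-interval contributions of exposures
# A_{k+1}..A_l and bw = sum_j A_j psi_j(l) the current-interval slope. The
# same bw (possibly with centred exposures) is the drift coefficient of the
# G-estimation equations, and censoring weights fold into (C0, bw) because
# the fitted cumulative censoring hazard is also linear in s within the
# interval.

# weighted least squares via the normal equations (much faster than a QR
# decomposition for the tall thin designs used here); returns NA
# coefficients when the weighted cross-product is singular.
.wls <- function(X, y, w = NULL) {
  Xw <- if (is.null(w)) X else X * w
  A <- crossprod(X, Xw)
  b <- crossprod(Xw, y)
  out <- tryCatch(drop(solve(A, b)), error = function(e) rep(NA_real_, ncol(X)))
  # guard against near-singular systems that solve() lets through
  if (!anyNA(out) && rcond(A) < 1e-12) out[] <- NA_real_
  out
}

# psi entries required by the recursion may be missing when an upstream fit
# was degenerate; they are treated as zero with a warning.
.psi_take <- function(psi, j, m) {
  v <- psi[j + 1L, m + 1L]
  if (is.na(v)) {
    warning(sprintf("psi_%d(%d) unavailable; treating as 0 in weights", j, m),
            call. = FALSE)
    v <- 0
  }
  v
}

.logw_coefs <- function(d, k, l, psi, stab = NULL, stabilized = FALSE,
                        center_later = FALSE, cw = NULL) {
  n <- d$n
  C0 <- numeric(n)
  bw <- numeric(n)
  bdrift <- numeric(n)
  Sf <- d$Sfull
  if (l > k) {
    for (j in (k + 1L):l) {
      Aj <- d$A[, j + 1L]
      Ajc <- if (!is.null(stab)) Aj - stab[[j]] else Aj
      pj <- .psi_take(psi, j, l)
      bw <- bw + (if (stabilized) Ajc else Aj) * pj
      bdrift <- bdrift + (if (center_later) Ajc else Aj) * pj
      if (l - 1L >= j) {
        for (m in j:(l - 1L)) {
          pm <- .psi_take(psi, j, m)
          C0 <- C0 + (if (stabilized) Ajc else Aj) * pm * (Sf[, m + 2L] - Sf[, m + 1L])
        }
      }
    }
  }
  if (!is.null(cw)) {
    C0 <- C0 + cw$Lambda0[, l + 1L]
    bw <- bw + cw$lambda[, l + 1L]
  }
  list(C0 = C0, bw = bw, bdrift = bdrift)
}

# pseudo-individual rows for interval l: grid of `grid_size` equally spaced
# times over [S_l, S_{l+1}] (endpoints included), one row per at-risk subject
# per grid time. Returns subject indices and s = t - S_l values.
.grid_rows <- function(d, l, grid_size) {
  Sl <- d$Sfull[, l + 1L]
  Sl1 <- d$Sfull[, l + 2L]
  fr <- (0:(grid_size - 1L)) / (grid_size - 1L)
  tt <- d$time
  idxs <- vector("list", grid_size)
  svals <- vector("list", grid_size)
  for (g in seq_len(grid_size)) {
    sg <- fr[g] * (Sl1 - Sl)
    sel <- which(tt >= Sl + sg)
    idxs[[g]] <- sel
    svals[[g]] <- sg[sel]
  }
  list(idx = unlist(idxs, use.names = FALSE),
       s = unlist(svals, use.names = FALSE))
}

# Shifted-intercept GLM fit on pseudo-individuals for pair (k, l):
# g{E(A_k | H_k, Q)} = alpha0' H_k + alpha_kl (Q - S_l), rows weighted by
# the blip weights (and censoring weights when supplied).
.pair_nuisance <- function(d, k, l, psi, H, design, config,
                           cw = NULL, stab = NULL) {
  lw <- .logw_coefs(d, k, l, psi, stab = stab,
                    stabilized = config$stabilized,
                    center_later = config$center_later, cw = cw)
  gr <- .grid_rows(d, l, config$grid_size)
  if (length(gr$idx) == 0L) {
    return(list(ok = FALSE, reason = "empty risk set", lw = lw))
  }
  X <- cbind(H[gr$idx, , drop = FALSE], Q = gr$s)
  y <- d$A[gr$idx, k + 1L]
  w <- exp(lw$C0[gr$idx] + lw$bw[gr$idx] * gr$s)
  q <- ncol(H)
  if (length(y) <= q) {
    return(list(ok = FALSE, reason = "risk set smaller than design", lw = lw))
  }
  if (design$link == "identity") {
    cf <- .wls(X, y, w)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(X, y, weights = w, family = stats::binomial())
    )
    cf <- fit$coefficients
    if (!fit$converged) {
      return(list(ok = FALSE, reason = "logit fit did not converge", lw = lw,
                  coef = cf))
    }
  }
  if (anyNA(cf)) {
    return(list(ok = FALSE, reason = "singular pseudo-individual design",
                lw = lw, coef = cf))
  }
  alpha0 <- unname(cf[seq_len(q)])
  akl <- unname(cf[q + 1L])
  eta0 <- drop(H %*% alpha0)             # linear predictor at s = 0
  e0 <- if (design$link == "identity") eta0 else stats::plogis(eta0)
  list(ok = TRUE, coef = cf, alpha0 = alpha0, akl = akl,
       eta0 = eta0, e0 = e0, lw = lw, n_pseudo = length(y))
}

# dispersion of Model A_k: residual variance of the GLM of A_k on H_k among
# subjects at risk at S_k (identity link); 1 for the logit link.
.dispersion <- function(d, k, H, link) {
  if (link == "logit") return(1)
  rs <- which(d$time >= d$Sfull[, k + 1L])
  q <- ncol(H)
  if (length(rs) < q + 1L) {
    stop(sprintf("risk set at visit %d too small to estimate the dispersion", k),
         call. = FALSE)
  }
  fit <- stats::lm.fit(H[rs, , drop = FALSE], d$A[rs, k + 1L])
  sum(fit$residuals^2) / (length(rs) - fit$rank)
}

# fitted means E(A_j | Abar_{k-1}, Lbar_k, T >= S_j) from the working models
# C_j(k), for all j > k; used for stabilised weights and centred drifts.
.stab_means <- function(d, k, design) {
  out <- vector("list", d$K)
  for (j in seq_len(d$K)) {
    if (j <= k) next
    X <- design$C(d, j, k)
    rs <- which(d$time >= d$Sfull[, j + 1L])
    if (length(rs) <= ncol(X)) {
      out[[j]] <- rep(mean(d$A[rs, j + 1L]), d$n)
      next
    }
    if (design$link == "identity") {
      cf <- stats::lm.fit(X[rs, , drop = FALSE], d$A[rs, j + 1L])$coefficients
      cf[is.na(cf)] <- 0
      out[[j]] <- drop(X %*% cf)
    } else {
      fit <- suppressWarnings(stats::glm.fit(X[rs, , drop = FALSE],
                                             d$A[rs, j + 1L],
                                             family = stats::binomial()))
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      out[[j]] <- stats::plogis(drop(X %*% cf))
    }
  }
  out
}

# int_0^u e^{b s} ds and int_0^u s e^{b s} ds, vectorised, with series
# expansions near b = 0 to avoid catastrophic cancellation.
.f1 <- function(b, u) {
  bu <- b * u
  out <- numeric(length(u))
  sm <- abs(bu) < 1e-5
  if (any(sm)) {
    x <- bu[sm]
    out[sm] <- u[sm] * (1 + x / 2 + x^2 / 6 + x^3 / 24)
  }
  if (any(!sm)) out[!sm] <- expm1(bu[!sm]) / b[!sm]
  out
}

.f2 <- function(b, u) {
  bu <- b * u
  out <- numeric(length(u))
  sm <- abs(bu) < 1e-5
  if (any(sm)) {
    x <- bu[sm]
    out[sm] <- u[sm]^2 * (1 / 2 + x / 3 + x^2 / 8 + x^3 / 30)
  }
  if (any(!sm)) {
    bb <- b[!sm]
    uu <- u[!sm]
    out[!sm] <- (uu * exp(bu[!sm]) - expm1(bu[!sm]) / bb) / bb
  }
  out
}

# Gauss-Legendre nodes and weights on [-1, 1] (Golub-Welsch).
.gauss_legendre <- function(m) {
  if (m == 1L) return(list(x = 0, w = 2))
  i <- seq_len(m - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = 2 * e$vectors[1L, ord]^2)
}

# Closed-form solve of the (k, l) estimating equation
#   sum_i int R w Delta [dN - (bdrift + Delta(l) psi) dt] = 0.
# Returns the event sum E, the per-subject integrals I_i = int w Delta dt,
# numerator, denominator and the solution.
.solve_pair_m2 <- function(d, k, l, nuis, design, config) {
  Sl <- d$Sfull[, l + 1L]
  Sl1 <- d$Sfull[, l + 2L]
  tt <- d$time
  rs <- which(tt >= Sl)
  if (length(rs) == 0L) {
    return(list(ok = FALSE, reason = "empty risk set"))
  }
  u <- pmin(tt[rs], Sl1[rs]) - Sl[rs]
  C0 <- nuis$lw$C0[rs]
  bw <- nuis$lw$bw[rs]
  bdrift <- nuis$lw$bdrift[rs]
  Ak <- d$A[rs, k + 1L]
  if (design$link == "identity") {
    d0 <- Ak - nuis$e0[rs]
    g <- nuis$akl
    I <- exp(C0) * (d0 * .f1(bw, u) - g * .f2(bw, u))
    wT <- exp(C0 + bw * u)
    dT <- d0 - g * u
  } else {
    eta0 <- nuis$eta0[rs]
    akl <- nuis$akl
    d0 <- Ak - stats::plogis(eta0)
    gl <- .gauss_legendre(config$quad_points)
    I <- numeric(length(rs))
    for (q in seq_along(gl$x)) {
      sq <- u * (gl$x[q] + 1) / 2
      I <- I + (u / 2) * gl$w[q] *
        exp(C0 + bw * sq) * (Ak - stats::plogis(eta0 + akl * sq))
    }
    wT <- exp(C0 + bw * u)
    dT <- Ak - stats::plogis(eta0 + akl * u)
  }
  ev <- d$event[rs] == 1L & tt[rs] < Sl1[rs]
  E <- sum(wT[ev] * dT[ev])
  num <- E - sum(bdrift * I)
  den <- sum(d0 * I)
  if (!is.finite(den) || abs(den) < 1e-12 * length(rs)) {
    return(list(ok = FALSE, reason = "zero denominator (exposure carries no residual variation in the risk set)"))
  }
  list(ok = TRUE, E = E, num = num, den = den, psi = num / den,
       d0 = d0, I = I, rs = rs)
}

# Method 3 solve for pair (k, l): the exposure nuisance model is refitted at
# every risk-set departure time in [S_l, S_{l+1}) with weights w_k(t); the
# residual Delta(t) is a right-continuous step function between refits.
# Regular visit grids only.
.solve_pair_m3 <- function(d, k, l, psi, H, design, config,
                           cw = NULL, stab = NULL) {
  Sl <- d$Sfull[1L, l + 1L]
  Sl1 <- d$Sfull[1L, l + 2L]
  lw <- .logw_coefs(d, k, l, psi, stab = stab,
                    stabilized = config$stabilized,
                    center_later = config$center_later, cw = cw)
  tt <- d$time
  rs0 <- which(tt >= Sl)
  if (length(rs0) <= ncol(H)) {
    return(list(ok = FALSE, reason = "empty or tiny risk set"))
  }
  dep <- sort(unique(tt[tt >= Sl & tt < Sl1]))
  fit_times <- c(Sl, dep)
  bounds <- c(fit_times, Sl1) - Sl       # segment boundaries in s units
  u <- pmin(tt, Sl1) - Sl                # exposure time in the interval
  C0 <- lw$C0
  bw <- lw$bw
  expC <- exp(C0)
  q <- ncol(H)
  Iacc <- numeric(d$n)
  E <- 0
  coef_prev <- NULL
  fallback <- FALSE
  d0 <- NULL
  linkinv <- if (design$link == "identity") identity else stats::plogis
  for (r in seq_along(fit_times)) {
    s_r <- bounds[r]
    s_next <- bounds[r + 1L]
    rs <- which(tt >= fit_times[r])
    cf <- NULL
    if (length(rs) > q) {
      w_r <- exp(C0[rs] + bw[rs] * s_r)
      if (design$link == "identity") {
        cf <- .wls(H[rs, , drop = FALSE], d$A[rs, k + 1L], w_r)
      } else {
        gfit <- suppressWarnings(
          stats::glm.fit(H[rs, , drop = FALSE], d$A[rs, k + 1L],
                         weights = w_r, family = stats::binomial())
        )
        cf <- if (gfit$converged) gfit$coefficients else NULL
      }
      if (!is.null(cf) && anyNA(cf)) cf <- NULL
    }
    if (is.null(cf)) {
      if (is.null(coef_prev)) {
        return(list(ok = FALSE, reason = "initial risk-set fit failed"))
      }
      fallback <- TRUE
      cf <- coef_prev
    }
    coef_prev <- cf
    e_rs <- linkinv(drop(H[rs, , drop = FALSE] %*% cf))
    delta_rs <- d$A[rs, k + 1L] - e_rs
    if (r == 1L) {
      d0 <- numeric(d$n)
      d0[rs] <- delta_rs
    }
    # events occurring exactly at this fit time
    evh <- d$event[rs] == 1L & tt[rs] == fit_times[r]
    if (any(evh)) {
      E <- E + sum(exp(C0[rs][evh] + bw[rs][evh] * s_r) * delta_rs[evh])
    }
    # segment [s_r, s_next): subjects still at risk past s_r contribute fully
    stay <- u[rs] > s_r
    if (any(stay) && s_next > s_r) {
      i2 <- rs[stay]
      b2 <- bw[i2]
      seg <- numeric(length(i2))
      sm <- abs(b2) < 1e-12
      if (any(sm)) seg[sm] <- s_next - s_r
      if (any(!sm)) {
        seg[!sm] <- (exp(b2[!sm] * s_next) - exp(b2[!sm] * s_r)) / b2[!sm]
      }
      Iacc[i2] <- Iacc[i2] + delta_rs[stay] * expC[i2] * seg
    }
  }
  if (fallback) {
    warning(sprintf("pair (%d,%d): some per-time fits failed; reused the most recent fit",
                    k, l), call. = FALSE)
  }
  num <- E - sum(lw$bdrift * Iacc)
  den <- sum(d0 * Iacc)
  if (!is.finite(den) || abs(den) < 1e-12 * d$n) {
    return(list(ok = FALSE, reason = "zero denominator"))
  }
  list(ok = TRUE, E = E, num = num, den = den, psi = num / den,
       n_refits = length(fit_times))
}

# subject-level resampling / subsetting
.subset_data <- function(d, idx) {
  new_sncstm_data(
    ids = as.character(seq_along(idx)),
    A = d$A[idx, , drop = FALSE],
    L = d$L[idx, , , drop = FALSE],
    S = d$S[idx, , drop = FALSE],
    admin_end = d$admin_end[idx],
    time = d$time[idx],
    event = d$event[idx]
  )
}

# recursion order: lag by lag along the diagonals
.pair_order <- function(K, max_lag = NULL) {
  mx <- if (is.null(max_lag)) K else min(max_lag, K)
  out <- list()
  for (m in 0:mx) {
    for (k in 0:(K - m)) out[[length(out) + 1L]] <- c(k = k, l = k + m)
  }
  out
}
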