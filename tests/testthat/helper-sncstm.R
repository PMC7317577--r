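# Shared helpers: small hand-built cohorts and independent numerical
# oracles used to cross-check the closed-form estimators.

# a tiny well-formed cohort (K = 1, two confounders)
make_toy_subjects <- function() {
  list(
    subject_history("a", c(0, 1), c(2.5, 3.1),
                    matrix(c(0.2, -0.1, 0.4, 0.3), 2, byrow = TRUE),
                    followup_time = 2, event = 0, admin_end = 2),
    subject_history("b", c(0, 1), c(3.6, 0),
                    matrix(c(-0.5, 0.8, 0, 0), 2, byrow = TRUE),
                    followup_time = 0.7, event = 1, admin_end = 2),
    subject_history("c", c(0, 1), c(2.9, 2.2),
                    matrix(c(0.1, 0.1, -0.2, 0.6), 2, byrow = TRUE),
                    followup_time = 1.8, event = 1, admin_end = 2)
  )
}

# Independent evaluation of the (k, l) estimating-equation pieces by
# composite Simpson quadrature on each subject's own at-risk window, with
# blip weights computed through the scalar user-facing blip_weight()
# (a code path disjoint from the estimator's closed-form integrals).
# Returns E (event sum), Ib = sum_i drift_i * int w Delta dt, and
# Id = sum_i Delta_i(l) * int w Delta dt, so that the estimating function
# at psi is E - Ib - psi * Id.
numeric_ee_pieces <- function(data, k, l, psi_prev, nuisance, nodes = 101L) {
  d <- as_sncstm_data(data)
  subs <- as_subject_list(d)
  pmat <- psi_matrix(d$K, 0)
  pmat[upper.tri(pmat, diag = TRUE)] <- unclass(psi_prev)[upper.tri(psi_prev, diag = TRUE)]
  E <- 0; Ib <- 0; Id <- 0
  for (i in seq_len(d$n)) {
    Sl <- d$Sfull[i, l + 1L]; Sl1 <- d$Sfull[i, l + 2L]
    Ti <- d$time[i]
    if (Ti < Sl) next
    u <- min(Ti, Sl1)
    # drift: sum_{j=k+1}^{l} A_j psi_j(l)
    drift <- 0
    if (l > k) for (j in (k + 1L):l) drift <- drift + d$A[i, j + 1L] * pmat[j + 1L, l + 1L]
    # Simpson quadrature of w(t) * Delta(t) over [Sl, u]
    if (u > Sl) {
      ts <- seq(Sl, u, length.out = nodes)
      wts <- vapply(ts, function(t) blip_weight(subs[[i]], k, t, pmat), numeric(1))
      dl <- d$A[i, k + 1L] - nuisance$predict(rep(i, nodes), ts)
      h <- (u - Sl) / (nodes - 1L)
      simp <- c(1, rep(c(4, 2), length.out = nodes - 2L), 1)
      Iw <- sum(simp * wts * dl) * h / 3
      Ib <- Ib + drift * Iw
      Id <- Id + (d$A[i, k + 1L] - nuisance$predict(i, Sl)) * Iw
    }
    if (d$event[i] == 1L && Ti >= Sl && Ti < Sl1) {
      wT <- blip_weight(subs[[i]], k, Ti, pmat)
      E <- E + wT * (d$A[i, k + 1L] - nuisance$predict(i, Ti))
    }
  }
  list(E = E, Ib = Ib, Id = Id)
}

# plain bisection for a root of f on [lo, hi]
bisect_root <- function(f, lo, hi, iter = 80L) {
  flo <- f(lo)
  for (it in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# a small binary-exposure cohort (logit-link exposure models), built by an
# explicit per-subject loop independent of simulate_dataset
make_binary_cohort <- function(n = 150L, K = 2L, seed = 7L) {
  set.seed(seed)
  subs <- vector("list", n)
  for (i in seq_len(n)) {
    L <- matrix(0, K + 1L, 1L)
    A <- numeric(K + 1L)
    Tfail <- Inf
    for (k in 0:K) {
      L[k + 1L, 1L] <- stats::rnorm(1, 0.3 * (if (k > 0) L[k, 1L] else 0), 1)
      A[k + 1L] <- stats::rbinom(1, 1, stats::plogis(-0.3 + 0.8 * L[k + 1L, 1L]))
      h <- max(0.25 + 0.05 * L[k + 1L, 1L] - 0.08 * A[k + 1L], 0)
      e <- stats::rexp(1)
      if (is.infinite(Tfail) && e < h) {
        Tfail <- k + e / h
      }
    }
    tt <- min(Tfail, K + 1L)
    ev <- as.integer(is.finite(Tfail) && Tfail < K + 1L)
    for (k in 0:K) {
      if (k >= tt) {
        A[k + 1L] <- 0
        L[k + 1L, 1L] <- 0
      }
    }
    subs[[i]] <- subject_history(i, 0:K, A, L, tt, ev, K + 1L)
  }
  as_sncstm_data(subs)
}
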