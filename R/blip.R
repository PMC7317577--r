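# The piecewise-linear blip basis v_k(t), the blip effect v_k(t)'psi_k, and
# the blip weights w_k(t) that relate observed and partially intervened
# at-risk populations.

#' Evaluate the blip basis \eqn{v_k(t)}
#'
#' The cumulative effect of the exposure given at visit \eqn{k} on the log
#' conditional survival-probability ratio is piecewise linear in time:
#' within the interval \eqn{[S_l, S_{l+1})} containing \eqn{t}, completed
#' earlier intervals contribute their full length and the current interval
#' contributes the elapsed part \eqn{t - S_l}. With regular annual visits
#' (\eqn{S_k = k}) and no effect modification the basis at, say, `k = 0`,
#' `t = 2.5` is \eqn{(1, 1, 0.5, 0)}.
#'
#' When an effect-modifier design is supplied, each element is replaced by
#' the corresponding block \eqn{(\cdot)\,Z_k(l)^\top}, where each
#' \eqn{Z_k(l)} has leading element 1 (intercept-first convention).
#'
#' @param k Visit index of the exposure whose effect is being traced
#'   (`0 <= k <= K`).
#' @param t Evaluation time; must satisfy `t >= visit_times[k + 1]`.
#' @param visit_times Vector \eqn{S_0, \dots, S_K} of visit times.
#' @param Z Optional effect-modifier values: a list with one numeric vector
#'   \eqn{Z_k(l)} per interval \eqn{l = k, \dots, K}, each with leading
#'   element 1. `NULL` means no effect modification (all \eqn{Z_k(l) = 1}).
#' @return Numeric vector: length `K - k + 1` without modifiers, otherwise
#'   the concatenation of the per-interval blocks.
#' @export
#' @examples
#' blip_basis(0, 2.5, 0:3)   # (1, 1, 0.5, 0)
blip_basis <- function(k, t, visit_times, Z = NULL) {
  K <- length(visit_times) - 1L
  stopifnot(k >= 0L, k <= K, length(t) == 1L)
  if (K >= 1L && any(diff(visit_times) <= 0)) {
    stop("visit_times must be strictly increasing", call. = FALSE)
  }
  if (t < visit_times[k + 1L]) {
    stop(sprintf("t = %g is before visit k = %d (S_k = %g)",
                 t, k, visit_times[k + 1L]), call. = FALSE)
  }
  idx <- k:K
  lo <- visit_times[idx + 1L]
  hi <- c(visit_times[idx[-length(idx)] + 2L], Inf)
  base <- ifelse(t >= hi, hi - lo, pmax(t - lo, 0))
  if (is.null(Z)) {
    return(as.numeric(base))
  }
  if (length(Z) != length(idx)) {
    stop("Z must supply one modifier vector per interval l = k..K", call. = FALSE)
  }
  if (any(vapply(Z, function(z) z[1] != 1, logical(1)))) {
    stop("every Z_k(l) must have leading element 1", call. = FALSE)
  }
  unlist(Map(function(b, z) b * z, as.list(base), Z), use.names = FALSE)
}

#' Evaluate the blip effect \eqn{v_k(t)^\top \psi_k}
#'
#' The inner product of the blip basis with the row-\eqn{k} parameters.
#' For \eqn{k \le l \le t < l+1} (regular visits) this equals
#' \eqn{\psi_k(k) + \dots + \psi_k(l-1) + \psi_k(l)(t - l)}; it is continuous
#' and piecewise linear in \eqn{t}.
#'
#' @inheritParams blip_basis
#' @param psi A `psi_matrix` (scalar entries) or, with effect modification, a
#'   list of coefficient vectors per interval.
#' @return A single number.
#' @export
blip_effect <- function(psi, k, t, visit_times, Z = NULL) {
  v <- blip_basis(k, t, visit_times, Z = Z)
  if (is.null(Z)) {
    K <- length(visit_times) - 1L
    coefs <- unclass(psi)[k + 1L, (k:K) + 1L]
  } else {
    coefs <- unlist(psi, use.names = FALSE)
    if (length(coefs) != length(v)) {
      stop("psi coefficient blocks do not match the modifier design", call. = FALSE)
    }
  }
  sum(v * coefs)
}

#' Evaluate the blip weight \eqn{w_k(t)} for one subject
#'
#' \eqn{w_k(t) = \prod_{j=k+1}^{K} \exp\{A_j v_j(t)^\top \psi_j\}} converts
#' at-risk proportions in the observed population into at-risk proportions
#' in the population where exposures after visit \eqn{k} are set to zero.
#' Exposures not yet administered contribute nothing
#' (\eqn{v_j(t) \equiv 0} for \eqn{t < S_j}), so for
#' \eqn{t \in [S_l, S_{l+1})} only \eqn{A_{k+1}, \dots, A_l} enter. When all
#' \eqn{\psi = 0} the weight is identically 1.
#'
#' The stabilised variant replaces \eqn{A_j} by the centred residual
#' \eqn{\Delta_{j(k)}^* = A_j - E(A_j \mid \bar A_{k-1}, \bar L_k, T \ge S_j)},
#' which reduces weight variability; the stabilised and unstabilised weights
#' then differ by a factor depending only on \eqn{(\bar A_{k-1}, \bar L_k)}.
#'
#' @param subject A [subject_history()].
#' @param k Visit index.
#' @param t Evaluation time (`t >= S_k`).
#' @param psi A `psi_matrix`.
#' @param stabilized Use centred exposures? Requires `C_fits`.
#' @param C_fits Numeric vector of fitted means
#'   \eqn{\hat E(A_j \mid \bar A_{k-1}, \bar L_k, T \ge S_j)} for
#'   \eqn{j = k+1, \dots, K} (length `K - k`), from working models fitted on
#'   the respective risk sets.
#' @return A strictly positive number.
#' @export
blip_weight <- function(subject, k, t, psi, stabilized = FALSE, C_fits = NULL) {
  stopifnot(inherits(subject, "subject_history"))
  S <- subject$visit_times
  K <- length(S) - 1L
  stopifnot(k >= 0L, k <= K)
  if (t < S[k + 1L]) {
    stop(sprintf("t = %g is before visit k = %d", t, k), call. = FALSE)
  }
  if (stabilized && is.null(C_fits)) {
    stop("stabilized weights require C_fits (working-model fitted means)",
         call. = FALSE)
  }
  if (k == K) return(1)
  logw <- 0
  for (j in (k + 1L):K) {
    if (t < S[j + 1L]) next   # v_j(t) = 0 before the j-th exposure is given
    aj <- subject$exposures[j + 1L]
    if (stabilized) aj <- aj - C_fits[j - k]
    logw <- logw + aj * blip_effect(psi, j, t, S)
  }
  exp(logw)
}
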