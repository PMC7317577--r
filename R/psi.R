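# Upper-triangular collection of blip parameters psi_k(l), 0 <= k <= l <= K.

#' Create a blip-parameter matrix
#'
#' The SNCSTM parameters form an upper-triangular array
#' \eqn{\{\psi_k(l) : 0 \le k \le l \le K\}}: \eqn{\psi_k(l)} is the
#' per-unit-exposure reduction in the hazard between visits \eqn{l} and
#' \eqn{l+1} obtained by setting the exposure given at visit \eqn{k} to zero,
#' once all exposures after visit \eqn{k} have already been set to zero.
#' Entries are stored in an \eqn{(K+1)\times(K+1)} matrix whose
#' \eqn{(k+1,l+1)} element is \eqn{\psi_k(l)}; the lower triangle is `NA`.
#'
#' @param K Number of follow-up visits (visits are indexed `0:K`).
#' @param entries Optional: a full matrix of the right shape, a single value
#'   recycled over the upper triangle, or a vector of per-lag values
#'   \eqn{\psi(0), \dots, \psi(K)} placed on the diagonals (the constrained
#'   parameterisation \eqn{\psi_k(k+m) = \psi(m)}).
#' @return A `psi_matrix` object.
#' @export
#' @examples
#' psi_matrix(3, 0)                    # the null parameter
#' psi_matrix(3, c(-0.04, -0.01, -0.004, -0.002))  # common lag effects
psi_matrix <- function(K, entries = NA_real_) {
  m <- matrix(NA_real_, K + 1L, K + 1L)
  if (is.matrix(entries)) {
    stopifnot(all(dim(entries) == K + 1L))
    m[upper.tri(m, diag = TRUE)] <- entries[upper.tri(entries, diag = TRUE)]
  } else if (length(entries) == 1L) {
    m[upper.tri(m, diag = TRUE)] <- entries
  } else {
    stopifnot(length(entries) == K + 1L)
    for (k in 0:K) for (l in k:K) m[k + 1L, l + 1L] <- entries[l - k + 1L]
  }
  dimnames(m) <- list(paste0("k", 0:K), paste0("l", 0:K))
  structure(m, class = c("psi_matrix", "matrix"))
}

#' @export
print.psi_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("<psi_matrix: K=%d>\n", nrow(x) - 1L))
  print(round(unclass(x), digits))
  invisible(x)
}

# strip class for fast arithmetic inside estimators
psi_values <- function(psi) {
  stopifnot(nrow(psi) == ncol(psi))
  unclass(psi)
}

#' Report blip parameters on the tabulation scale
#'
#' Internally the package follows the convention that a beneficial exposure
#' has negative \eqn{\psi} (it subtracts from the hazard); summary tables
#' conventionally print \eqn{-10\,\hat\psi} so that hazard reductions appear
#' as positive numbers of convenient magnitude. This helper applies that
#' transform.
#'
#' @param psi A `psi_matrix`, or any numeric vector/matrix of estimates.
#' @return The same object with entries multiplied by \eqn{-10}.
#' @export
table_scale <- function(psi) {
  out <- -10 * unclass(psi)
  out
}

#' Extract the upper-triangular entries as a named vector
#'
#' Entries are ordered by lag (diagonal) and then by visit, matching the
#' recursion order of the estimators.
#'
#' @param psi A `psi_matrix`.
#' @return Named numeric vector with names like `"psi0(1)"`.
#' @export
psi_flatten <- function(psi) {
  K <- nrow(psi) - 1L
  out <- numeric(0)
  nm <- character(0)
  for (k in 0:K) for (l in k:K) {
    out <- c(out, psi[k + 1L, l + 1L])
    nm <- c(nm, sprintf("psi%d(%d)", k, l))
  }
  names(out) <- nm
  out
}
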