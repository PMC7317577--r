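# User-facing specification of the nuisance (exposure-model) designs and of
# estimator options.

#' Specify the exposure nuisance models
#'
#' Each visit's exposure \eqn{A_k} is modelled, among subjects still at risk,
#' by a canonical-link GLM
#' \eqn{g\{E(A_k \mid \bar A_{k-1}, \bar L_k, T \ge S_k)\} = \alpha_{k0}^\top H_k},
#' where \eqn{H_k} is a covariate vector with leading element 1. The default
#' design is \eqn{H_0 = (1, L_0^\top)^\top} and
#' \eqn{H_k = (1, A_{k-1}, L_k^\top)^\top} for \eqn{k \ge 1}.
#'
#' The same object also carries the working models \eqn{C_j(k)} for
#' \eqn{E(A_j \mid \bar A_{k-1}, \bar L_k, T \ge S_j)} used by stabilised
#' weights (these need not be correctly specified), and the covariate design
#' for the discrete censoring-hazard model used by
#' [fit_censoring_weights()].
#'
#' @param H_builder Function `(data, k) -> matrix` returning the
#'   \eqn{n \times q_k} design \eqn{H_k}; first column must be 1.
#' @param link `"identity"` for a continuous exposure (linear model),
#'   `"logit"` for a binary exposure.
#' @param C_builder Function `(data, j, k) -> matrix` giving the working
#'   design for \eqn{C_j(k)}; defaults to `H_builder(data, k)`, a function of
#'   \eqn{(\bar A_{k-1}, \bar L_k)} as required.
#' @param cw_builder Function `(data, l) -> matrix` giving the covariates of
#'   the censoring-hazard model in the interval starting at visit \eqn{l};
#'   defaults to \eqn{(1, A_l, L_l^\top)}.
#' @return An object of class `sncstm_design`.
#' @export
nuisance_design <- function(H_builder = NULL,
                            link = c("identity", "logit"),
                            C_builder = NULL,
                            cw_builder = NULL) {
  link <- match.arg(link)
  if (is.null(H_builder)) H_builder <- default_H_builder
  if (is.null(C_builder)) {
    force(H_builder)
    C_builder <- function(data, j, k) H_builder(data, k)
  }
  if (is.null(cw_builder)) cw_builder <- default_cw_builder
  structure(
    list(H = H_builder, link = link, C = C_builder, cw = cw_builder),
    class = "sncstm_design"
  )
}

#' Default exposure-model covariates
#'
#' \eqn{H_0 = (1, L_0^\top)}, and \eqn{H_k = (1, A_{k-1}, L_k^\top)} for
#' \eqn{k \ge 1}.
#'
#' @param data An `sncstm_data` object.
#' @param k Visit index.
#' @return Numeric matrix with `data$n` rows, first column all ones.
#' @export
default_H_builder <- function(data, k) {
  Lk <- matrix(data$L[, , k + 1L], nrow = data$n)
  if (k == 0L) {
    cbind(`(Intercept)` = 1, L = Lk)
  } else {
    cbind(`(Intercept)` = 1, Aprev = data$A[, k], L = Lk)
  }
}

default_cw_builder <- function(data, l) {
  Ll <- matrix(data$L[, , l + 1L], nrow = data$n)
  cbind(`(Intercept)` = 1, A = data$A[, l + 1L], L = Ll)
}

# validates the intercept-first convention on a concrete design matrix
check_H <- function(H, what = "H") {
  if (any(H[, 1] != 1)) {
    stop(sprintf("first element of %s must equal 1 for every subject", what),
         call. = FALSE)
  }
  invisible(H)
}

#' Estimator options
#'
#' @param stabilized Use stabilised blip weights \eqn{w_k^*(t)} (centred
#'   exposures in the weight exponent)? Requires working models
#'   \eqn{C_j(k)}, which are fitted automatically.
#' @param censoring_weights Apply inverse-probability-of-censoring weights
#'   (estimated by [fit_censoring_weights()]) to pseudo-individual rows
#'   (method 1) or to the at-risk integrands (methods 2 and 3)?
#' @param constrained Impose the common-lag constraint
#'   \eqn{\psi_k(k+m) = \psi_{k'}(k'+m)}?
#' @param grid_size Number of equally spaced pseudo-individual times per
#'   inter-visit interval, endpoints included. Default 10.
#' @param center_later Replace \eqn{A_j \psi_j(l)} by
#'   \eqn{\Delta_{j(k)}^* \psi_j(l)} in the G-estimation drift term, making
#'   methods 2 and 3 invariant to additive shifts of the later exposures.
#' @param cw_floor Lower truncation for the estimated censoring survival
#'   probability (weights are capped at `1 / cw_floor`). Default 0.05.
#' @param max_lag Restrict estimation to lags \eqn{l - k \le} `max_lag`
#'   (`NULL` = all lags). Useful when only short-lag parameters are needed.
#' @param quad_points Gauss-Legendre points per interval for the logit-link
#'   integrals of methods 2 and 3. Default 32.
#' @return An object of class `sncstm_config`.
#' @export
estimator_config <- function(stabilized = FALSE,
                             censoring_weights = FALSE,
                             constrained = FALSE,
                             grid_size = 10L,
                             center_later = FALSE,
                             cw_floor = 0.05,
                             max_lag = NULL,
                             quad_points = 32L) {
  stopifnot(grid_size >= 2L, cw_floor > 0, cw_floor < 1)
  structure(
    list(
      stabilized = isTRUE(stabilized),
      censoring_weights = isTRUE(censoring_weights),
      constrained = isTRUE(constrained),
      grid_size = as.integer(grid_size),
      center_later = isTRUE(center_later),
      cw_floor = cw_floor,
      max_lag = max_lag,
      quad_points = as.integer(quad_points)
    ),
    class = "sncstm_config"
  )
}
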