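# Domain containers: per-subject histories and the rectangular dataset layout
# used by all estimation routines.

#' Construct a single subject history
#'
#' A subject history records everything the SNCSTM estimators need about one
#' individual: the visit times \eqn{S_0 < S_1 < \dots < S_K} (with
#' \eqn{S_0 = 0}), the exposure and confounder measurements taken at those
#' visits, the observed follow-up time \eqn{T} (the minimum of the failure
#' time, any random censoring time, and the administrative end of follow-up),
#' and the event indicator (1 if the failure was observed, 0 if censored).
#'
#' By convention, exposures and confounders at visits the subject did not
#' reach (visits with \eqn{S_k \ge T}) are zero; [validate_dataset()] flags
#' departures from this convention.
#'
#' @param id Subject identifier (scalar, coerced to character).
#' @param visit_times Numeric vector \eqn{S_0, \dots, S_K}; strictly
#'   increasing with `visit_times[1] == 0`.
#' @param exposures Numeric vector \eqn{A_0, \dots, A_K} (binary or
#'   continuous), one per visit.
#' @param confounders Numeric matrix with `length(visit_times)` rows; row
#'   \eqn{k+1} holds the confounder vector \eqn{L_k}. A vector is accepted
#'   when there is a single confounder.
#' @param followup_time Observed follow-up time \eqn{T \ge 0}.
#' @param event Event indicator: 1 = failure observed, 0 = censored.
#' @param admin_end Administrative censoring time \eqn{S_{K+1}} (may be
#'   `Inf` when there is none).
#'
#' @return An object of class `subject_history`.
#' @seealso [validate_dataset()], [as_sncstm_data()]
#' @export
#' @examples
#' subject_history(
#'   id = "s1", visit_times = 0:3, exposures = c(3.1, 2.8, 3.4, 2.9),
#'   confounders = matrix(rnorm(8), nrow = 4), followup_time = 3.6,
#'   event = 1, admin_end = 4
#' )
subject_history <- function(id, visit_times, exposures, confounders,
                            followup_time, event, admin_end = Inf) {
  if (is.vector(confounders)) {
    confounders <- matrix(confounders, nrow = length(visit_times))
  }
  structure(
    list(
      id = as.character(id)[1],
      visit_times = as.numeric(visit_times),
      exposures = as.numeric(exposures),
      confounders = as.matrix(confounders),
      followup_time = as.numeric(followup_time)[1],
      event = as.integer(event)[1],
      admin_end = as.numeric(admin_end)[1]
    ),
    class = "subject_history"
  )
}

#' @export
print.subject_history <- function(x, ...) {
  cat(sprintf(
    "<subject_history %s: K=%d, T=%.4g, event=%d>\n",
    x$id, length(x$visit_times) - 1L, x$followup_time, x$event
  ))
  invisible(x)
}

#' Validate a longitudinal survival dataset
#'
#' Checks the structural invariants every estimator in the package relies on:
#' strictly increasing visit times starting at zero, non-negative follow-up
#' not exceeding the administrative end, a 0/1 event indicator, finite
#' exposure/confounder values at visits actually reached, the zero-fill
#' convention for visits at or after the follow-up time, and a common number
#' of visits and confounder dimension across subjects.
#'
#' Validation is report-only: it never stops. Estimators refuse datasets
#' whose report is non-empty.
#'
#' @param subjects A list of [subject_history()] objects, or an
#'   `sncstm_data` object.
#' @return A data frame with columns `id`, `check` and `message`; zero rows
#'   when the dataset is well formed.
#' @export
validate_dataset <- function(subjects) {
  if (inherits(subjects, "sncstm_data")) subjects <- as_subject_list(subjects)
  bad <- list()
  note <- function(id, check, message) {
    bad[[length(bad) + 1L]] <<- data.frame(
      id = id, check = check, message = message, stringsAsFactors = FALSE
    )
  }
  Ks <- integer(0)
  ps <- integer(0)
  for (s in subjects) {
    if (!inherits(s, "subject_history")) {
      note(NA_character_, "type", "element is not a subject_history")
      next
    }
    K <- length(s$visit_times) - 1L
    Ks <- c(Ks, K)
    ps <- c(ps, ncol(s$confounders))
    if (length(s$exposures) != K + 1L) {
      note(s$id, "length", "exposures and visit_times lengths differ")
    }
    if (nrow(s$confounders) != K + 1L) {
      note(s$id, "length", "confounder rows and visit_times lengths differ")
    }
    if (s$visit_times[1] != 0) note(s$id, "ordering", "S0 must equal 0")
    if (K >= 1L && any(diff(s$visit_times) <= 0)) {
      note(s$id, "ordering", "visit times must be strictly increasing")
    }
    if (is.na(s$followup_time) || s$followup_time < 0) {
      note(s$id, "followup", "followup_time must be >= 0")
    }
    if (!is.na(s$followup_time) && s$followup_time > s$admin_end) {
      note(s$id, "followup", "followup_time exceeds admin_end")
    }
    if (!(s$event %in% c(0L, 1L))) note(s$id, "event", "event must be 0 or 1")
    reached <- s$visit_times < s$followup_time
    vals <- cbind(s$exposures, s$confounders)
    if (any(reached) && any(!is.finite(vals[reached, , drop = FALSE]))) {
      note(s$id, "finite", "non-finite exposure/confounder at a reached visit")
    }
    if (any(!reached) && any(vals[!reached, , drop = FALSE] != 0, na.rm = TRUE)) {
      note(s$id, "zero-fill",
           "nonzero exposure/confounder at a visit at or after followup_time")
    }
  }
  if (length(unique(Ks)) > 1L) {
    note(NA_character_, "consistency", "subjects disagree on the number of visits")
  }
  if (length(unique(ps)) > 1L) {
    note(NA_character_, "consistency", "subjects disagree on the confounder dimension")
  }
  if (length(bad) == 0L) {
    return(data.frame(id = character(0), check = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

#' Assemble subject histories into the rectangular estimation layout
#'
#' The estimators operate on a columnar layout: an \eqn{n \times (K+1)}
#' exposure matrix, an \eqn{n \times p \times (K+1)} confounder array, an
#' \eqn{n \times (K+2)} matrix of visit times (the last column being the
#' administrative end), and follow-up/event vectors. This constructor
#' validates first and refuses malformed input.
#'
#' @param x A list of [subject_history()] objects, a long-format data frame
#'   as produced by [write_long_csv()]/[read_long_csv()], or an
#'   `sncstm_data` object (returned unchanged).
#' @param ... Passed to methods.
#' @return An object of class `sncstm_data`.
#' @export
as_sncstm_data <- function(x, ...) UseMethod("as_sncstm_data")

#' @export
as_sncstm_data.sncstm_data <- function(x, ...) x

#' @export
as_sncstm_data.list <- function(x, ...) {
  rep_ <- validate_dataset(x)
  if (nrow(rep_) > 0L) {
    stop("dataset fails validation; first problem: ",
         rep_$check[1], " (", rep_$message[1], ")", call. = FALSE)
  }
  n <- length(x)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  K <- length(x[[1]]$visit_times) - 1L
  p <- ncol(x[[1]]$confounders)
  A <- matrix(0, n, K + 1L)
  L <- array(0, dim = c(n, p, K + 1L))
  S <- matrix(0, n, K + 1L)
  admin <- numeric(n)
  tt <- numeric(n)
  ev <- integer(n)
  ids <- character(n)
  for (i in seq_len(n)) {
    s <- x[[i]]
    A[i, ] <- s$exposures
    L[i, , ] <- t(s$confounders)
    S[i, ] <- s$visit_times
    admin[i] <- s$admin_end
    tt[i] <- s$followup_time
    ev[i] <- s$event
    ids[i] <- s$id
  }
  new_sncstm_data(ids, A, L, S, admin, tt, ev)
}

#' @export
as_sncstm_data.data.frame <- function(x, ...) {
  long_to_data(x, ...)
}

# Internal constructor; assumes inputs already consistent.
new_sncstm_data <- function(ids, A, L, S, admin_end, time, event) {
  n <- nrow(A)
  K <- ncol(A) - 1L
  regular <- nrow(S) == 1L ||
    all(abs(S - matrix(S[1, ], n, K + 1L, byrow = TRUE)) < 1e-12)
  admin1 <- admin_end[1]
  common_admin <- all(admin_end == admin1)
  structure(
    list(
      id = ids, n = n, K = K, p = dim(L)[2],
      A = A, L = L, S = S,
      Sfull = cbind(S, admin_end, deparse.level = 0L),
      admin_end = admin_end,
      time = time, event = as.integer(event),
      regular = regular && common_admin
    ),
    class = "sncstm_data"
  )
}

#' @export
print.sncstm_data <- function(x, ...) {
  cat(sprintf(
    "<sncstm_data: n=%d subjects, K=%d follow-up visits, %d confounder(s), %s visits>\n",
    x$n, x$K, x$p, if (x$regular) "regular" else "irregular"
  ))
  cat(sprintf("  events: %d observed failures, %d censored\n",
              sum(x$event == 1L), sum(x$event == 0L)))
  invisible(x)
}

#' Convert the rectangular layout back to a list of subject histories
#'
#' @param data An `sncstm_data` object.
#' @return A list of [subject_history()] objects.
#' @export
as_subject_list <- function(data) {
  stopifnot(inherits(data, "sncstm_data"))
  lapply(seq_len(data$n), function(i) {
    subject_history(
      id = data$id[i],
      visit_times = data$S[i, ],
      exposures = data$A[i, ],
      confounders = t(matrix(data$L[i, , ], nrow = data$p)),
      followup_time = data$time[i],
      event = data$event[i],
      admin_end = data$admin_end[i]
    )
  })
}
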