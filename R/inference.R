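# Subject-level bootstrap confidence intervals and the Monte-Carlo
# simulation harness.

# dispatch a fit by method label ("1", "1cw", "2", "3")
.fit_by_method <- function(d, method, design, config) {
  if (method == "1cw") {
    config$censoring_weights <- TRUE
    method <- "1"
  }
  switch(method,
    "1" = estimate_method1(d, design, config),
    "2" = estimate_method2(d, design, config),
    "3" = estimate_method3(d, design, config),
    stop("unknown method: ", method, call. = FALSE)
  )
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Nonparametric bootstrap confidence intervals
#'
#' Resamples subjects with replacement and re-runs the full estimator —
#' nuisance models included — on each replicate; percentile intervals are
#' taken per parameter. Replicates on which the estimator fails (or returns
#' a missing entry) are dropped and counted; a warning is issued when more
#' than 5 percent fail.
#'
#' @param data An `sncstm_data` object.
#' @param method `"1"`, `"1cw"` (method 1 with censoring weights), `"2"` or
#'   `"3"`.
#' @param design A [nuisance_design()].
#' @param config An [estimator_config()].
#' @param B Number of bootstrap replicates.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the resampling (required for
#'   reproducibility).
#' @return An object of class `sncstm_boot`: list with `estimate` (the
#'   point estimates, native scale), `lower`, `upper`, `level`, `B`,
#'   `n_failed`, and the replicate draws in `draws`.
#' @export
bootstrap_ci <- function(data, method = "2", design = nuisance_design(),
                         config = estimator_config(), B = 1000L,
                         level = 0.95, seed = 1L) {
  stopifnot(B >= 2L, level > 0, level < 1)
  d <- as_sncstm_data(data)
  point <- suppressWarnings(.fit_by_method(d, method, design, config))
  est <- coef(point)
  npar <- length(est)
  draws <- matrix(NA_real_, B, npar, dimnames = list(NULL, names(est)))
  .with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample.int(d$n, d$n, replace = TRUE)
      fit <- tryCatch(
        suppressWarnings(.fit_by_method(.subset_data(d, idx), method, design, config)),
        error = function(e) NULL
      )
      if (!is.null(fit)) draws[b, ] <- coef(fit)
    }
  })
  ok <- stats::complete.cases(draws)
  n_failed <- sum(!ok)
  if (n_failed > 0.05 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed", n_failed, B),
            call. = FALSE)
  }
  a <- (1 - level) / 2
  qs <- apply(draws[ok, , drop = FALSE], 2L, stats::quantile,
              probs = c(a, 1 - a), names = FALSE)
  structure(
    list(estimate = est, lower = qs[1L, ], upper = qs[2L, ],
         level = level, B = B, n_failed = n_failed, method = method,
         draws = draws),
    class = "sncstm_boot"
  )
}

#' @export
print.sncstm_boot <- function(x, ...) {
  cat(sprintf("Bootstrap percentile intervals (method %s, B=%d, level %.0f%%)\n",
              x$method, x$B, 100 * x$level))
  tab <- data.frame(estimate = x$estimate, lower = x$lower, upper = x$upper)
  print(round(tab, 5))
  if (x$n_failed > 0) cat(sprintf("  %d replicate(s) failed and were dropped\n",
                                  x$n_failed))
  invisible(x)
}

#' Run a Monte-Carlo simulation study
#'
#' Generates `reps` datasets from a scenario and fits the requested
#' estimators to each, reporting per-parameter means and empirical standard
#' deviations on the tabulation scale (\eqn{-10\hat\psi}), together with
#' Monte-Carlo standard errors (empirical SD / sqrt(reps)). Each replicate
#' uses its own seed derived from the master seed, so the report is fully
#' reproducible and individual replicates can be regenerated.
#'
#' @param scenario A [scenario_spec()].
#' @param methods Character vector drawn from `"1"`, `"1cw"`, `"2"`, `"3"`.
#' @param constrained Logical vector; each method is run at every requested
#'   constraint setting.
#' @param reps Number of simulated datasets.
#' @param seed Master seed.
#' @param design,config Passed to the estimators (`config$constrained` is
#'   overridden per run).
#' @param keep_estimates Attach the raw per-replicate estimates (table
#'   scale) as attribute `"estimates"`?
#' @return A data frame of class `sncstm_simstudy` with columns `method`,
#'   `constrained`, `parameter`, `mean`, `sd`, `mc_se`, `reps_ok`.
#' @export
run_simulation_study <- function(scenario, methods = c("1", "2"),
                                 constrained = c(FALSE, TRUE),
                                 reps = 1000L, seed = 1L,
                                 design = nuisance_design(),
                                 config = estimator_config(),
                                 keep_estimates = FALSE) {
  stopifnot(inherits(scenario, "scenario_spec"), reps >= 1L)
  combos <- expand.grid(method = methods, constrained = constrained,
                        stringsAsFactors = FALSE)
  npar <- (scenario$K + 1L) * (scenario$K + 2L) / 2L
  store <- lapply(seq_len(nrow(combos)),
                  function(i) matrix(NA_real_, reps, npar))
  parnames <- NULL
  for (r in seq_len(reps)) {
    dat <- simulate_dataset(scenario, seed = (seed + r) %% .Machine$integer.max)
    for (i in seq_len(nrow(combos))) {
      cfg <- config
      cfg$constrained <- combos$constrained[i]
      fit <- tryCatch(
        suppressWarnings(.fit_by_method(dat, combos$method[i], design, cfg)),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        est <- table_scale(coef(fit))
        store[[i]][r, ] <- est
        if (is.null(parnames)) parnames <- names(coef(fit))
      }
    }
  }
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    M <- store[[i]]
    colnames(M) <- parnames
    ok <- stats::complete.cases(M)
    mu <- colMeans(M[ok, , drop = FALSE])
    sdv <- apply(M[ok, , drop = FALSE], 2L, stats::sd)
    rows[[i]] <- data.frame(
      method = combos$method[i], constrained = combos$constrained[i],
      parameter = parnames, mean = mu, sd = sdv,
      mc_se = sdv / sqrt(sum(ok)), reps_ok = sum(ok),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sncstm_simstudy", "data.frame")
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  if (keep_estimates) {
    names(store) <- paste0(combos$method, ifelse(combos$constrained, "_con", ""))
    attr(out, "estimates") <- store
  }
  out
}

#' Compare a simulation report against reference values
#'
#' Computes, for each (method, constrained, parameter) row of a
#' [run_simulation_study()] report, the z-score of the simulated mean
#' against a reference mean, using the report's Monte-Carlo standard error
#' (optionally inflated to account for the reference itself being a
#' Monte-Carlo mean from `ref_reps` replicates).
#'
#' @param report An `sncstm_simstudy`.
#' @param reference Data frame with columns `method`, `constrained`,
#'   `parameter`, `mean` (table scale).
#' @param ref_reps Replicate count behind the reference means (`Inf` for an
#'   exact reference).
#' @return The report with extra columns `ref_mean` and `z`.
#' @export
compare_to_reference <- function(report, reference, ref_reps = Inf) {
  key <- c("method", "constrained", "parameter")
  m <- merge(as.data.frame(report), reference, by = key,
             suffixes = c("", "_ref"))
  infl <- sqrt(1 + ifelse(is.finite(ref_reps), m$reps_ok / ref_reps, 0))
  m$ref_mean <- m$mean_ref
  m$z <- (m$mean - m$ref_mean) / (m$mc_se * infl)
  m[order(m$method, m$constrained, m$parameter),
    c(key, "mean", "sd", "mc_se", "ref_mean", "z", "reps_ok")]
}

#' Double-robustness experiment
#'
#' Simulates from the one-side-misspecified scenarios of
#' [dr_scenario_spec()] and reports, per arm, the Monte-Carlo mean of the
#' first-interval estimate \eqn{\hat\psi_0(0)}, its bias against the known
#' truth, and the z-score of the bias. Under either single
#' misspecification the G-estimators remain consistent; the `"both"` arm is
#' a negative control expected to show bias.
#'
#' @param base Base [scenario_spec()] (its `n` is the per-replicate sample
#'   size).
#' @param arms Which misspecification arms to run.
#' @param method `"2"` or `"3"`.
#' @param reps Replicates per arm.
#' @param seed Master seed.
#' @param a_strength,b_strength Perturbation sizes, see
#'   [dr_scenario_spec()].
#' @return Data frame with columns `arm`, `mean_psi00`, `truth`, `bias`,
#'   `mc_se`, `z`, `reps_ok` (all on the native scale).
#' @export
run_dr_experiment <- function(base = scenario_spec(n = 5000L),
                              arms = c("A", "B", "both"),
                              method = "2", reps = 200L, seed = 1L,
                              a_strength = 0.3, b_strength = 0.1) {
  cfg <- estimator_config(max_lag = 0L)
  truth <- base$hazard_lags[1L]
  rows <- list()
  for (a in arms) {
    spec <- dr_scenario_spec(a, base = base, a_strength = a_strength,
                             b_strength = b_strength)
    vals <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      dat <- simulate_dr_dataset(
        spec, seed = (seed + 7919L * match(a, c("A", "B", "both", "none")) + r) %%
          .Machine$integer.max
      )
      fit <- tryCatch(
        suppressWarnings(.fit_by_method(dat, method, nuisance_design(), cfg)),
        error = function(e) NULL
      )
      if (!is.null(fit)) vals[r] <- fit$psi[1L, 1L]
    }
    ok <- !is.na(vals)
    mse <- stats::sd(vals[ok]) / sqrt(sum(ok))
    rows[[a]] <- data.frame(
      arm = a, mean_psi00 = mean(vals[ok]), truth = truth,
      bias = mean(vals[ok]) - truth, mc_se = mse,
      z = (mean(vals[ok]) - truth) / mse, reps_ok = sum(ok),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap coverage experiment
#'
#' Estimates the coverage of percentile bootstrap confidence intervals for
#' every blip parameter: for each of `sims` simulated datasets a full
#' bootstrap with `B` replicates is run and the interval is checked against
#' the scenario's true parameter values.
#'
#' @param scenario A [scenario_spec()].
#' @param method Estimator label (see [bootstrap_ci()]).
#' @param sims Number of simulated datasets.
#' @param B Bootstrap replicates per dataset.
#' @param level Nominal level.
#' @param seed Master seed.
#' @param design,config Passed through.
#' @return Data frame with columns `parameter`, `coverage` (percent),
#'   `sims_ok`; attribute `"binomial_se"` gives the Monte-Carlo standard
#'   error of a coverage estimate at the nominal level.
#' @export
coverage_experiment <- function(scenario, method = "2", sims = 200L,
                                B = 200L, level = 0.95, seed = 1L,
                                design = nuisance_design(),
                                config = estimator_config()) {
  truth <- psi_flatten(true_psi(scenario))
  hits <- matrix(NA, sims, length(truth),
                 dimnames = list(NULL, names(truth)))
  for (s in seq_len(sims)) {
    dat <- simulate_dataset(scenario, seed = (seed + s) %% .Machine$integer.max)
    bs <- tryCatch(
      suppressWarnings(bootstrap_ci(dat, method = method, design = design,
                                    config = config, B = B, level = level,
                                    seed = seed + 31L * s)),
      error = function(e) NULL
    )
    if (!is.null(bs)) {
      hits[s, ] <- bs$lower <= truth & truth <= bs$upper
    }
  }
  ok <- stats::complete.cases(hits)
  cov <- 100 * colMeans(hits[ok, , drop = FALSE])
  out <- data.frame(parameter = names(truth), coverage = cov,
                    sims_ok = sum(ok), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "binomial_se") <- 100 * sqrt(level * (1 - level) / sum(ok))
  out
}
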