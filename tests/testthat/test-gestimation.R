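# Closed-form G-estimation (methods 2 and 3).

test_that("the closed form solves the estimating equation exactly", {
  d <- simulate_dataset(scenario_spec(n = 400), seed = 3)
  psi_prev <- psi_matrix(3, 0)
  sol <- solve_psi_kl(d, 0, 0, psi_prev)
  r0 <- estimating_equation_residual(d, 0, 0, sol$psi, psi_prev)
  expect_lt(abs(r0), 1e-8 * max(abs(sol$num), abs(sol$den)))
  # linearity: unit increase in psi changes the residual by -denominator
  r1 <- estimating_equation_residual(d, 0, 0, sol$psi + 1, psi_prev)
  expect_equal(r1 - r0, -sol$den, tolerance = 1e-8)
})

test_that("closed-form solutions equal bisection roots of the numeric equation", {
  # continuous exposure, several (k, l) pairs and random nuisance parameters
  set.seed(101)
  cases <- list(c(0, 0), c(0, 1), c(1, 2), c(0, 3), c(2, 3))
  for (ci in seq_along(cases)) {
    k <- cases[[ci]][1]; l <- cases[[ci]][2]
    d <- simulate_dataset(scenario_spec(n = 50), seed = 300 + ci)
    psi_prev <- psi_matrix(3, 0)
    if (l > k) {
      for (j in (k + 1):l) for (m in j:l) {
        psi_prev[j + 1, m + 1] <- stats::runif(1, -0.08, 0.02)
      }
    }
    sol <- solve_psi_kl(d, k, l, psi_prev)
    nuis <- fit_shifted_glm(d, k, l, psi = psi_prev)
    pieces <- numeric_ee_pieces(d, k, l, psi_prev, nuis)
    f <- function(p) pieces$E - pieces$Ib - p * pieces$Id
    root <- bisect_root(f, sol$psi - 0.5, sol$psi + 0.5)
    expect_lt(abs(root - sol$psi) / max(abs(sol$psi), 1e-3), 1e-6)
  }
})

test_that("the logit-link solve matches the numeric oracle on a binary cohort", {
  d <- make_binary_cohort(n = 200, K = 2, seed = 5)
  des <- nuisance_design(
    H_builder = function(data, k) cbind(1, matrix(data$L[, , k + 1], nrow = data$n)),
    link = "logit"
  )
  psi_prev <- psi_matrix(2, 0)
  psi_prev[2, 2] <- -0.06
  sol <- solve_psi_kl(d, 0, 1, psi_prev, design = des)
  nuis <- fit_shifted_glm(d, 0, 1, design = des, psi = psi_prev)
  pieces <- numeric_ee_pieces(d, 0, 1, psi_prev, nuis)
  root <- bisect_root(function(p) pieces$E - pieces$Ib - p * pieces$Id,
                      sol$psi - 0.5, sol$psi + 0.5)
  expect_lt(abs(root - sol$psi), 1e-6)
})

test_that("method 2 is invariant to additive shifts of the exposure", {
  d <- simulate_dataset(scenario_spec(n = 1200), seed = 11)
  f0 <- suppressWarnings(estimate_method2(d))
  # shift A_0 for every subject who reached visit 0 (nuisance models refit)
  d2 <- d
  reach <- d$S[, 1] < d$time
  d2$A[reach, 1] <- d2$A[reach, 1] + 5
  f2 <- suppressWarnings(estimate_method2(d2))
  expect_lt(max(abs(unclass(f0$psi) - unclass(f2$psi)), na.rm = TRUE), 1e-10)
  # shifts of later exposures require centred drift and stabilised weights
  cfg <- estimator_config(stabilized = TRUE, center_later = TRUE)
  g0 <- suppressWarnings(estimate_method2(d, config = cfg))
  d3 <- d
  reach2 <- d$S[, 3] < d$time
  d3$A[reach2, 3] <- d3$A[reach2, 3] + 7
  g3 <- suppressWarnings(estimate_method2(d3, config = cfg))
  expect_lt(max(abs(unclass(g0$psi) - unclass(g3$psi)), na.rm = TRUE), 1e-10)
})

test_that("method 3 shares the shift-invariance property", {
  d <- simulate_dataset(scenario_spec(n = 600), seed = 12)
  f0 <- suppressWarnings(estimate_method3(d))
  d2 <- d
  reach <- d$S[, 1] < d$time
  d2$A[reach, 1] <- d2$A[reach, 1] + 5
  f2 <- suppressWarnings(estimate_method3(d2))
  expect_lt(max(abs(unclass(f0$psi) - unclass(f2$psi)), na.rm = TRUE), 1e-10)
})

test_that("methods 2 and 3 agree closely on the same data", {
  d <- simulate_dataset(scenario_spec(n = 4000), seed = 11)
  f2 <- suppressWarnings(estimate_method2(d))
  f3 <- suppressWarnings(estimate_method3(d))
  expect_lt(max(abs(unclass(f2$psi) - unclass(f3$psi)), na.rm = TRUE), 2e-3)
})

test_that("under a null exposure effect method 2 estimates vanish", {
  spec <- scenario_spec(n = 20000, hazard_lags = c(0, 0, 0, 0),
                        L_exposure_loadings = c(0, 0))
  d <- simulate_dataset(spec, seed = 29)
  fit <- estimate_method2(d)
  expect_true(all(abs(psi_flatten(fit$psi)) < 0.025))
})

test_that("the estimating function is unbiased at the truth", {
  spec <- scenario_spec(n = 150)
  truth <- true_psi(spec)
  vals <- vapply(1:300, function(r) {
    d <- simulate_dataset(spec, seed = 4000 + r)
    sol <- tryCatch(solve_psi_kl(d, 0, 0, psi_matrix(3, 0)),
                    error = function(e) NULL)
    if (is.null(sol)) return(NA_real_)
    sol$num - truth[1, 1] * sol$den
  }, numeric(1))
  vals <- vals[!is.na(vals)]
  z <- mean(vals) / (stats::sd(vals) / sqrt(length(vals)))
  expect_lt(abs(z), 3)
})

test_that("the closed-form time integrals match adaptive quadrature", {
  set.seed(8)
  for (i in 1:25) {
    b <- stats::runif(1, -2, 2) * sample(c(1, 1e-7), 1)
    u <- stats::runif(1, 0.1, 1)
    f1_num <- stats::integrate(function(s) exp(b * s), 0, u,
                               rel.tol = 1e-12)$value
    f2_num <- stats::integrate(function(s) s * exp(b * s), 0, u,
                               rel.tol = 1e-12)$value
    expect_equal(sncstm:::.f1(b, u), f1_num, tolerance = 1e-10)
    expect_equal(sncstm:::.f2(b, u), f2_num, tolerance = 1e-10)
  }
})

test_that("constant exposure in the risk set is reported as non-identifiable", {
  subs <- lapply(1:20, function(i) {
    reached <- i > 6
    subject_history(i, c(0, 1), c(2, if (reached) 2 else 0),
                    matrix(c(stats::rnorm(1), if (reached) stats::rnorm(1) else 0),
                           2, 1),
                    followup_time = if (reached) 2 else 0.5 + i / 20,
                    event = as.integer(!reached), admin_end = 2)
  })
  d <- as_sncstm_data(subs)
  expect_error(solve_psi_kl(d, 0, 0), "singular|denominator")
})

test_that("with K = 0 the G-estimator collapses to a single point-exposure solve", {
  spec <- scenario_spec(n = 3000, K = 0, hazard_lags = -0.04, admin_end = 1)
  d <- simulate_dataset(spec, seed = 51)
  f2 <- estimate_method2(d)
  f2c <- estimate_g_constrained(d)
  one <- solve_psi_kl(d, 0, 0)
  expect_equal(f2$psi[1, 1], one$psi, tolerance = 1e-12)
  expect_equal(f2c$psi[1, 1], one$psi, tolerance = 1e-12)
  f3 <- estimate_method3(d)
  expect_lt(abs(f3$psi[1, 1] - one$psi), 0.02)
})

test_that("method 2 stays unbiased under completely-random censoring", {
  spec <- scenario_spec(n = 40000, censoring = "exponential")
  d <- simulate_dataset(spec, seed = 61)
  fit <- suppressWarnings(estimate_method2(d))
  truth <- true_psi(spec)
  expect_lt(abs(fit$psi[1, 1] - truth[1, 1]), 0.01)
  expect_lt(abs(fit$psi[4, 4] - truth[4, 4]), 0.02)
})

test_that("method 3 refuses irregular visit grids", {
  d <- simulate_dataset(scenario_spec(n = 100, visit_regime = "irregular"),
                        seed = 5)
  expect_error(estimate_method3(d), "regular")
})

test_that("methods 1 and 2 handle irregular visit grids", {
  spec <- scenario_spec(n = 30000, visit_regime = "irregular",
                        censoring = "exponential")
  d <- simulate_dataset(spec, seed = 71)
  truth <- true_psi(spec)
  f2 <- suppressWarnings(estimate_method2(d))
  expect_lt(abs(f2$psi[1, 1] - truth[1, 1]), 0.012)
  f1 <- suppressWarnings(estimate_method1(d))
  expect_lt(abs(f1$psi[1, 1] - truth[1, 1]), 0.02)
})
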