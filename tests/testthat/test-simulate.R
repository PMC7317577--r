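# Synthetic-data generator: determinism, survival-draw correctness, and the
# known-truth parameter values.

test_that("a fixed seed reproduces the dataset bit for bit", {
  spec <- scenario_spec(n = 400, censoring = "exponential")
  d1 <- simulate_dataset(spec, seed = 77)
  d2 <- simulate_dataset(spec, seed = 77)
  expect_identical(d1$A, d2$A)
  expect_identical(d1$time, d2$time)
  expect_identical(d1$event, d2$event)
})

test_that("growing n extends the dataset without reshuffling earlier subjects", {
  spec_small <- scenario_spec(n = 50, censoring = "exponential")
  spec_big <- scenario_spec(n = 200, censoring = "exponential")
  ds <- simulate_dataset(spec_small, seed = 5)
  db <- simulate_dataset(spec_big, seed = 5)
  expect_equal(db$A[1:50, ], ds$A)
  expect_equal(db$time[1:50], ds$time)
})

test_that("with a constant hazard the failure times are exponential", {
  h <- 0.3
  spec <- scenario_spec(
    n = 40000, hazard_intercept = h, hazard_L = c(0, 0),
    hazard_lags = c(0, 0, 0, 0)
  )
  d <- simulate_dataset(spec, seed = 21)
  for (t in c(0.5, 1.5, 2.5, 3.5)) {
    emp <- mean(d$time >= t)
    expect_lt(abs(emp - exp(-h * t)), 4 * sqrt(exp(-h * t) * (1 - exp(-h * t)) / 40000))
  }
})

test_that("exponential inversion agrees with a fine-grid discrete-time oracle", {
  # re-implement the default DGP with per-step Bernoulli failure draws
  # (dt = 1e-3) and compare marginal survival against simulate_dataset
  n <- 4000
  spec <- scenario_spec(n = n)
  set.seed(913)
  cholS <- chol(spec$Sigma)
  Lprev <- matrix(stats::rnorm(n * 2), n, 2) %*% cholS
  Aprev <- matrix(0, n, 4)
  oracle_t <- rep(Inf, n)
  alive <- rep(TRUE, n)
  dt <- 1e-3
  for (k in 0:3) {
    Lk <- if (k == 0) Lprev else {
      Lprev %*% t(spec$Omega) + outer(Aprev[, k], spec$L_exposure_loadings) +
        matrix(stats::rnorm(n * 2), n, 2) %*% cholS
    }
    Ak <- if (k == 0) {
      3 + drop(Lk %*% c(0.2, 0.1)) + 0.9 * stats::rnorm(n)
    } else {
      3 + drop(Lk %*% c(0.1, 0.05)) + 0.7 * stats::rnorm(n)
    }
    Aprev[, k + 1] <- Ak
    h <- spec$hazard_intercept + drop(Lk %*% spec$hazard_L)
    for (m in 0:k) h <- h + spec$hazard_lags[m + 1] * Aprev[, k - m + 1]
    h <- pmax(h, 0)
    for (s in seq_len(as.integer(1 / dt))) {
      die <- alive & (stats::runif(n) < h * dt)
      oracle_t[die] <- k + (s - 0.5) * dt
      alive <- alive & !die
    }
    Lprev <- Lk
  }
  d <- simulate_dataset(spec, seed = 913)
  for (k in 0:3) {
    p_o <- mean(oracle_t >= k & oracle_t < k + 1)
    p_p <- mean(d$event == 1 & d$time >= k & d$time < k + 1)
    expect_lt(abs(p_o - p_p), 4 * sqrt(2 * p_o * (1 - p_o) / n))
  }
})

test_that("true_psi returns the closed-form blip values of the default DGP", {
  spec <- scenario_spec()
  psi <- true_psi(spec)
  expect_equal(psi[1, 1], -0.04)
  expect_equal(psi[1, 2], -0.01)
  # lag-2/3 values derived independently: hazard lag + c_L' Omega^{m-1} c_A
  cL <- c(0.03, 0.03); cA <- c(0.1, 0.05)
  Om <- matrix(c(0.2, 0.1, 0.2, 0.1), 2)
  expect_equal(psi[1, 3], -0.0055 + drop(cL %*% Om %*% cA))
  expect_equal(psi[2, 4], -0.0055 + drop(cL %*% Om %*% cA))
  expect_equal(psi[1, 4], -0.00245 + drop(cL %*% Om %*% Om %*% cA))
  # agreement with the conventionally quoted rounded values
  expect_lt(abs(psi[1, 3] - (-0.004)), 2e-4)
  expect_lt(abs(psi[1, 4] - (-0.002)), 2e-4)
  # common lag effects: the constraint holds in truth
  expect_equal(psi[1, 1], psi[4, 4])
  expect_equal(psi[1, 2], psi[3, 4])
  # null variant
  null_spec <- scenario_spec(hazard_lags = c(0, 0, 0, 0),
                             L_exposure_loadings = c(0, 0))
  expect_true(all(psi_flatten(true_psi(null_spec)) == 0))
})

test_that("true_psi refuses a hazard-perturbed DR scenario unless partial", {
  spec <- dr_scenario_spec("B")
  expect_error(true_psi(spec), "allow_partial")
  expect_equal(true_psi(spec, allow_partial = TRUE)[1, 1], -0.04)
  # exposure-side perturbation leaves the full truth intact
  expect_equal(psi_flatten(true_psi(dr_scenario_spec("A"))),
               psi_flatten(true_psi(scenario_spec())))
})

test_that("irregular gaps are uniform and independent of covariates", {
  spec <- scenario_spec(n = 3000, visit_regime = "irregular")
  d <- simulate_dataset(spec, seed = 8)
  gaps <- d$S[, 2:4] - d$S[, 1:3]
  expect_gt(min(gaps), 0.5 - 1e-12)
  expect_lt(max(gaps), 1.5 + 1e-12)
  expect_lt(abs(mean(gaps) - 1), 0.02)
  expect_false(d$regular)
})

test_that("the short-follow-up variant rescales the visit grid", {
  spec <- scenario_spec(n = 20, time_scale = 1 / 4, admin_end = 1)
  d <- simulate_dataset(spec, seed = 2)
  expect_equal(d$S[1, ], c(0, 0.25, 0.5, 0.75))
  expect_true(all(d$time <= 1))
})
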