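# The pseudo-individual GLM estimator.

test_that("under a null exposure effect the estimates and weights vanish", {
  spec <- scenario_spec(n = 20000, hazard_lags = c(0, 0, 0, 0),
                        L_exposure_loadings = c(0, 0))
  d <- simulate_dataset(spec, seed = 23)
  fit <- estimate_method1(d)
  est <- psi_flatten(fit$psi)
  expect_true(all(abs(est) < 0.025))
  # the implied blip weights are close to one everywhere
  subs <- as_subject_list(d)
  ws <- vapply(1:50, function(i) blip_weight(subs[[i]], 0, 3.9, fit$psi),
               numeric(1))
  expect_true(all(abs(ws - 1) < 0.3))
})

test_that("estimates are insensitive to the pseudo-grid resolution", {
  d <- simulate_dataset(scenario_spec(n = 50000), seed = 3)
  f10 <- suppressWarnings(estimate_method1(d))
  f50 <- suppressWarnings(estimate_method1(d, config = estimator_config(grid_size = 50L)))
  expect_lt(max(abs(unclass(f10$psi) - unclass(f50$psi)), na.rm = TRUE), 8e-4)
  expect_lt(abs(f10$psi[1, 1] - f50$psi[1, 1]) / abs(f10$psi[1, 1]), 0.01)
})

test_that("estimates are invariant to relabelling of subjects", {
  d <- simulate_dataset(scenario_spec(n = 800), seed = 31)
  set.seed(1)
  perm <- sample.int(d$n)
  dp <- sncstm:::.subset_data(d, perm)
  f1 <- suppressWarnings(estimate_method1(d))
  f2 <- suppressWarnings(estimate_method1(dp))
  expect_equal(unclass(f1$psi), unclass(f2$psi), tolerance = 1e-10)
})

test_that("with K = 0 the constrained and unconstrained fits coincide", {
  spec <- scenario_spec(n = 2000, K = 0, hazard_lags = -0.04, admin_end = 1)
  d <- simulate_dataset(spec, seed = 41)
  f <- estimate_method1(d)
  fc <- estimate_method1_constrained(d)
  expect_equal(f$psi[1, 1], fc$psi[1, 1], tolerance = 1e-10)
})

test_that("the recursion uses only shorter-lag entries", {
  # restricting the recursion to lag <= m leaves those entries unchanged,
  # so no pair depends on anything outside its own triangle
  d <- simulate_dataset(scenario_spec(n = 1500), seed = 13)
  full <- suppressWarnings(estimate_method1(d))
  for (m in 0:2) {
    part <- suppressWarnings(
      estimate_method1(d, config = estimator_config(max_lag = m))
    )
    for (k in 0:(3 - m)) {
      expect_identical(part$psi[k + 1, k + m + 1], full$psi[k + 1, k + m + 1])
    }
  }
})

test_that("psi-hat equals minus the slope over the dispersion", {
  d <- simulate_dataset(scenario_spec(n = 1000), seed = 15)
  fit <- suppressWarnings(estimate_method1(d))
  for (k in 0:3) {
    expect_equal(fit$psi[k + 1, k + 1],
                 -fit$alpha[k + 1, k + 1] / fit$phi[k + 1])
  }
  # dispersion matches the exported estimator
  expect_equal(fit$phi[2], estimate_dispersion(d, 1))
})

test_that("stabilised weights leave the estimator consistent", {
  d <- simulate_dataset(scenario_spec(n = 30000), seed = 57)
  f_plain <- suppressWarnings(estimate_method1(d))
  f_stab <- suppressWarnings(
    estimate_method1(d, config = estimator_config(stabilized = TRUE))
  )
  # same estimand; agreement well within sampling noise at this n
  expect_lt(abs(f_plain$psi[1, 2] - f_stab$psi[1, 2]), 0.004)
  # a deliberately wrong working model must not break consistency
  des <- nuisance_design(C_builder = function(data, j, k) matrix(1, data$n, 1))
  f_bad <- suppressWarnings(
    estimate_method1(d, design = des, config = estimator_config(stabilized = TRUE))
  )
  truth <- true_psi(scenario_spec())
  expect_lt(abs(f_bad$psi[1, 2] - truth[1, 2]), 0.004)
})
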