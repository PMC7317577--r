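# Pseudo-individual expansion, shifted-intercept GLM fits, dispersion,
# working models and censoring weights.

test_that("pseudo-individual rows follow the at-risk rule on the grid", {
  subs <- list(
    subject_history("s1", 0:3, c(1, 0, 0, 0), matrix(0, 4, 1), 0.35, 1, 4),
    subject_history("s2", 0:3, c(1, 1, 0, 0), matrix(c(1, 1, 0, 0), 4, 1), 2.0, 1, 4),
    subject_history("s3", 0:3, c(1, 1, 1, 1), matrix(1, 4, 1), 4.0, 0, 4)
  )
  d <- as_sncstm_data(subs)
  tab <- expand_pseudo(d, l = 0, grid_size = 10)
  # grid times j/9: subject 1 (T = 0.35) contributes at 0, 1/9, 2/9, 3/9
  expect_equal(nrow(tab), 4 + 10 + 10)
  expect_equal(sum(tab$id == "s1"), 4L)
  expect_equal(tab$Q[tab$id == "s1"], (0:3) / 9)

  tab2 <- expand_pseudo(d, l = 0, grid_size = 2)
  expect_equal(sort(unique(tab2$Q)), c(0, 1))

  # empty risk set: all follow-up before the interval
  short <- lapply(subs, function(s) { s$followup_time <- 0.2; s$event <- 1L
    s$exposures[2:4] <- 0; s$confounders[2:4, ] <- 0; s })
  dshort <- as_sncstm_data(short)
  expect_warning(tab3 <- expand_pseudo(dshort, l = 2), "no subject at risk")
  expect_equal(nrow(tab3), 0L)
})

test_that("the identity-link pseudo GLM equals weighted least squares by lm()", {
  d <- simulate_dataset(scenario_spec(n = 60), seed = 14)
  psi <- psi_matrix(3, c(-0.05, -0.01, -0.005, -0.002))
  fit <- fit_shifted_glm(d, k = 0, l = 1, psi = psi)
  # rebuild the same pseudo rows by hand and fit with stats::lm (QR path)
  tab <- expand_pseudo(d, l = 1, grid_size = 10)
  subs <- as_subject_list(d)
  w <- mapply(function(i, t) blip_weight(subs[[i]], 0, t, psi),
              tab$subject, tab$Q)
  H <- cbind(1, d$L[tab$subject, , 1])
  df <- data.frame(y = d$A[tab$subject, 1], H1 = H[, 2], H2 = H[, 3], s = tab$s)
  ref <- stats::lm(y ~ H1 + H2 + s, data = df, weights = w)
  expect_equal(unname(fit$alpha0), unname(coef(ref)[1:3]), tolerance = 1e-9)
  expect_equal(unname(fit$alpha_kl), unname(coef(ref)["s"]), tolerance = 1e-9)
})

test_that("fitted means at two times differ by alpha_k(l) times the gap", {
  d <- simulate_dataset(scenario_spec(n = 500), seed = 9)
  fit <- fit_shifted_glm(d, k = 1, l = 1)
  idx <- c(3L, 57L, 200L)
  gap <- fit$predict(idx, 1.8) - fit$predict(idx, 1.3)
  expect_equal(gap, rep(fit$alpha_kl * 0.5, 3), tolerance = 1e-12)
})

test_that("dispersion estimates converge to the generating variances", {
  d <- simulate_dataset(scenario_spec(n = 50000), seed = 17)
  phi1 <- estimate_dispersion(d, 1)
  expect_lt(abs(phi1 - 0.49) / 0.49, 0.02)
  phi0 <- estimate_dispersion(d, 0)
  expect_lt(abs(phi0 - 0.81) / 0.81, 0.02)
})

test_that("dispersion is close to 1 when the exposure has unit residual variance", {
  spec <- scenario_spec(n = 20000, a_sd = 1, a_loadings = c(0, 0),
                        a0_sd = 1, a0_loadings = c(0, 0))
  d <- simulate_dataset(spec, seed = 6)
  expect_lt(abs(estimate_dispersion(d, 2) - 1), 0.05)
})

test_that("an intercept-only working model returns the risk-set mean", {
  d <- simulate_dataset(scenario_spec(n = 300), seed = 10)
  des <- nuisance_design(C_builder = function(data, j, k) matrix(1, data$n, 1))
  wc <- fit_working_C(d, j = 2, k = 0, design = des)
  rs <- d$time >= 2
  expect_equal(unique(round(wc$fitted, 12)),
               round(mean(d$A[rs, 3]), 12))
})

test_that("censoring weights are 1 without censoring events", {
  d <- simulate_dataset(scenario_spec(n = 300), seed = 11)  # admin only
  cw <- fit_censoring_weights(d)
  expect_true(all(cw$lambda == 0))
  expect_equal(cw$weight(5, 3.2), 1)
})

test_that("under exponential censoring the weights track exp(t/mean)", {
  spec <- scenario_spec(n = 40000, censoring = "exponential", censoring_mean = 5)
  d <- simulate_dataset(spec, seed = 19)
  cw <- fit_censoring_weights(d)
  for (t in 1:4) {
    w_avg <- mean(vapply(1:200, function(i) cw$weight(i, t), numeric(1)))
    expect_lt(abs(w_avg - exp(t / 5)) / exp(t / 5), 0.06)
  }
})

test_that("the first design element must equal 1", {
  d <- simulate_dataset(scenario_spec(n = 50), seed = 1)
  bad <- nuisance_design(H_builder = function(data, k) cbind(data$A[, 1], 1))
  expect_error(estimate_dispersion(d, 0, design = bad), "must equal 1")
})
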