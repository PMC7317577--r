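# Blip basis, blip effect and blip weights.

test_that("blip basis is the documented piecewise-linear form", {
  S <- 0:3
  expect_equal(blip_basis(0, 0.5, S), c(0.5, 0, 0, 0))
  expect_equal(blip_basis(0, 2.5, S), c(1, 1, 0.5, 0))
  expect_equal(blip_basis(2, 2, S), c(0, 0))        # no elapsed time at S_k
  expect_equal(blip_basis(1, 4, S), c(1, 1, 1))     # all intervals completed
  expect_error(blip_basis(2, 1.5, S), "before visit")
  expect_error(blip_basis(0, 1, c(0, 1, 1, 2)), "strictly increasing")
})

test_that("blip basis handles irregular visit grids and effect modifiers", {
  S <- c(0, 0.7, 1.9, 3.1)
  expect_equal(blip_basis(1, 2.4, S), c(1.2, 0.5, 0))
  Z <- list(c(1, 2), c(1, -1), c(1, 0))
  expect_equal(blip_basis(1, 2.4, S, Z = Z),
               c(1.2 * c(1, 2), 0.5 * c(1, -1), 0 * c(1, 0)))
  badZ <- list(c(2, 1), c(1, 0), c(1, 0))
  expect_error(blip_basis(1, 2.4, S, Z = badZ), "leading element 1")
})

test_that("blip effect evaluates the cumulative direct effect", {
  psi <- psi_matrix(3, c(-0.04, -0.01, -0.004, -0.002))
  expect_equal(blip_effect(psi, 0, 1, 0:3), -0.04)
  expect_equal(blip_effect(psi, 0, 2.5, 0:3), -0.04 - 0.01 - 0.004 * 0.5)
  psi0 <- psi_matrix(3, 0)
  for (t in c(0, 0.3, 1.7, 3.9)) expect_equal(blip_effect(psi0, 0, t, 0:3), 0)
})

test_that("blip effect is continuous in t across interval boundaries", {
  psi <- psi_matrix(3, c(-0.04, -0.01, -0.004, -0.002))
  eps <- 1e-9
  for (k in 0:2) {
    for (l in (k + 1):3) {
      lo <- blip_effect(psi, k, l - eps, 0:3)
      hi <- blip_effect(psi, k, l + eps, 0:3)
      expect_lt(abs(hi - lo), 1e-7)
    }
  }
})

test_that("blip weights reduce to 1 in the documented degenerate cases", {
  s <- subject_history("x", 0:3, c(3, 2, 0, 0),
                       matrix(0, 4, 2), followup_time = 4, event = 0,
                       admin_end = 4)
  psi0 <- psi_matrix(3, 0)
  psi <- psi_matrix(3, c(-0.04, -0.01, -0.004, -0.002))
  expect_equal(blip_weight(s, 0, 2.5, psi0), 1)     # all psi zero
  s0 <- subject_history("y", 0:3, c(3, 0, 0, 0), matrix(0, 4, 2), 4, 0, 4)
  expect_equal(blip_weight(s0, 0, 3.5, psi), 1)     # later exposures all zero
  expect_equal(blip_weight(s, 3, 3.9, psi), 1)      # k = K: empty product
})

test_that("blip weight matches the hand-evaluated single-exposure form", {
  # A1 = 2, psi_1(1) = -0.04, t in [1,2): w_0(t) = exp{2 * (-0.04)(t-1)}
  s <- subject_history("x", 0:3, c(3, 2, 0, 0), matrix(0, 4, 2), 4, 0, 4)
  psi <- psi_matrix(3, c(-0.04, -0.01, -0.004, -0.002))
  expect_equal(blip_weight(s, 0, 1.5, psi), exp(-0.04))
  expect_equal(blip_weight(s, 0, 1, psi), 1)        # nothing elapsed yet
})

test_that("stabilised / unstabilised weight ratio depends only on shared history", {
  # two subjects with identical exposures after visit k share the weight,
  # and the stabilised version subtracts the same centring for both
  psi <- psi_matrix(3, c(-0.05, -0.02, -0.01, -0.005))
  mk <- function(id, a0) subject_history(id, 0:3, c(a0, 2, 1.5, 1),
                                         matrix(0, 4, 2), 4, 0, 4)
  s1 <- mk("p", 2.2); s2 <- mk("q", 2.2)
  cf <- c(1.8, 2.1, 1.9)   # fitted means for A_1..A_3 given shared history
  for (t in c(1.5, 2.7, 3.9)) {
    expect_equal(blip_weight(s1, 0, t, psi), blip_weight(s2, 0, t, psi))
    expect_equal(blip_weight(s1, 0, t, psi, stabilized = TRUE, C_fits = cf),
                 blip_weight(s2, 0, t, psi, stabilized = TRUE, C_fits = cf))
  }
  expect_error(blip_weight(s1, 0, 2, psi, stabilized = TRUE), "C_fits")
})

test_that("with K = 0 the blip weight is identically 1", {
  s <- subject_history("z", 0, 2.4, matrix(c(0.1, 0.2), 1), 0.9, 1, 1)
  psi <- psi_matrix(0, -0.04)
  for (t in c(0, 0.3, 0.9)) expect_equal(blip_weight(s, 0, t, psi), 1)
})
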