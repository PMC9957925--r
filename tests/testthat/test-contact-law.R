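# Point-wise constitutive model: state function, friction blend, cohesive
# normal traction, sliding limits, return mapping, damage bookkeeping.

test_that("state function branches, continuity and monotonicity", {
  a_s <- 22e-6; b_s <- 0.74
  expect_identical(state_function(0, 1, a_s, b_s), 1)
  expect_identical(state_function(0.99 * a_s, 1, a_s, b_s), 1)
  # transition midpoint: the sine argument vanishes
  expect_equal(state_function(a_s * (1 + b_s), 1, a_s, b_s), 0.5,
               tolerance = 1e-15)
  expect_identical(state_function(2 * a_s * (1 + 2 * b_s), 0.7, a_s, b_s), 0)
  # dense sweep: non-increasing, continuous at both branch joints
  gd <- seq(0, 2 * a_s * (1 + 2 * b_s), length.out = 20001)
  phi <- state_function(gd, 1, a_s, b_s)
  expect_true(all(diff(phi) <= 1e-15))
  dg <- 1e-13
  for (joint in c(a_s, a_s * (1 + 2 * b_s)))
    expect_equal(state_function(joint - dg, 1, a_s, b_s),
                 state_function(joint + dg, 1, a_s, b_s), tolerance = 1e-6)
  # phi scales with phi0
  expect_equal(state_function(gd, 0.3, a_s, b_s), 0.3 * phi,
               tolerance = 1e-15)
  expect_error(state_function(-1e-6, 1, a_s, b_s), "non-negative")
  expect_error(state_function(0, 1.5, a_s, b_s), "phi0")
})

test_that("friction coefficient is the state-weighted blend", {
  expect_identical(friction_coefficient(1, 0.44, 0.3), 0.44)
  expect_identical(friction_coefficient(0, 0.44, 0.3), 0.3)
  expect_equal(friction_coefficient(0.5, 0.44, 0.3), 0.37, tolerance = 1e-15)
  expect_error(friction_coefficient(1.2, 0.44, 0.3), "phi")
})

test_that("normal traction: penalty compression, exponential tension, cutoff", {
  p <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, t0 = 1.8e6,
                                g0 = 66e-6, g_b = 132e-6, eps_n = 1.8e12,
                                law = "emc")
  # peak of the cohesive branch is phi0 * t0, attained exactly at g_n = g0
  expect_equal(normal_traction(66e-6, phi = 1, p), 1.8e6, tolerance = 1e-12)
  expect_equal(normal_traction(66e-6, phi = 0.5, p, phi0 = 0.5), 0.9e6,
               tolerance = 1e-12)
  gr <- seq(0, 132e-6, length.out = 2000)
  expect_lt(max(normal_traction(gr, 1, p)) , 1.8e6 * (1 + 1e-12))
  # cutoff and broken bond drop to zero
  expect_identical(normal_traction(132e-6, phi = 1, p), 0)
  expect_identical(normal_traction(50e-6, phi = 0, p, phi0 = 1), 0)
  # compression: linear penalty
  expect_equal(normal_traction(-1e-6, phi = 1, p), -1.8e6, tolerance = 1e-12)
  # MC carries no tension
  pm <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, eps_n = 1.8e12,
                                 law = "mc")
  expect_identical(normal_traction(66e-6, phi = 1, pm), 0)
})

test_that("sliding limits: Coulomb, state-dependent, adhesion-shifted", {
  pe <- table3_params("emc")
  # adhesion fully mobilised in tension: zero resistance
  expect_identical(sliding_limit(1.8e6, phi = 1, pe), 0)
  # broken state under zero normal traction keeps mu_b * t0
  expect_equal(sliding_limit(0, phi = 0, pe), 0.54e6, tolerance = 1e-12)
  # compression shifts the limit up
  expect_equal(sliding_limit(-1e6, phi = 1, pe), 0.44 * 2.8e6, tolerance = 1e-12)
  # clamped at zero beyond t0
  expect_identical(sliding_limit(3e6, phi = 1, pe), 0)
  pm <- table3_params("mc")
  expect_equal(sliding_limit(-1e6, phi = 0, pm), 0.3e6, tolerance = 1e-12)
  expect_identical(sliding_limit(1e6, phi = 1, pm), 0)   # no tension support
})

test_that("law degenerations hold pointwise on random samples", {
  set.seed(42)
  n <- 1e4
  gn <- runif(n, -50e-6, 150e-6)
  phi <- runif(n)
  tn <- runif(n, -3e6, 2e6)
  base <- list(a_s = 22e-6, b_s = 0.74, mu_ub = 0.44, mu_b = 0.3,
               g0 = 66e-6, g_b = 66e-6, eps_n = 1.8e12, eps_t = 1.8e12)
  emc0 <- do.call(adhesive_friction_params, c(base, list(t0 = 0, law = "emc")))
  mc <- do.call(adhesive_friction_params, c(base, list(t0 = 0, law = "mc")))
  co <- do.call(adhesive_friction_params, c(base, list(t0 = 0, law = "coulomb")))
  # EMC with t0 = 0 is MC: no tensile traction, identical sliding limit
  expect_equal(normal_traction(gn, phi, emc0), normal_traction(gn, phi, mc),
               tolerance = 1e-12)
  expect_equal(sliding_limit(tn, phi, emc0), sliding_limit(tn, phi, mc),
               tolerance = 1e-12)
  # MC at phi = 0 is classical Coulomb with mu_b
  expect_equal(sliding_limit(tn, 0, mc), sliding_limit(tn, phi, co),
               tolerance = 1e-12)
})

test_that("return mapping respects the slip criterion", {
  r1 <- slip_update(c(0.2e6, 0, 0), 0.54e6)
  expect_identical(r1$status, "stick")
  expect_identical(r1$traction, c(0.2e6, 0, 0))
  r2 <- slip_update(c(1e6, 0, 0), 0.54e6)
  expect_identical(r2$status, "slip")
  expect_equal(r2$traction, c(0.54e6, 0, 0), tolerance = 1e-12)
  # direction preserved under radial return
  t3 <- c(0.6e6, 0.8e6, 0)
  r3 <- slip_update(t3, 0.5e6)
  expect_equal(r3$traction / sqrt(sum(r3$traction^2)), t3 / 1e6,
               tolerance = 1e-12)
  # zero limit: free sliding
  r4 <- slip_update(c(1e5, 0, 0), 0)
  expect_identical(r4$status, "slip")
  expect_identical(r4$traction, c(0, 0, 0))
  # f_s <= 0 after return on random trials
  set.seed(7)
  tr <- matrix(rnorm(300, sd = 1e6), ncol = 3)
  lim <- runif(100, 0, 1e6)
  rr <- slip_update(tr, lim)
  expect_true(all(sqrt(rowSums(rr$traction^2)) <= lim * (1 + 1e-12)))
})

test_that("smooth penalty gives a C1 traction curve at zero gap", {
  eps <- smooth_penalty(1, 1.8e6, 66e-6)
  expect_equal(eps, exp(1) * 1.8e6 / 66e-6, tolerance = 1e-15)
  expect_identical(smooth_penalty(0, 1.8e6, 66e-6), 0)
  p <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, t0 = 1.8e6,
                                g0 = 66e-6, g_b = 132e-6, eps_n = eps,
                                law = "emc")
  h <- 1e-12
  slope_left <- (normal_traction(0, 1, p) - normal_traction(-h, 1, p)) / h
  slope_right <- (normal_traction(h, 1, p) - normal_traction(0, 1, p)) / h
  expect_equal(slope_left, slope_right, tolerance = 1e-4)
})

test_that("pull-out calibration inverts the uniform-separation peak force", {
  expect_equal(calibrate_t0(9, 0.26, 2.5e-3), 9 / (0.26 * pi * 2.5e-3^2),
               tolerance = 1e-15)
  # the two experimental data points give consistent amplitudes
  expect_equal(calibrate_t0(9, 0.26, 2.5e-3), 1.76e6, tolerance = 0.01)
  expect_equal(calibrate_t0(35, 1, 2.5e-3), 1.78e6, tolerance = 0.01)
  expect_identical(calibrate_t0(0, 0.5, 2.5e-3), 0)
  expect_error(calibrate_t0(9, 0, 2.5e-3), "phi0")
  # forward and inverse are consistent
  expect_equal(uniform_pullout_peak(0.26, calibrate_t0(9, 0.26, 2.5e-3), 2.5e-3),
               9, tolerance = 1e-12)
})

test_that("damage accumulates monotonically, also under load reversal", {
  p <- table3_params("mc")
  s <- bond_state_init(1, phi0 = 1, p)
  expect_identical(s$g_d, 0)
  expect_identical(s$phi, 1)
  # zero motion leaves the state unchanged
  s0 <- update_damage(s, slip_inc = 0, g_en = 0, p)
  expect_identical(s0$g_d, 0)
  # +10 um then -10 um of slip: g_s = 20 um, irreversible
  s1 <- update_damage(s, slip_inc = 10e-6, g_en = 0, p)
  s1 <- update_damage(s1, slip_inc = 10e-6, g_en = 0, p)
  expect_equal(s1$g_s, 20e-6, tolerance = 1e-18)
  expect_identical(s1$g_sn, 0)
  # oscillating normal gap 0 -> g0 -> 0 accumulates 2 g0
  s2 <- update_damage(s, slip_inc = 0, g_en = 66e-6, p)
  s2 <- update_damage(s2, slip_inc = 0, g_en = 0, p)
  expect_equal(s2$g_sn, 132e-6, tolerance = 1e-18)
  # phi tracks the state function of the accumulated damage
  expect_equal(s2$phi, state_function(132e-6, 1, p$a_s, p$b_s),
               tolerance = 1e-15)
  # random walk: g_s, g_sn, g_d never decrease
  set.seed(11)
  s3 <- bond_state_init(1, 1, p)
  prev <- c(0, 0, 0)
  for (k in 1:50) {
    s3 <- update_damage(s3, slip_inc = abs(rnorm(1, sd = 3e-6)),
                        g_en = rnorm(1, sd = 10e-6), p)
    now <- c(s3$g_s, s3$g_sn, s3$g_d)
    expect_true(all(now >= prev - 1e-18))
    prev <- now
  }
})

test_that("parameter validation rejects unphysical sets", {
  expect_error(adhesive_friction_params(-1e-6, 0.74, 0.44, 0.3, eps_n = 1),
               "a_s")
  expect_error(adhesive_friction_params(22e-6, 0.74, 0.2, 0.3, eps_n = 1),
               "mu")
  expect_error(adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, t0 = 1e6,
                                        g0 = 2e-6, g_b = 1e-6, eps_n = 1),
               "g0")
})
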