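# Contact discretisation: closest-point projection, traction assembly,
# action-reaction, and the flat-punch penalty oracle.

plane_patch <- function(n = 2, L = 1) {
  s <- seq(0, L, length.out = n + 1)
  g <- expand.grid(x = s, y = s)
  C <- cbind(g$x, g$y, 0)
  id <- function(i, j) i + (j - 1L) * (n + 1L)
  f <- matrix(0L, n * n, 4); m <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    m <- m + 1L
    f[m, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  list(C = C, f = f, bnd = osseodebond:::facet_boundary_edges(f))
}

test_that("closest-point projection on a flat master plane", {
  pp <- plane_patch()
  pts <- rbind(c(0.4, 0.6, 0.25), c(0.7, 0.3, -0.1))
  pr <- osseodebond:::.project_points_cpp(pts, pp$C, pp$f, pp$bnd, 10, 0.01)
  expect_identical(as.integer(pr$valid), c(1L, 1L))
  # sign convention: separation positive, penetration negative
  expect_equal(as.vector(pr$g_n), c(0.25, -0.1), tolerance = 1e-12)
  expect_equal(pr$n[, 3], c(1, 1), tolerance = 1e-12)
  expect_equal(pr$x_l[1, ], c(0.4, 0.6, 0), tolerance = 1e-12)
  # a point beyond the surface boundary is rejected (flagged open)
  out <- osseodebond:::.project_points_cpp(matrix(c(1.4, 0.5, 0.05), 1),
                                           pp$C, pp$f, pp$bnd, 10, 0.01)
  expect_identical(as.integer(out$valid), 0L)
})

test_that("closest-point projection on a faceted sphere", {
  # slave point at distance d from the centre of a sphere of radius R
  # projects radially: g_n = d - R (to facet-interpolation accuracy)
  msh <- mesh_cup(R_out = 0.0255, thickness = 0.003, n = 16, nl = 1,
                  correct_radius = FALSE)
  fac <- msh$surfaces$outer
  bnd <- osseodebond:::facet_boundary_edges(fac)
  d <- c(0.027, 0.024)
  dir <- c(0.3, -0.4, -0.866); dir <- dir / sqrt(sum(dir^2))
  pts <- rbind(d[1] * dir, d[2] * dir)
  pr <- osseodebond:::.project_points_cpp(pts, msh$nodes, fac, bnd, 10, 0.01)
  expect_identical(as.integer(pr$valid), c(1L, 1L))
  # to within the chord sag of the faceted sphere; the widest cells of the
  # square-to-disc map (near its corners) have ~1.4x the mean angular width,
  # giving sag up to ~2 * R * dtheta^2 / 8 = 2.5e-4 at this resolution
  expect_lt(max(abs(as.vector(pr$g_n) - (d - 0.0255))), 2.5e-4)
  # projection point lies on the radial ray
  for (k in 1:2) {
    xl <- pr$x_l[k, ]
    expect_equal(xl / sqrt(sum(xl^2)), dir, tolerance = 5e-3)
  }
})

test_that("contact tractions match the point law and obey action-reaction", {
  cfg <- csi_config(law = "emc")
  m <- build_csi(cfg)
  pr <- stage_to_force(m, target = -70, du = -cfg$du, stage = "press")
  mdl <- pr$model
  ct <- mdl$last$ct
  act <- ct$status > 0
  expect_gt(sum(act), 100)
  # C++ kernel agrees with the exported R law at every active point
  tn_R <- normal_traction(ct$g_n[act], mdl$state$phi[act], mdl$law,
                          phi0 = mdl$state$phi0[act])
  expect_equal(ct$t_n[act], tn_R, tolerance = 1e-12)
  lim_R <- sliding_limit(ct$t_n[act], mdl$state$phi[act], mdl$law)
  expect_equal(ct$limit[act], lim_R, tolerance = 1e-12)
  # slip criterion after return mapping
  tt_norm <- sqrt(rowSums(ct$t_t^2))
  expect_true(all(tt_norm[act] <= ct$limit[act] * (1 + 1e-9)))
  # action-reaction: contact contributions sum to zero force
  expect_lt(max(abs(colSums(matrix(ct$fc, ncol = 3, byrow = TRUE)))), 1e-8)
})

test_that("flat-punch compression matches the penalty oracle", {
  # at equilibrium the interface pressure balances eps_n times the
  # penetration; the resultant equals the held force and the mean
  # penetration follows |F| / (eps_n * A)
  cfg <- csi_config(law = "mc")
  m <- build_csi(cfg)
  pr <- stage_to_force(m, target = -70, du = -cfg$du, stage = "press")
  ct <- pr$model$last$ct
  act <- ct$status > 0
  w <- pr$model$contact$wA
  A <- sum(w[act])
  expect_equal(A, pi * cfg$R_i^2, tolerance = 0.04)
  expect_equal(sum(ct$p[act] * w[act]), 70, tolerance = 1e-6)
  pen <- -sum(ct$g_n[act] * w[act]) / A
  expect_equal(pen, 70 / (cfg$eps * A), tolerance = 0.05)
  expect_equal(ct$p[act], -cfg$eps * ct$g_n[act], tolerance = 1e-12)
})

test_that("mean bonding is the area-weighted interface average", {
  cfg <- csi_config()
  m <- build_csi(cfg)
  expect_equal(mean_bonding(m), 0)   # unbonded before osseointegration
  m$state$phi <- rep(0.5, nrow(m$state))
  expect_equal(mean_bonding(m), 0.5, tolerance = 1e-12)
  # half the interface bonded (by area)
  w <- m$contact$wA * m$contact$point_interface
  phi <- as.numeric(seq_along(w) %% 2 == 0)
  m$state$phi <- phi
  expect_equal(mean_bonding(m), sum(w * phi) / sum(w), tolerance = 1e-12)
})

test_that("CSI mode II response is mirror-symmetric in the slide direction", {
  cfg <- csi_config(law = "mc", n_slide = 12)
  run_dir <- function(sgn) {
    m <- build_csi(cfg)
    pr <- stage_to_force(m, target = -70, du = -cfg$du, stage = "press")
    m2 <- stage_set_phi0(pr$model, 1)
    rm <- stage_ramp(m2, du = c(sgn * cfg$du, 0, 0), n_steps = 12, hold = -70,
                     stage = "slide")
    rm$history$F_x
  }
  expect_equal(run_dir(1), -run_dir(-1), tolerance = 1e-6)
})
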