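# Scenario builders and staged protocols.

test_that("CSI model matches the standard discretisation", {
  m <- build_csi(csi_config())
  expect_equal(sum(m$mesh$body == 2), 18)    # implant bulk
  expect_equal(sum(m$mesh$body == 1), 450)   # bone bulk
  expect_equal(nrow(m$mesh$surfaces$imp_bottom), 9)
  # structured refinement multiplies bulk counts by 8
  m2 <- build_csi(csi_config(refine = 2))
  expect_equal(nrow(m2$mesh$elems), 8 * nrow(m$mesh$elems))
  # implant centred over the block: contact patch centroid at the origin
  sf <- m$contact$sfac
  cen <- colMeans(m$mesh$nodes[as.vector(sf), 1:2])
  expect_lt(max(abs(cen)), 1e-3 * 0.8334)
  # penalties follow E_b / L0 with L0 = 1 cm
  expect_equal(m$law$eps_n, 18e9 / 0.01)
})

test_that("ACI geometry follows the interference-fit rule", {
  cfg <- aci_config(IF = 1e-3)
  expect_equal(cfg$R_b, 25.0e-3)
  expect_equal(cfg$eps, 0.2e9 / 25.5e-3)
  m <- build_aci(aci_config(IF = 1e-3, mesh_scale = 0.5))
  expect_s3_class(m, "bi_model")
  # conforming cavity (IF = 0): cup starts just touching the pole
  cfg0 <- aci_config(IF = 0, mesh_scale = 0.5)
  expect_equal(cfg0$R_b, cfg0$R_i)
  expect_error(build_aci(aci_config(IF = 30e-3)), "interference|cavity")
})

test_that("zero-target press ends immediately with d0 = 0", {
  m <- build_csi(csi_config())
  pr <- stage_to_force(m, target = -1e-9, du = -0.65e-6)
  expect_equal(pr$d, 0, tolerance = 1e-12)
})

test_that("force-monitored press lands on the target within one increment", {
  m <- build_csi(csi_config())
  pr <- stage_to_force(m, target = -70, du = -0.65e-6)
  expect_equal(unname(reaction_outputs(pr$model)["F_z"]), -70,
               tolerance = 1e-4)
  expect_lt(pr$d, 0)
})

test_that("osseointegration stage resets interface history", {
  cfg <- csi_config(law = "mc")
  m <- build_csi(cfg)
  pr <- stage_to_force(m, target = -70, du = -cfg$du)
  m2 <- stage_set_phi0(pr$model, 0.75)
  expect_equal(mean_bonding(m2), 0.75, tolerance = 1e-12)
  expect_true(all(m2$state$g_d == 0))
  # the held load is undisturbed by the reset
  expect_equal(unname(reaction_outputs(m2)["F_z"]), -70, tolerance = 0.02)
})

test_that("EMC with t0 = 0 reproduces the MC response exactly", {
  # law-degeneration oracle on a short mode IIa slide
  run_short <- function(law, t0) {
    cfg <- csi_config(law = law, t0 = t0, n_slide = 8)
    m <- build_csi(cfg)
    pr <- stage_to_force(m, target = -70, du = -cfg$du)
    m2 <- stage_set_phi0(pr$model, 1)
    stage_ramp(m2, du = c(cfg$du, 0, 0), n_steps = 8, hold = -70)$history
  }
  h_mc <- run_short("mc", 1.8e6)    # t0 ignored by MC
  h_emc0 <- run_short("emc", 0)
  expect_equal(h_emc0$F_x, h_mc$F_x, tolerance = 1e-9)
  expect_equal(h_emc0$F_z, h_mc$F_z, tolerance = 1e-9)
})

test_that("sweep collects peaks and records failures without stopping", {
  cfgs <- list(csi_config(law = "mc", n_slide = 6),
               structure(list(law = "mc", phi0 = 1, mu_b = 0.3),
                         class = "csi_config"))  # broken config -> error row
  out <- sweep_peaks(cfgs, mode = "IIa")
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$error[1]))
  expect_false(is.na(out$error[2]))
  expect_gt(out$F_x_max[1], 0)
})

test_that("peak metrics equal the column maxima of the removal stage", {
  h <- csi_history("IIa", "mc")
  pk <- peak_metrics(h, stage = "slide")
  s <- h[h$stage == "slide", ]
  expect_equal(pk$F_x_max, max(s$F_x))
  expect_equal(pk$M_z_max, max(s$M_z))
})
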