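# Finite-strain element technology: material law, residual/tangent
# consistency, frame indifference, and linear-regime verification.

rand_hex <- function(seed = 1, distort = 0.05) {
  set.seed(seed)
  X <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  X <- X[c(1, 2, 4, 3, 5, 6, 8, 7), ]
  X + matrix(runif(24, -distort, distort), 8)
}

test_that("Neo-Hookean stress closed forms", {
  mat <- elastic_params(18e9, 0.3)
  expect_equal(mat$G, 18e9 / 2.6, tolerance = 1e-15)
  expect_equal(mat$Lambda, 2 * mat$G * 0.3 / 0.4, tolerance = 1e-15)
  # stress-free reference
  expect_equal(neo_hookean_stress(diag(3), mat), matrix(0, 3, 3),
               tolerance = 1e-20)
  # uniform dilation: closed-form substitution
  lam <- 1.1
  s <- neo_hookean_stress(lam * diag(3), mat)
  J <- lam^3
  expected <- (mat$Lambda * log(J) / J + mat$G * (lam^2 - 1) / J) * diag(3)
  expect_equal(s, expected, tolerance = 1e-12)
  # small simple shear: sigma_12 ~ G * gamma
  g <- 1e-4
  F <- diag(3); F[1, 2] <- g
  s2 <- neo_hookean_stress(F, mat)
  expect_equal(s2[1, 2], mat$G * g, tolerance = 1e-3)
  expect_equal(s2, t(s2), tolerance = 1e-12)
  expect_error(neo_hookean_stress(-diag(3), mat), "inversion")
})

test_that("element tangent matches finite differences of the residual", {
  X <- rand_hex(3)
  set.seed(4)
  U <- matrix(runif(24, -0.02, 0.02), 8)
  conn <- matrix(1:8, 1)
  mat <- elastic_params(1e6, 0.3)
  r <- osseodebond:::.hex8_assemble_cpp(X, U, conn, mat$G, mat$Lambda, TRUE)
  K <- as.matrix(Matrix::sparseMatrix(i = r$Ki, j = r$Kj, x = r$Kx,
                                      dims = c(24, 24)))
  h <- 1e-7
  Kfd <- matrix(0, 24, 24)
  for (j in 1:24) {
    Up <- U; Up[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] <-
      Up[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] + h
    Um <- U; Um[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] <-
      Um[(j - 1) %/% 3 + 1, (j - 1) %% 3 + 1] - h
    fp <- osseodebond:::.hex8_assemble_cpp(X, Up, conn, mat$G, mat$Lambda, FALSE)$fint
    fm <- osseodebond:::.hex8_assemble_cpp(X, Um, conn, mat$G, mat$Lambda, FALSE)$fint
    Kfd[, j] <- (fp - fm) / (2 * h)
  }
  expect_lt(norm(K - Kfd, "F") / norm(Kfd, "F"), 1e-6)
})

test_that("rigid-body motions produce no internal force", {
  X <- rand_hex(5)
  conn <- matrix(1:8, 1)
  mat <- elastic_params(1e9, 0.25)
  scale <- mat$E  # force scale for the zero checks
  # translation
  Ut <- matrix(rep(c(0.3, -0.2, 0.5), each = 8), 8)
  ft <- osseodebond:::.hex8_assemble_cpp(X, Ut, conn, mat$G, mat$Lambda, FALSE)$fint
  expect_lt(max(abs(ft)) / scale, 1e-12)
  # finite random rotation
  set.seed(8)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- 0.7
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3,
               byrow = TRUE)
  R <- diag(3) + sin(th) * Kx + (1 - cos(th)) * Kx %*% Kx
  Ur <- X %*% t(R) - X
  fr <- osseodebond:::.hex8_assemble_cpp(X, Ur, conn, mat$G, mat$Lambda, FALSE)$fint
  expect_lt(max(abs(fr)) / scale, 1e-12)
})

test_that("uniaxial patch: block under prescribed compression matches linear elasticity", {
  # laterally unconstrained column of 2x2x2 elements, compressed by a small
  # prescribed top displacement: stress and reaction match the linear
  # closed form within 1% at strain 1e-3
  msh <- mesh_block(0.01, 0.01, 0.01, 2, 2, 2)
  E <- 18e9; nu <- 0.3
  law <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, eps_n = 1.8e12,
                                  law = "mc")
  # no contact partner: give the model a dummy far-away master surface
  msh$surfaces$far <- msh$surfaces$bottom
  msh$nsets$base <- msh$nsets$bottom
  m <- bi_model(msh, materials = list("1" = elastic_params(E, nu)),
                slave = "top", master = "far", law = law,
                fixed = "base", driven = "top", ngp = 2)
  strain <- 1e-3
  # uniaxial state: base held vertically, lateral rigid modes suppressed on
  # the two symmetry planes so Poisson contraction stays free
  symx <- which(abs(msh$nodes[, 1]) < 1e-12)
  symy <- which(abs(msh$nodes[, 2]) < 1e-12)
  res <- osseodebond:::newton_solve(
    m, rbind(data.frame(dof = osseodebond:::dofs_of(m$fixed_nodes, 3), value = 0),
             data.frame(dof = osseodebond:::dofs_of(symx, 1), value = 0),
             data.frame(dof = osseodebond:::dofs_of(symy, 2), value = 0),
             data.frame(dof = osseodebond:::dofs_of(m$driven_nodes, 3),
                        value = -strain * 0.01)))
  expect_true(res$ok)
  mdl <- res$model
  r <- reaction_outputs(mdl)
  # uniaxial state (lateral dofs free): F = E * strain * A
  expect_equal(unname(r["F_z"]), -E * strain * 0.01^2, tolerance = 0.01)
  # equal and opposite base reaction
  fb <- mdl$last$fint[osseodebond:::dofs_of(mdl$fixed_nodes, 3)]
  expect_equal(sum(fb), -unname(r["F_z"]), tolerance = 1e-6)
})

test_that("zero-load step leaves the solution unchanged", {
  msh <- mesh_block(0.01, 0.01, 0.01, 2, 2, 2)
  law <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, eps_n = 1.8e12,
                                  law = "mc")
  msh$surfaces$far <- msh$surfaces$bottom
  m <- bi_model(msh, materials = list("1" = elastic_params(1e9, 0.3)),
                slave = "top", master = "far", law = law,
                fixed = "bottom", driven = "top", ngp = 2)
  res <- osseodebond:::newton_solve(
    m, rbind(osseodebond:::clamp_presc(m),
             data.frame(dof = osseodebond:::dofs_of(m$driven_nodes, 3), value = 0)))
  expect_true(res$ok)
  expect_lt(max(abs(res$model$U)), 1e-15)
})
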