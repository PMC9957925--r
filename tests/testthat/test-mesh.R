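# Mesh generators: counts, orientation, surface measures, chord-sag
# compensation, VTK output.

test_that("block mesh has the requested structure and outward surfaces", {
  m <- mesh_block(0.0125, 0.0125, 0.005, 15, 15, 2)
  expect_equal(nrow(m$elems), 450)
  expect_equal(nrow(m$surfaces$top), 225)
  expect_equal(surface_area(m, "top"), 0.0125^2, tolerance = 1e-12)
  # every element has a positive reference Jacobian (assembly would stop)
  expect_no_error(osseodebond:::.hex8_assemble_cpp(
    m$nodes, 0 * m$nodes, m$elems, rep(1, 450), rep(1, 450), FALSE))
  # top facet normals point up
  f <- m$surfaces$top[1, ]
  x <- m$nodes[f, ]
  nrm <- osseodebond:::pracma_cross(x[2, ] - x[1, ], x[4, ] - x[1, ])
  expect_gt(nrm[3], 0)
})

test_that("cylinder mesh: counts and equal-area cross-section", {
  m <- mesh_cylinder(2.5e-3, 3e-3, 3, 2)
  expect_equal(nrow(m$elems), 18)
  expect_equal(nrow(m$surfaces$bottom), 9)
  me <- mesh_cylinder(2.5e-3, 3e-3, 3, 2, equal_area = TRUE)
  expect_equal(surface_area(me, "bottom"), pi * 2.5e-3^2, tolerance = 1e-6)
  # uncorrected polygon under-represents the disc
  expect_lt(surface_area(m, "bottom"), pi * 2.5e-3^2)
})

test_that("cup shell: mean surface radius equals the nominal radius", {
  m <- mesh_cup(25.5e-3, 3e-3, 12, 2)
  r <- osseodebond:::mean_surface_radius(m$nodes, m$surfaces$outer)
  expect_equal(r, 25.5e-3, tolerance = 1e-4)
  # outward orientation: normals point away from the centre
  f <- m$surfaces$outer[5, ]
  x <- m$nodes[f, ]
  nrm <- osseodebond:::pracma_cross(x[2, ] - x[1, ], x[4, ] - x[1, ])
  expect_gt(sum(nrm * colMeans(x)), 0)
})

test_that("socket mesh: cavity radius, clamped bottom, valid elements", {
  m <- mesh_socket(25e-3, 50e-3, 40e-3, 12, 5)
  r <- osseodebond:::mean_surface_radius(m$nodes, m$surfaces$cavity)
  expect_equal(r, 25e-3, tolerance = 1e-4)
  expect_gt(length(m$nsets$bottom), 0)
  expect_true(all(abs(m$nodes[m$nsets$bottom, 3] + 40e-3) < 1e-9))
  expect_no_error(osseodebond:::.hex8_assemble_cpp(
    m$nodes, 0 * m$nodes, m$elems, rep(1, nrow(m$elems)),
    rep(1, nrow(m$elems)), FALSE))
  # cavity facet normals point into the cavity (outward from the bone)
  f <- m$surfaces$cavity[3, ]
  x <- m$nodes[f, ]
  nrm <- osseodebond:::pracma_cross(x[2, ] - x[1, ], x[4, ] - x[1, ])
  expect_lt(sum(nrm * colMeans(x)), 0)
})

test_that("mesh_join offsets nodes and keeps prefixed sets", {
  a <- mesh_block(1, 1, 1, 2, 2, 2)
  b <- mesh_cylinder(0.4, 1, 2, 2)
  j <- mesh_join(a, b, "bone_", "imp_")
  expect_equal(nrow(j$nodes), nrow(a$nodes) + nrow(b$nodes))
  expect_true(all(j$surfaces$imp_bottom > nrow(a$nodes)))
  expect_setequal(names(j$surfaces),
                  c("bone_top", "bone_bottom", "imp_bottom", "imp_top"))
})

test_that("legacy VTK writer emits a parseable unstructured grid", {
  m <- mesh_block(1, 1, 1, 2, 2, 2)
  f <- tempfile(fileext = ".vtk")
  write_vtk(m, f, displacement = 0 * m$nodes,
            point_data = list(phi = rep(0.5, nrow(m$nodes))))
  lines <- readLines(f)
  expect_identical(lines[4], "DATASET UNSTRUCTURED_GRID")
  np <- as.integer(strsplit(lines[5], " ")[[1]][2])
  expect_equal(np, nrow(m$nodes))
  expect_true(any(grepl("^CELL_TYPES 8$", lines)))
  expect_true(any(grepl("^SCALARS phi double 1$", lines)))
})
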