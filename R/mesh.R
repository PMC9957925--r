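#' Hexahedral mesh container
#'
#' A minimal unstructured hex8 mesh: node coordinates, element connectivity,
#' a per-element body tag, named surface patch sets (oriented quad facets)
#' and named node sets for boundary conditions. Facets are stored with
#' outward orientation (the bilinear tangent cross product points out of the
#' body).
#'
#' @param nodes Numeric matrix `n x 3` of coordinates (m).
#' @param elems Integer matrix `m x 8` of node indices (1-based, standard
#'   hex8 ordering: bottom face counter-clockwise, then top face).
#' @param body Integer per-element body tag (length `m`).
#' @param surfaces Named list of `k x 4` facet node-index matrices.
#' @param nsets Named list of node-index vectors.
#' @return An object of class `"hex_mesh"`.
#' @export
hex_mesh <- function(nodes, elems, body = rep(1L, nrow(elems)),
                     surfaces = list(), nsets = list()) {
  stopifnot(ncol(nodes) == 3, ncol(elems) == 8, length(body) == nrow(elems))
  structure(
    list(nodes = as.matrix(nodes), elems = matrix(as.integer(elems), ncol = 8),
         body = as.integer(body), surfaces = surfaces, nsets = nsets),
    class = "hex_mesh"
  )
}

#' @export
print.hex_mesh <- function(x, ...) {
  cat(sprintf("<hex_mesh: %d nodes, %d hex8 elements, %d bodies>\n",
              nrow(x$nodes), nrow(x$elems), length(unique(x$body))))
  if (length(x$surfaces))
    cat("  surfaces:", paste(sprintf("%s[%d]", names(x$surfaces),
                                     vapply(x$surfaces, nrow, 1L)),
                             collapse = ", "), "\n")
  if (length(x$nsets))
    cat("  node sets:", paste(sprintf("%s[%d]", names(x$nsets),
                                      vapply(x$nsets, length, 1L)),
                              collapse = ", "), "\n")
  invisible(x)
}

# structured grid helpers ----------------------------------------------------

grid_hexes <- function(ni, nj, nk) {
  # connectivity of an (ni x nj x nk)-element structured grid whose nodes are
  # indexed id(i,j,k) = i + (j-1)*(ni+1) + (k-1)*(ni+1)*(nj+1)
  id <- function(i, j, k) i + (j - 1L) * (ni + 1L) + (k - 1L) * (ni + 1L) * (nj + 1L)
  e <- matrix(0L, ni * nj * nk, 8)
  n <- 0L
  for (k in seq_len(nk)) for (j in seq_len(nj)) for (i in seq_len(ni)) {
    n <- n + 1L
    e[n, ] <- c(id(i, j, k), id(i + 1L, j, k), id(i + 1L, j + 1L, k), id(i, j + 1L, k),
                id(i, j, k + 1L), id(i + 1L, j, k + 1L), id(i + 1L, j + 1L, k + 1L),
                id(i, j + 1L, k + 1L))
  }
  e
}

flip_hexes <- function(e) e[, c(5:8, 1:4), drop = FALSE]

ref_jacobian_sign <- function(nodes, elem) {
  # trilinear Jacobian at the element centre
  x <- nodes[elem, ]
  dxi <- colMeans(x[c(2, 3, 6, 7), ]) - colMeans(x[c(1, 4, 5, 8), ])
  deta <- colMeans(x[c(3, 4, 7, 8), ]) - colMeans(x[c(1, 2, 5, 6), ])
  dze <- colMeans(x[5:8, ]) - colMeans(x[1:4, ])
  det(cbind(dxi, deta, dze) / 2)
}

orient_hexes <- function(nodes, elems) {
  if (ref_jacobian_sign(nodes, elems[1, ]) < 0) flip_hexes(elems) else elems
}

#' Structured block mesh
#'
#' Axis-aligned rectangular block meshed with `nx x ny x nz` hex8 elements.
#' Provides surfaces `"top"` (outward +z) and `"bottom"` (outward -z) and
#' node sets `"top"`, `"bottom"`.
#'
#' @param lx,ly,lz Edge lengths (m).
#' @param nx,ny,nz Element counts per direction.
#' @param centre Centre of the top face, length-3; the block extends
#'   downwards (`z` from `centre[3]-lz` to `centre[3]`).
#' @param body Body tag.
#' @return A [hex_mesh()].
#' @export
mesh_block <- function(lx, ly, lz, nx, ny, nz, centre = c(0, 0, 0), body = 1L) {
  xs <- seq(-lx / 2, lx / 2, length.out = nx + 1) + centre[1]
  ys <- seq(-ly / 2, ly / 2, length.out = ny + 1) + centre[2]
  zs <- seq(-lz, 0, length.out = nz + 1) + centre[3]
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  elems <- grid_hexes(nx, ny, nz)
  id <- function(i, j, k) i + (j - 1L) * (nx + 1L) + (k - 1L) * (nx + 1L) * (ny + 1L)
  top <- matrix(0L, nx * ny, 4); bot <- matrix(0L, nx * ny, 4)
  n <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    n <- n + 1L
    top[n, ] <- c(id(i, j, nz + 1L), id(i + 1L, j, nz + 1L),
                  id(i + 1L, j + 1L, nz + 1L), id(i, j + 1L, nz + 1L))
    bot[n, ] <- c(id(i, j, 1L), id(i, j + 1L, 1L),
                  id(i + 1L, j + 1L, 1L), id(i + 1L, j, 1L))
  }
  kbot <- which(abs(nodes[, 3] - (centre[3] - lz)) < 1e-12)
  ktop <- which(abs(nodes[, 3] - centre[3]) < 1e-12)
  hex_mesh(nodes, orient_hexes(nodes, elems), rep(as.integer(body), nrow(elems)),
           surfaces = list(top = top, bottom = bot),
           nsets = list(top = ktop, bottom = kbot))
}

# smooth square -> disc map (elliptical), orientation preserving
square_to_disc <- function(a, b) {
  cbind(a * sqrt(pmax(0, 1 - b^2 / 2)), b * sqrt(pmax(0, 1 - a^2 / 2)))
}

#' Structured cylinder mesh
#'
#' Solid circular cylinder meshed by mapping an `n x n` square grid onto the
#' disc cross-section and extruding `nz` layers along z. Surfaces `"bottom"`
#' (outward -z) and `"top"`; node sets `"top"`, `"bottom"`.
#'
#' @param R Radius (m).
#' @param H Height (m).
#' @param n In-plane grid subdivisions (gives `n^2` elements per layer).
#' @param nz Number of layers.
#' @param base Length-3 centre of the bottom face.
#' @param body Body tag.
#' @param equal_area If `TRUE`, scale the cross-section so the polygonal
#'   boundary encloses exactly `pi R^2`: the facet polygon is a chordal
#'   approximation of the circle and would otherwise under-represent the
#'   contact area of the face.
#' @return A [hex_mesh()].
#' @export
mesh_cylinder <- function(R, H, n, nz, base = c(0, 0, 0), body = 1L,
                          equal_area = FALSE) {
  s <- seq(-1, 1, length.out = n + 1)
  g <- expand.grid(a = s, b = s)
  xy <- square_to_disc(g$a, g$b) * R
  if (equal_area) {
    # area of the mapped polygon via the shoelace formula on its boundary
    ring <- ring_indices(n + 1L)
    bx <- xy[ring, 1]; by <- xy[ring, 2]
    A <- 0.5 * abs(sum(bx * c(by[-1], by[1]) - c(bx[-1], bx[1]) * by))
    xy <- xy * sqrt(pi * R^2 / A)
  }
  zs <- seq(0, H, length.out = nz + 1)
  nodes <- do.call(rbind, lapply(zs, function(z)
    cbind(xy[, 1] + base[1], xy[, 2] + base[2], z + base[3])))
  elems <- grid_hexes(n, n, nz)
  id <- function(i, j, k) i + (j - 1L) * (n + 1L) + (k - 1L) * (n + 1L) * (n + 1L)
  bot <- matrix(0L, n * n, 4); top <- matrix(0L, n * n, 4)
  m <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    m <- m + 1L
    bot[m, ] <- c(id(i, j, 1L), id(i, j + 1L, 1L), id(i + 1L, j + 1L, 1L), id(i + 1L, j, 1L))
    top[m, ] <- c(id(i, j, nz + 1L), id(i + 1L, j, nz + 1L),
                  id(i + 1L, j + 1L, nz + 1L), id(i, j + 1L, nz + 1L))
  }
  npl <- (n + 1L)^2
  hex_mesh(nodes, orient_hexes(nodes, elems), rep(as.integer(body), nrow(elems)),
           surfaces = list(bottom = bot, top = top),
           nsets = list(bottom = seq_len(npl),
                        top = nz * npl + seq_len(npl)))
}

# directions of the lower hemisphere parameterised over the unit square,
# pole-singularity free (disc map in the middle)
hemi_directions <- function(a, b) {
  pq <- square_to_disc(a, b)
  s <- sqrt(rowSums(pq^2))
  th <- s * pi / 2
  phi <- atan2(pq[, 2], pq[, 1])
  cbind(sin(th) * cos(phi), sin(th) * sin(phi), -cos(th))
}

#' Hemispherical shell mesh (acetabular cup)
#'
#' Lower-hemisphere shell between radii `R_out - thickness` and `R_out`,
#' centred at `centre`, meshed with an `n x n` surface grid (cubed-sphere
#' style, no pole degeneracy) and `nl` radial layers. Surfaces: `"outer"`
#' (the contacting spherical surface, outward from the shell) and node set
#' `"inner"` (inner-surface nodes, used as the rigid driver attachment).
#'
#' @param R_out Outer radius (m).
#' @param thickness Shell thickness (m).
#' @param n Surface grid subdivisions.
#' @param nl Radial layers.
#' @param centre Sphere centre, length-3.
#' @param body Body tag.
#' @param correct_radius If `TRUE` (default), inflate the vertex radii so
#'   the area-weighted mean radius of the bilinear outer surface equals
#'   `R_out`: facets are chords of the sphere and would otherwise make the
#'   discrete surface systematically undersized, which directly biases an
#'   interference fit.
#' @param rim_exp Surface-grid grading exponent; values `> 1` concentrate
#'   the grid rings towards the equator (rim contact region).
#' @return A [hex_mesh()].
#' @export
mesh_cup <- function(R_out, thickness, n, nl = 2, centre = c(0, 0, 0),
                     body = 1L, correct_radius = TRUE, rim_exp = 1) {
  s <- seq(-1, 1, length.out = n + 1)
  g <- expand.grid(a = s, b = s)
  pq <- square_to_disc(g$a, g$b)
  sr <- sqrt(rowSums(pq^2))
  if (rim_exp != 1) sr <- 1 - (1 - sr)^rim_exp
  th <- pmin(sr, 1) * pi / 2
  phi <- atan2(pq[, 2], pq[, 1])
  d <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), -cos(th))
  if (correct_radius) {
    fac <- surf_sheet_facets(n)
    R_out <- R_out / mean_surface_radius(d * R_out, fac) * R_out
  }
  radii <- seq(R_out - thickness, R_out, length.out = nl + 1)
  nodes <- do.call(rbind, lapply(radii, function(r)
    sweep(d * r, 2, centre, "+")))
  elems <- grid_hexes(n, n, nl)
  id <- function(i, j, k) i + (j - 1L) * (n + 1L) + (k - 1L) * (n + 1L) * (n + 1L)
  outer <- matrix(0L, n * n, 4)
  m <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    m <- m + 1L
    outer[m, ] <- c(id(i, j, nl + 1L), id(i + 1L, j, nl + 1L),
                    id(i + 1L, j + 1L, nl + 1L), id(i, j + 1L, nl + 1L))
  }
  npl <- (n + 1L)^2
  msh <- hex_mesh(nodes, orient_hexes(nodes, elems),
                  rep(as.integer(body), nrow(elems)),
                  surfaces = list(outer = outer),
                  nsets = list(inner = seq_len(npl),
                               all = seq_len(nrow(nodes))))
  # ensure outer facets point away from the centre
  f <- msh$surfaces$outer[1, ]
  x <- msh$nodes[f, ]
  nrm <- pracma_cross(x[2, ] - x[1, ], x[4, ] - x[1, ])
  if (sum(nrm * (colMeans(x) - centre)) < 0)
    msh$surfaces$outer <- msh$surfaces$outer[, 4:1]
  msh
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3], u[1] * v[2] - u[2] * v[1])
}

#' Bone block with a hemispherical socket
#'
#' Cylindrical bone block (radius `R_cyl`, height `H`) whose top surface
#' carries a hemispherical cavity of radius `R_cav` centred at the origin of
#' the top plane. The solid is star-shaped with respect to the cavity centre
#' and is meshed by radial rays: an `n x n` hemisphere surface grid times
#' `nl` geometrically graded radial layers (finest at the cavity surface).
#' Surfaces: `"cavity"` (outward = into the cavity) and `"annulus"` (the flat
#' top ring between cavity rim and outer radius, outward +z, restricted to
#' `annulus_rmax`). Node set `"bottom"` holds the nodes on the bottom face.
#'
#' @param R_cav Cavity radius (m).
#' @param R_cyl Cylinder radius (m).
#' @param H Cylinder height (m).
#' @param n Hemisphere surface grid subdivisions.
#' @param nl Radial layers.
#' @param grading Geometric grading ratio of consecutive radial layers.
#' @param annulus_rmax Radial extent of the contact-candidate annulus facets.
#' @param body Body tag.
#' @param correct_radius If `TRUE` (default), inflate the cavity vertex
#'   radii so the area-weighted mean radius of the bilinear cavity surface
#'   equals `R_cav` (chord-sag compensation, see [mesh_cup()]).
#' @param fillet Radius of the fillet rounding the cavity rim (m); `0`
#'   leaves the sharp edge. The fillet arc is tangent to the cavity sphere
#'   and to the flat top, and is part of the cavity contact surface.
#' @param rim_exp Surface-grid grading exponent: values `> 1` concentrate
#'   the rings of the hemisphere grid towards the rim, where the press-fit
#'   contact forces vary most strongly.
#' @return A [hex_mesh()].
#' @export
mesh_socket <- function(R_cav, R_cyl, H, n, nl, grading = 1.6,
                        annulus_rmax = 1.25 * R_cav, body = 1L,
                        correct_radius = TRUE, fillet = 0, rim_exp = 1) {
  s <- seq(-1, 1, length.out = n + 1)
  g <- expand.grid(a = s, b = s)
  pq <- square_to_disc(g$a, g$b)
  sr <- sqrt(rowSums(pq^2))
  if (rim_exp != 1) sr <- 1 - (1 - sr)^rim_exp
  th <- pmin(sr, 1) * pi / 2
  phi <- atan2(pq[, 2], pq[, 1])
  d <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), -cos(th))
  if (correct_radius) {
    fac <- surf_sheet_facets(n)
    R_cav <- R_cav / mean_surface_radius(d * R_cav, fac) * R_cav
  }
  # cavity surface profile: sphere, blended into the top plane by the fillet
  R_s <- rep(R_cav, nrow(d))
  if (fillet > 0) {
    rho_c <- sqrt((R_cav + fillet)^2 - fillet^2)
    # fillet-arc centre ring at (rho_c, -fillet); tangent polar angle
    th_t <- atan2(rho_c, fillet)
    on_f <- th > th_t
    if (any(on_f)) {
      m <- sin(th[on_f]) * rho_c + cos(th[on_f]) * fillet  # d . C_f
      disc <- pmax(0, m^2 - ((R_cav + fillet)^2 - fillet^2))
      R_s[on_f] <- m - sqrt(disc)
    }
  }
  # ray length to the cylinder boundary (side wall or bottom)
  sth <- sqrt(d[, 1]^2 + d[, 2]^2)
  cth <- -d[, 3]
  L <- pmin(ifelse(sth > 1e-12, R_cyl / sth, Inf),
            ifelse(cth > 1e-12, H / cth, Inf))
  # graded radial stations: t_k in [0,1], finest near the cavity
  r <- grading^(0:nl); t <- cumsum(c(0, r[-length(r)])) / sum(r[-length(r)])
  nodes <- do.call(rbind, lapply(t, function(tk)
    d * (R_s + tk * (L - R_s))))
  elems <- grid_hexes(n, n, nl)
  id <- function(i, j, k) i + (j - 1L) * (n + 1L) + (k - 1L) * (n + 1L) * (n + 1L)
  cav <- matrix(0L, n * n, 4)
  m <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    m <- m + 1L
    cav[m, ] <- c(id(i, j, 1L), id(i + 1L, j, 1L),
                  id(i + 1L, j + 1L, 1L), id(i, j + 1L, 1L))
  }
  # flat top annulus: boundary columns of the (i,j) grid, all radial layers
  bnd <- which(abs(g$a) == 1 | abs(g$b) == 1)
  ann <- list()
  # boundary traversal in order: collect boundary (i,j) in a ring
  ring <- ring_indices(n + 1L)
  for (k in seq_len(nl)) {
    for (q in seq_len(length(ring))) {
      q2 <- if (q == length(ring)) 1L else q + 1L
      i1 <- ring[[q]]; i2 <- ring[[q2]]
      n1 <- i1 + (k - 1L) * (n + 1L)^2
      n2 <- i2 + (k - 1L) * (n + 1L)^2
      n3 <- i2 + k * (n + 1L)^2
      n4 <- i1 + k * (n + 1L)^2
      ann[[length(ann) + 1L]] <- c(n1, n2, n3, n4)
    }
  }
  ann <- do.call(rbind, ann)
  elems <- orient_hexes(nodes, elems)
  msh <- hex_mesh(nodes, elems, rep(as.integer(body), nrow(elems)))
  # orient cavity facets toward the centre (outward from the bone)
  f <- cav[1, ]; x <- nodes[f, ]
  nrm <- pracma_cross(x[2, ] - x[1, ], x[4, ] - x[1, ])
  if (sum(nrm * colMeans(x)) > 0) cav <- cav[, 4:1]
  # orient annulus facets to +z and keep those within annulus_rmax
  f <- ann[1, ]; x <- nodes[f, ]
  nrm <- pracma_cross(x[2, ] - x[1, ], x[4, ] - x[1, ])
  if (nrm[3] < 0) ann <- ann[, 4:1]
  cen_r <- apply(ann, 1, function(f) {
    x <- nodes[f, ]; sqrt(sum(colMeans(x)[1:2]^2))
  })
  ann <- ann[cen_r <= annulus_rmax, , drop = FALSE]
  if (!nrow(ann)) ann <- matrix(integer(0), 0, 4)
  msh$surfaces <- list(cavity = cav, annulus = ann)
  msh$nsets <- list(bottom = which(abs(nodes[, 3] + H) < 1e-9))
  msh
}

# facet connectivity of one (n+1) x (n+1) structured node sheet
surf_sheet_facets <- function(n) {
  id <- function(i, j) i + (j - 1L) * (n + 1L)
  f <- matrix(0L, n * n, 4)
  m <- 0L
  for (j in seq_len(n)) for (i in seq_len(n)) {
    m <- m + 1L
    f[m, ] <- c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L), id(i, j + 1L))
  }
  f
}

# area-weighted mean distance of a bilinear facet sheet from the origin
mean_surface_radius <- function(coords, facets, ngp = 3) {
  quad <- facet_quadrature(ngp)
  wA <- facet_weights(coords, facets, quad)
  r <- numeric(length(wA))
  k <- 0
  for (f in seq_len(nrow(facets))) {
    x <- coords[facets[f, ], , drop = FALSE]
    for (g in seq_len(quad$n)) {
      k <- k + 1
      r[k] <- sqrt(sum((quad$N[g, ] %*% x)^2))
    }
  }
  sum(wA * r) / sum(wA)
}

# indices of the boundary ring of an (np x np) node sheet, counter-clockwise
ring_indices <- function(np) {
  id <- function(i, j) i + (j - 1L) * np
  c(sapply(1:(np - 1L), function(i) id(i, 1L)),
    sapply(1:(np - 1L), function(j) id(np, j)),
    sapply(np:2L, function(i) id(i, np)),
    sapply(np:2L, function(j) id(1L, j)))
}

#' Join two meshes into one
#'
#' Concatenates nodes, elements, surfaces and node sets; surface and set
#' names are prefixed to stay unique.
#'
#' @param a,b [hex_mesh()] objects.
#' @param prefix_a,prefix_b Name prefixes (default `"a_"`, `"b_"`).
#' @return A [hex_mesh()].
#' @export
mesh_join <- function(a, b, prefix_a = "a_", prefix_b = "b_") {
  off <- nrow(a$nodes)
  nodes <- rbind(a$nodes, b$nodes)
  elems <- rbind(a$elems, b$elems + off)
  body <- c(a$body, b$body)
  sa <- setNames(a$surfaces, paste0(prefix_a, names(a$surfaces)))
  sb <- setNames(lapply(b$surfaces, function(s) s + off),
                 paste0(prefix_b, names(b$surfaces)))
  na <- setNames(a$nsets, paste0(prefix_a, names(a$nsets)))
  nb <- setNames(lapply(b$nsets, function(s) s + off),
                 paste0(prefix_b, names(b$nsets)))
  hex_mesh(nodes, elems, body, surfaces = c(sa, sb), nsets = c(na, nb))
}

# facet quadrature -----------------------------------------------------------

gauss_1d <- function(n) {
  # Golub-Welsch via symmetric tridiagonal eigen decomposition
  if (n == 1) return(list(x = 0, w = 2))
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

facet_quadrature <- function(ngp = 5) {
  q <- gauss_1d(ngp)
  g <- expand.grid(xi = q$x, eta = q$x)
  w <- as.vector(outer(q$w, q$w))
  N <- cbind(0.25 * (1 - g$xi) * (1 - g$eta), 0.25 * (1 + g$xi) * (1 - g$eta),
             0.25 * (1 + g$xi) * (1 + g$eta), 0.25 * (1 - g$xi) * (1 + g$eta))
  dNxi <- cbind(-0.25 * (1 - g$eta), 0.25 * (1 - g$eta),
                0.25 * (1 + g$eta), -0.25 * (1 + g$eta))
  dNeta <- cbind(-0.25 * (1 - g$xi), -0.25 * (1 + g$xi),
                 0.25 * (1 + g$xi), 0.25 * (1 - g$xi))
  list(N = N, dNxi = dNxi, dNeta = dNeta, w = w, n = nrow(N))
}

# reference area weight for every gauss point of every facet
facet_weights <- function(nodes, facets, quad) {
  nf <- nrow(facets)
  wA <- numeric(nf * quad$n)
  for (f in seq_len(nf)) {
    x <- nodes[facets[f, ], , drop = FALSE]
    for (g in seq_len(quad$n)) {
      a1 <- quad$dNxi[g, ] %*% x
      a2 <- quad$dNeta[g, ] %*% x
      wA[(f - 1) * quad$n + g] <- sqrt(sum(pracma_cross(a1, a2)^2)) * quad$w[g]
    }
  }
  wA
}

# per-facet flags of free (unshared) boundary edges, local edge order
# 1:(1-2), 2:(2-3), 3:(3-4), 4:(4-1)
facet_boundary_edges <- function(facets) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eks <- c(key(facets[, 1], facets[, 2]), key(facets[, 2], facets[, 3]),
           key(facets[, 3], facets[, 4]), key(facets[, 4], facets[, 1]))
  cnt <- table(eks)
  matrix(cnt[eks] == 1L, ncol = 4)
}

#' Total area of a facet set
#' @param mesh A [hex_mesh()].
#' @param surface Surface name.
#' @param ngp Gauss points per direction.
#' @return Area (m^2).
#' @export
surface_area <- function(mesh, surface, ngp = 5) {
  quad <- facet_quadrature(ngp)
  sum(facet_weights(mesh$nodes, mesh$surfaces[[surface]], quad))
}

#' Write a mesh (with optional point data) as legacy ASCII VTK
#'
#' Minimal unstructured-grid writer for visual inspection of deformed
#' configurations and interface fields in ParaView.
#'
#' @param mesh A [hex_mesh()].
#' @param path Output file.
#' @param displacement Optional `n x 3` displacement added as a vector field.
#' @param point_data Optional named list of per-node scalar vectors.
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, path, displacement = NULL, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "osseodebond mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)), con)
  coords <- mesh$nodes
  if (!is.null(displacement)) coords <- coords + displacement
  write(t(coords), con, ncolumns = 3)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  write(t(cbind(8L, mesh$elems - 1L)), con, ncolumns = 9)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  write(rep(12L, m), con, ncolumns = 10)
  if (length(point_data) || !is.null(displacement)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    if (!is.null(displacement)) {
      writeLines("VECTORS displacement double", con)
      write(t(displacement), con, ncolumns = 3)
    }
    for (nm in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      write(point_data[[nm]], con, ncolumns = 6)
    }
  }
  invisible(path)
}
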