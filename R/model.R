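#' Assemble a bone-implant contact model
#'
#' Combines a mesh, per-body elastic materials, one master-slave contact
#' pair carrying the adhesive-frictional law, and the boundary/driver node
#' sets into the state object advanced by the staged solvers. The slave
#' surface (which carries the per-quadrature-point bonding states) belongs
#' to the bone; the implant surface is the master.
#'
#' @param mesh A [hex_mesh()].
#' @param materials Named list mapping body tag (as character) to
#'   [elastic_params()].
#' @param slave,master Surface names in `mesh$surfaces`. `slave` may be a
#'   character vector (facet sets are concatenated).
#' @param law An [adhesive_friction_params()] object.
#' @param phi0 Initial osseointegration applied to the slave points (used
#'   when a `set_phi0` stage runs; points start unbonded).
#' @param fixed Node-set name(s) fully clamped.
#' @param driven Node-set name of the driven (loaded) surface.
#' @param interface Optional logical per slave facet marking the nominal
#'   bone-implant interface for the area-weighted mean bonding; defaults to
#'   all slave facets.
#' @param ngp Contact Gauss points per facet direction (default 5).
#' @param opts Solver options, see [solver_options()].
#' @return An object of class `"bi_model"`.
#' @export
bi_model <- function(mesh, materials, slave, master, law, phi0 = 0,
                     fixed, driven, interface = NULL, ngp = 5,
                     opts = solver_options()) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(law, "afp"))
  Gv <- Lv <- numeric(nrow(mesh$elems))
  for (tag in unique(mesh$body)) {
    m <- materials[[as.character(tag)]]
    if (is.null(m)) stop("no material for body ", tag)
    Gv[mesh$body == tag] <- m$G
    Lv[mesh$body == tag] <- m$Lambda
  }
  sfac <- do.call(rbind, lapply(slave, function(s) mesh$surfaces[[s]]))
  mfac <- mesh$surfaces[[master]]
  if (is.null(sfac) || is.null(mfac)) stop("unknown contact surface name")
  quad <- facet_quadrature(ngp)
  wA <- facet_weights(mesh$nodes, sfac, quad)
  if (is.null(interface)) interface <- rep(TRUE, nrow(sfac))
  npts <- nrow(sfac) * quad$n
  st <- bond_state_init(npts, 0, law)   # unbonded until a set_phi0 stage
  st$anchor_facet <- 0L
  st$anchor_xi <- 0
  st$anchor_eta <- 0
  fixed_nodes <- sort(unique(unlist(mesh$nsets[fixed])))
  driven_nodes <- sort(unique(mesh$nsets[[driven]]))
  structure(list(
    mesh = mesh, Gv = Gv, Lv = Lv, law = law, phi0_target = phi0,
    contact = list(sfac = sfac, mfac = mfac,
                   mbnd = facet_boundary_edges(mfac),
                   quad = quad, wA = wA,
                   point_interface = rep(interface, each = quad$n)),
    state = st,
    U = matrix(0, nrow(mesh$nodes), 3),
    fixed_nodes = fixed_nodes, driven_nodes = driven_nodes,
    driven_ref = mesh$nodes[driven_nodes, , drop = FALSE],
    driven_u = c(0, 0, 0), driven_theta = 0,
    opts = opts, last = NULL
  ), class = "bi_model")
}

#' @export
print.bi_model <- function(x, ...) {
  cat(sprintf("<bi_model: %d nodes, %d elements, %d contact points, law %s>\n",
              nrow(x$mesh$nodes), nrow(x$mesh$elems), nrow(x$state),
              toupper(x$law$law)))
  invisible(x)
}

#' Nonlinear solver options
#'
#' @param tol_rel Relative residual tolerance of the Newton loop.
#' @param tol_abs Absolute residual floor (N).
#' @param tol_stall Secondary acceptance tolerance: penalty frictional
#'   contact can settle into a tiny stick-slip limit cycle in which the
#'   residual stagnates instead of contracting to `tol_rel`; an iterate
#'   whose residual has stopped improving is accepted once it is below
#'   `tol_stall` relative to the load scale.
#' @param max_iter Maximum Newton iterations per step.
#' @param bisect_depth Maximum recursive step halvings on non-convergence.
#' @return A list of options.
#' @export
solver_options <- function(tol_rel = 1e-8, tol_abs = 1e-9, tol_stall = 1e-4,
                           max_iter = 40, bisect_depth = 4) {
  list(tol_rel = tol_rel, tol_abs = tol_abs, tol_stall = tol_stall,
       max_iter = max_iter, bisect_depth = bisect_depth)
}

law_par_list <- function(law) {
  law[c("a_s", "b_s", "mu_ub", "mu_b", "t0", "g0", "g_b",
        "eps_n", "eps_t", "law")]
}

#' Area-weighted mean bonding state of the interface
#'
#' @param model A [bi_model()].
#' @return Mean `phi` over the interface quadrature points, weighted by
#'   their reference area.
#' @export
mean_bonding <- function(model) {
  w <- model$contact$wA * model$contact$point_interface
  if (sum(w) <= 0) stop("empty interface")
  sum(w * model$state$phi) / sum(w)
}

#' Reaction resultants on the driven node set
#'
#' Sums the internal nodal forces over the driven nodes of the last
#' converged state: the force the rest of the structure exerts on the
#' driver, i.e. the applied load. The torque is taken about the vertical
#' axis through the reference centroid of the driven set.
#'
#' @param model A [bi_model()] after at least one solved step.
#' @return Named numeric: `F_x`, `F_y`, `F_z`, `M_z` (N, N m).
#' @export
reaction_outputs <- function(model) {
  if (is.null(model$last)) return(c(F_x = 0, F_y = 0, F_z = 0, M_z = 0))
  fi <- model$last$fint
  dn <- model$driven_nodes
  fx <- fi[3 * (dn - 1) + 1]; fy <- fi[3 * (dn - 1) + 2]; fz <- fi[3 * (dn - 1) + 3]
  cen <- colMeans(model$driven_ref)
  x <- model$mesh$nodes[dn, 1] + model$U[dn, 1] - cen[1]
  y <- model$mesh$nodes[dn, 2] + model$U[dn, 2] - cen[2]
  c(F_x = sum(fx), F_y = sum(fy), F_z = sum(fz),
    M_z = sum(x * fy - y * fx))
}
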