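# Newton-Raphson driver with prescribed-displacement / constraint reduction.
#
# A load step is defined by
#   * presc: data frame (dof, value) of absolute prescribed displacements at
#     the end of the step,
#   * cons:  list of generalized constraint columns, each
#     list(dofs, coefs, value, force): the listed dofs move as
#     u[dofs] = base[dofs] + coefs * q with one shared unknown q (value = NA)
#     or prescribed q (value set); `force` is an external work-conjugate load.
# Free dofs are every remaining dof not clamped.

build_reduction <- function(ndof, presc_dofs, cons) {
  used <- presc_dofs
  for (cc in cons) used <- c(used, cc$dofs)
  free <- setdiff(seq_len(ndof), used)
  ncol_c <- sum(vapply(cons, function(cc) is.na(cc$value), TRUE))
  nred <- length(free) + ncol_c
  ii <- free; jj <- seq_along(free); xx <- rep(1, length(free))
  fred <- numeric(nred)
  col <- length(free)
  for (cc in cons) {
    if (is.na(cc$value)) {
      col <- col + 1
      ii <- c(ii, cc$dofs); jj <- c(jj, rep(col, length(cc$dofs)))
      xx <- c(xx, cc$coefs)
      if (!is.null(cc$force)) fred[col] <- cc$force
    }
  }
  T <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, nred))
  list(T = T, free = free, fred = fred)
}

assemble_all <- function(model, want_K) {
  msh <- model$mesh
  hx <- .hex8_assemble_cpp(msh$nodes, model$U, msh$elems, model$Gv, model$Lv,
                           want_K)
  if (hx$minJ <= 0) return(list(ok = FALSE))
  ct <- .contact_assemble_cpp(msh$nodes + model$U,
                              model$contact$sfac, model$contact$mfac,
                              model$contact$mbnd, model$contact$quad$N,
                              model$contact$wA,
                              list(phi0 = model$state$phi0,
                                   phi = model$state$phi,
                                   anchor_facet = as.integer(model$state$anchor_facet),
                                   anchor_xi = model$state$anchor_xi,
                                   anchor_eta = model$state$anchor_eta),
                              law_par_list(model$law), want_K)
  out <- list(ok = TRUE, fint = hx$fint + ct$fc, ct = ct)
  if (want_K) {
    ndof <- 3 * nrow(msh$nodes)
    out$K <- Matrix::sparseMatrix(
      i = c(hx$Ki, ct$Ki), j = c(hx$Kj, ct$Kj), x = c(hx$Kx, ct$Kx),
      dims = c(ndof, ndof)
    )
  }
  out
}

# Newton iteration on the reduced system. The tangent is factored on the
# first iteration and reused while the residual keeps contracting; it is
# re-assembled whenever convergence stalls (contact status changes).
newton_core <- function(model, red) {
  opts <- model$opts
  ref <- NULL
  lufac <- NULL
  rn_prev <- Inf
  rn_best <- Inf
  stall <- 0L
  for (it in seq_len(opts$max_iter)) {
    need_K <- is.null(lufac)
    asm <- assemble_all(model, want_K = need_K)
    if (!asm$ok) return(list(ok = FALSE, model = model, reason = "element inversion"))
    fint_red <- as.vector(Matrix::crossprod(red$T, asm$fint))
    r_red <- red$fred - fint_red
    rn <- sqrt(sum(r_red^2))
    if (is.null(ref))
      ref <- max(sqrt(sum(red$fred^2)), sqrt(sum(fint_red^2)), rn, 1)
    stall <- if (rn > 0.8 * rn_best) stall + 1L else 0L
    rn_best <- min(rn_best, rn)
    converged <- rn <= opts$tol_rel * ref + opts$tol_abs ||
      (stall >= 3L && rn <= opts$tol_stall * ref) ||
      (it > 15L && rn <= opts$tol_stall * ref) ||
      (it > 30L && rn <= 10 * opts$tol_stall * ref)
    if (converged) {
      model$last <- list(fint = asm$fint, ct = asm$ct, resid = rn)
      return(list(ok = TRUE, model = model, iters = it))
    }
    if (!need_K && rn > 0.25 * rn_prev) {
      # slow contraction with the frozen tangent: reassemble and refactor
      asm <- assemble_all(model, want_K = TRUE)
      if (!asm$ok) return(list(ok = FALSE, model = model, reason = "element inversion"))
      need_K <- TRUE
    }
    if (need_K) {
      Kred <- Matrix::crossprod(red$T, asm$K %*% red$T)
      # the assembled tangent is symmetric by construction (symmetrised slip
      # tangent); supernodal Cholesky is much faster than sparse LU, with LU
      # as the fallback for indefinite tangents (cohesive softening)
      lufac <- tryCatch(
        Matrix::Cholesky(Matrix::forceSymmetric(Kred), LDL = FALSE,
                         super = TRUE, perm = TRUE),
        warning = function(w) NULL, error = function(e) NULL)
      if (is.null(lufac))
        lufac <- tryCatch(Matrix::lu(Kred), error = function(e) NULL)
      if (is.null(lufac))
        return(list(ok = FALSE, model = model, reason = "singular system"))
    }
    du <- tryCatch(as.vector(Matrix::solve(lufac, r_red)),
                   error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du)))
      return(list(ok = FALSE, model = model, reason = "singular system"))
    uv <- as.vector(t(model$U)) + as.vector(red$T %*% du)
    model$U <- matrix(uv, ncol = 3, byrow = TRUE)
    rn_prev <- rn
  }
  if (isTRUE(getOption("osseodebond.verbose")))
    message(sprintf("  newton: no convergence after %d iters (last |r| = %.3e, ref %.3e)",
                    opts$max_iter, rn_prev, ref))
  list(ok = FALSE, model = model, reason = "no convergence")
}

# one Newton solve to the prescribed state; does not commit contact history
newton_solve <- function(model, presc, cons = list()) {
  ndof <- 3 * nrow(model$mesh$nodes)
  red <- build_reduction(ndof, presc$dof, cons)
  uv <- as.vector(t(model$U))   # dof-major: 3*(i-1)+c
  uv[presc$dof] <- presc$value
  base <- uv
  for (cc in cons) if (!is.na(cc$value)) uv[cc$dofs] <- base[cc$dofs] + cc$coefs * cc$value
  model$U <- matrix(uv, ncol = 3, byrow = TRUE)
  newton_core(model, red)
}

# commit contact history after a converged step (damage accumulation cadence:
# once per converged load step)
commit_state <- function(model) {
  ct <- model$last$ct
  st <- model$state
  act <- ct$status > 0L
  st$g_s[act] <- st$g_s[act] + ct$slip_inc[act]
  st$g_sn[act] <- st$g_sn[act] + abs(ct$g_n[act] - st$g_en_prev[act])
  st$g_en_prev[act] <- ct$g_n[act]
  st$g_d <- st$g_s + st$g_sn
  st$phi <- state_function(st$g_d, st$phi0, model$law$a_s, model$law$b_s)
  st$status <- c("open", "stick", "slip")[ct$status + 1L]
  st$anchor_facet <- ct$anchor_facet
  st$anchor_xi <- ct$anchor_xi
  st$anchor_eta <- ct$anchor_eta
  model$state <- st
  model
}

# recursive step bisection
solve_and_commit <- function(model, presc_at, cons_at, depth = NULL) {
  if (is.null(depth)) depth <- model$opts$bisect_depth
  attempt <- newton_solve(model, presc_at(1), cons_at(1))
  if (attempt$ok) return(commit_state(attempt$model))
  if (depth <= 0)
    stop("load step failed to converge (", attempt$reason, ")")
  half <- solve_and_commit(model, function(f) presc_at(f / 2),
                           function(f) cons_at(f / 2), depth - 1)
  solve_and_commit(half, function(f) presc_at(1 / 2 + f / 2),
                   function(f) cons_at(1 / 2 + f / 2), depth - 1)
}

# dof helpers ---------------------------------------------------------------
dofs_of <- function(nodes, comp) 3 * (nodes - 1) + comp

clamp_presc <- function(model) {
  fx <- model$fixed_nodes
  data.frame(dof = c(dofs_of(fx, 1), dofs_of(fx, 2), dofs_of(fx, 3)),
             value = 0)
}

# prescribed driven-set positions for translation u (3-vec) + rotation theta
# about the vertical axis through the driven centroid (reference coords)
driven_presc <- function(model, u, theta, hold_z = FALSE) {
  dn <- model$driven_nodes
  X <- model$driven_ref
  cen <- colMeans(X)
  ct <- cos(theta); stn <- sin(theta)
  xr <- cen[1] + ct * (X[, 1] - cen[1]) - stn * (X[, 2] - cen[2])
  yr <- cen[2] + stn * (X[, 1] - cen[1]) + ct * (X[, 2] - cen[2])
  ux <- xr - X[, 1] + u[1]
  uy <- yr - X[, 2] + u[2]
  uz <- rep(u[3], length(dn))
  d <- data.frame(dof = c(dofs_of(dn, 1), dofs_of(dn, 2)), value = c(ux, uy))
  if (!hold_z)
    d <- rbind(d, data.frame(dof = dofs_of(dn, 3), value = uz))
  d
}

record_row <- function(model, stage, step) {
  r <- reaction_outputs(model)
  tibble::tibble(
    step = step, stage = stage,
    u_x = model$driven_u[1], u_z = model$driven_u[3],
    theta = model$driven_theta,
    F_x = unname(r["F_x"]), F_z = unname(r["F_z"]), M_z = unname(r["M_z"]),
    phi_bar = mean_bonding(model)
  )
}

# stage runners ---------------------------------------------------------------

#' Run a force-monitored press/pull stage
#'
#' Ramps a uniform vertical displacement of the driven set (step size `du`,
#' signed) until the vertical reaction resultant on the driven set crosses
#' `target` (N), then lands on the target force with one secant sub-step.
#' Used for the implant preload (e.g. press to -70 N, pull to +20 N) and for
#' acetabular-cup insertion (press to -2500 N).
#'
#' @param model A [bi_model()].
#' @param target Target vertical force (N), negative = compression.
#' @param du Signed step increment (m).
#' @param max_steps Ramp bound; exceeding it is an error.
#' @param stage Stage label recorded in the history.
#' @return `list(model, history, d = attained driven displacement)`.
#' @export
stage_to_force <- function(model, target, du, max_steps = 400,
                           stage = "press") {
  hist <- list()
  Fz_prev <- unname(reaction_outputs(model)["F_z"])
  z_prev <- model$driven_u[3]
  crossed <- function(F) if (du < 0) F <= target else F >= target
  presc_to <- function(mdl, z) function(f)
    rbind(clamp_presc(mdl),
          driven_presc(mdl, c(mdl$driven_u[1:2],
                              mdl$driven_u[3] + f * (z - mdl$driven_u[3])),
                       mdl$driven_theta))
  for (s in seq_len(max_steps)) {
    z_new <- model$driven_u[3] + du
    # trial solve without committing damage: an overshoot past the target is
    # discarded and replaced by a secant-interpolated sub-step, so the
    # attained state never contains the overshoot history
    att <- newton_solve(model, presc_to(model, z_new)(1))
    if (att$ok) {
      Fz <- unname(reaction_outputs(att$model)["F_z"])
      if (crossed(Fz)) {
        z_hit <- if (abs(Fz - Fz_prev) > 1e-12)
          z_prev + (target - Fz_prev) / (Fz - Fz_prev) * (z_new - z_prev)
        else z_new
        final <- solve_and_commit(model, presc_to(model, z_hit),
                                  function(f) list())
        final$driven_u[3] <- z_hit
        hist[[length(hist) + 1]] <- record_row(final, stage, s)
        return(list(model = final, history = dplyr::bind_rows(hist),
                    d = final$driven_u[3]))
      }
      model <- commit_state(att$model)
    } else {
      # fall back to the bisecting driver for a genuinely hard step
      model <- solve_and_commit(model, presc_to(model, z_new),
                                function(f) list())
    }
    model$driven_u[3] <- z_new
    Fz <- unname(reaction_outputs(model)["F_z"])
    z_prev <- z_new; Fz_prev <- Fz
    hist[[length(hist) + 1]] <- record_row(model, stage, s)
  }
  stop("target force ", target, " N not reached within ", max_steps, " steps")
}

#' Apply homogeneous osseointegration to the interface
#'
#' Assigns the initial bonding state `phi0` and zeroes the accumulated
#' interface damage: the healing period regrows bone at the interface, so
#' insertion damage does not pre-consume the new bond. The mechanical state
#' is untouched -- the implant stays wedged exactly as inserted, with its
#' contact pressures and frictional stick state (the primary-stability
#' state the bond forms around), so the model remains in equilibrium and no
#' re-solve is needed.
#'
#' @param model A [bi_model()].
#' @param phi0 Initial degree of osseointegration in `[0, 1]`.
#' @return The updated model.
#' @export
stage_set_phi0 <- function(model, phi0 = model$phi0_target) {
  st <- model$state
  st$phi0 <- rep_len(phi0, nrow(st))
  st$g_s <- 0; st$g_sn <- 0; st$g_d <- 0
  st$phi <- state_function(0, st$phi0, model$law$a_s, model$law$b_s)
  model$state <- st
  model
}

#' Run a displacement/rotation ramp stage
#'
#' Advances the driven set over `n_steps` increments of translation `du`
#' (length-3, m) and rotation `dtheta` (rad, about the vertical axis through
#' the driven centroid). If `hold` is given, the vertical translation of the
#' driven set is not prescribed: all driven vertical dofs are tied to one
#' shared unknown carrying the constant vertical force `hold` (N), which
#' re-equilibrates every step (constant-compression / constant-tension
#' protocols).
#'
#' @param model A [bi_model()].
#' @param du Per-step translation increment, length-3 (m).
#' @param dtheta Per-step rotation increment (rad).
#' @param n_steps Number of steps.
#' @param hold Optional constant vertical force (N).
#' @param stage Stage label for the history.
#' @param stop_when Optional function(history_row) returning TRUE to end the
#'   stage early (e.g. once contact is fully lost).
#' @return `list(model, history)`.
#' @export
stage_ramp <- function(model, du = c(0, 0, 0), dtheta = 0, n_steps,
                       hold = NULL, stage = "removal", stop_when = NULL) {
  hist <- list()
  for (s in seq_len(n_steps)) {
    u0 <- model$driven_u; th0 <- model$driven_theta
    cons_at <- function(f) {
      if (is.null(hold)) return(list())
      dn <- model$driven_nodes
      zd <- dofs_of(dn, 3)
      list(list(dofs = zd, coefs = rep(1, length(zd)), value = NA,
                force = hold))
    }
    presc_at <- function(f) {
      rbind(clamp_presc(model),
            driven_presc(model, u0 + f * du, th0 + f * dtheta,
                         hold_z = !is.null(hold)))
    }
    step_ok <- tryCatch({ model <- solve_and_commit(model, presc_at, cons_at); TRUE },
                        error = function(e) e)
    if (!isTRUE(step_ok)) {
      # a tensile hold becomes unsupportable the moment the remaining bonded
      # capacity drops below the held force: contact is lost abruptly and the
      # reactions fall to zero (no equilibrium exists with the hold applied)
      if (!is.null(hold) && hold > 0) {
        w <- model$contact$wA
        capacity <- sum(w * model$state$phi0 * model$law$t0 *
                          (model$state$phi > 0) * (model$state$status != "open"))
        if (capacity < 1.5 * hold) {
          hist[[length(hist) + 1]] <- tibble::tibble(
            step = s, stage = stage, u_x = model$driven_u[1],
            u_z = model$driven_u[3], theta = model$driven_theta,
            F_x = 0, F_z = 0, M_z = 0, phi_bar = 0)
          break
        }
      }
      stop(step_ok)
    }
    model$driven_u <- u0 + du
    # track the realised vertical position under force hold
    if (!is.null(hold)) {
      dn <- model$driven_nodes
      model$driven_u[3] <- mean(model$U[dn, 3])
    }
    model$driven_theta <- th0 + dtheta
    row <- record_row(model, stage, s)
    hist[[length(hist) + 1]] <- row
    if (!is.null(stop_when) && isTRUE(stop_when(row))) break
  }
  list(model = model, history = dplyr::bind_rows(hist))
}

#' Run a rigid-lever stage (lateral lever-out)
#'
#' Drives the implant through a rigid lever attached to the driven set: the
#' lateral displacement of a reference point at height `lever_z` above the
#' driven-set centroid is prescribed, the vertical translation and the tilt
#' about the y-axis remain free (the lever carries no net vertical force),
#' and the out-of-plane motions are suppressed by symmetry. The driven set
#' moves rigidly; increments are linearised per step.
#'
#' @param model A [bi_model()].
#' @param dux Per-step lateral displacement of the lever point (m).
#' @param n_steps Number of steps.
#' @param lever_z Height of the lever reference point above the driven-set
#'   centroid (m).
#' @param stage Stage label.
#' @param stop_when Optional early-stop predicate on the history row.
#' @return `list(model, history)`.
#' @export
stage_lever <- function(model, dux, n_steps, lever_z, stage = "removal",
                        stop_when = NULL) {
  hist <- list()
  dn <- model$driven_nodes
  for (s in seq_len(n_steps)) {
    x_cur <- model$mesh$nodes[dn, , drop = FALSE] + model$U[dn, , drop = FALSE]
    cen <- colMeans(model$driven_ref)
    ref <- c(cen[1], cen[2], cen[3] + lever_z)
    dz <- x_cur[, 3] - ref[3]
    dx <- x_cur[, 1] - ref[1]
    presc_at <- function(f) {
      # lateral dof fully prescribed by lever x + (free tilt handled in cons)
      rbind(clamp_presc(model),
            data.frame(dof = dofs_of(dn, 2), value = 0))
    }
    cons_at <- function(f) {
      list(
        # shared vertical translation (zero net vertical force on the lever)
        list(dofs = dofs_of(dn, 3), coefs = rep(1, length(dn)), value = NA,
             force = 0),
        # tilt about y through the lever point: u_x += w*dz ; u_z += -w*dx
        list(dofs = c(dofs_of(dn, 1), dofs_of(dn, 3)),
             coefs = c(dz, -dx), value = NA, force = 0),
        # prescribed lateral translation increment
        list(dofs = dofs_of(dn, 1), coefs = rep(1, length(dn)),
             value = f * dux, force = NULL)
      )
    }
    # constraints are relative to the current base displacement
    model_step <- model
    res <- newton_solve_with_base(model_step, presc_at(1), cons_at(1))
    if (!res$ok) stop("lever step failed: ", res$reason)
    model <- commit_state(res$model)
    model$driven_u[1] <- model$driven_u[1] + dux
    row <- record_row(model, stage, s)
    hist[[length(hist) + 1]] <- row
    if (!is.null(stop_when) && isTRUE(stop_when(row))) break
  }
  list(model = model, history = dplyr::bind_rows(hist))
}

# variant of newton_solve whose constraint columns displace relative to the
# current displacement of the constrained dofs (used by the rigid lever)
newton_solve_with_base <- function(model, presc, cons) {
  ndof <- 3 * nrow(model$mesh$nodes)
  red <- build_reduction(ndof, presc$dof, cons)
  uv <- as.vector(t(model$U))
  uv[presc$dof] <- presc$value
  for (cc in cons) if (!is.null(cc$value) && !is.na(cc$value))
    uv[cc$dofs] <- uv[cc$dofs] + cc$coefs * cc$value
  model$U <- matrix(uv, ncol = 3, byrow = TRUE)
  newton_core(model, red)
}
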