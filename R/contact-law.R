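#' Parameters of the adhesive-frictional contact law
#'
#' Bundles and validates all constants of the bone-implant interface
#' constitutive model: the state-function shape (`a_s`, `b_s`), the two
#' friction coefficients (`mu_ub` for the unbroken, osseointegrated state and
#' `mu_b` for the broken state), the cohesive zone model (peak adhesive
#' traction `t0`, peak-traction gap `g0`, cutoff gap `g_b`), and the penalty
#' moduli (`eps_n`, `eps_t`). The `law` selector chooses between
#'
#' * `"coulomb"` -- classical Coulomb friction with constant `mu = mu_b`,
#'   no adhesion;
#' * `"mc"` -- modified Coulomb law: the friction coefficient is the
#'   state-weighted blend `mu(phi) = phi * mu_ub + (1 - phi) * mu_b`, but the
#'   interface carries no tensile traction;
#' * `"emc"` -- extended modified Coulomb law: `"mc"` plus an exponential
#'   cohesive zone in the normal direction and an adhesion-shifted sliding
#'   limit `mu(phi) * (t0 - t_n)`.
#'
#' @param a_s Displacement threshold of the state function (m). Accumulated
#'   interface deformation below `a_s` leaves the bond intact.
#' @param b_s Dimensionless half-width of the transition zone between the
#'   fully bonded and fully broken state.
#' @param mu_ub Friction coefficient of the unbroken (osseointegrated) state.
#' @param mu_b Friction coefficient of the broken state; `mu_b <= mu_ub`.
#' @param t0 Peak adhesive normal traction of the cohesive zone (Pa).
#' @param g0 Normal gap at which the peak traction `t0` is attained (m).
#' @param g_b Cutoff gap beyond which contact is lost (m); `g_b >= g0`.
#' @param eps_n,eps_t Normal and tangential penalty moduli (Pa/m).
#' @param law One of `"coulomb"`, `"mc"`, `"emc"`.
#' @return An object of class `"afp"` (a named list).
#' @examples
#' adhesive_friction_params(
#'   a_s = 22e-6, b_s = 0.74, mu_ub = 0.44, mu_b = 0.3,
#'   t0 = 1.8e6, g0 = 66e-6, g_b = 66e-6,
#'   eps_n = 1.8e12, eps_t = 1.8e12, law = "emc"
#' )
#' @export
adhesive_friction_params <- function(a_s, b_s, mu_ub, mu_b,
                                     t0 = 0, g0 = 1e-6, g_b = g0,
                                     eps_n, eps_t = eps_n,
                                     law = c("mc", "emc", "coulomb")) {
  law <- match.arg(law)
  stopifnot(
    "a_s must be > 0" = is.numeric(a_s) && a_s > 0,
    "b_s must be > 0" = is.numeric(b_s) && b_s > 0,
    "friction coefficients need 0 <= mu_b <= mu_ub" =
      mu_b >= 0 && mu_ub >= mu_b,
    "t0 must be >= 0" = t0 >= 0,
    "need 0 < g0 <= g_b" = g0 > 0 && g_b >= g0,
    "eps_n must be > 0" = eps_n > 0,
    "eps_t must be > 0" = eps_t > 0
  )
  structure(
    list(a_s = a_s, b_s = b_s, mu_ub = mu_ub, mu_b = mu_b,
         t0 = t0, g0 = g0, g_b = g_b, eps_n = eps_n, eps_t = eps_t,
         law = law),
    class = "afp"
  )
}

#' @export
print.afp <- function(x, ...) {
  cat("<adhesive-frictional contact law: ", toupper(x$law), ">\n", sep = "")
  cat(sprintf("  state function: a_s = %.3g m, b_s = %.3g\n", x$a_s, x$b_s))
  cat(sprintf("  friction:       mu_ub = %.3g, mu_b = %.3g\n",
              x$mu_ub, x$mu_b))
  if (x$law == "emc")
    cat(sprintf("  cohesive zone:  t0 = %.3g Pa, g0 = %.3g m, g_b = %.3g m\n",
                x$t0, x$g0, x$g_b))
  cat(sprintf("  penalties:      eps_n = %.3g, eps_t = %.3g Pa/m\n",
              x$eps_n, x$eps_t))
  invisible(x)
}

#' Osseointegration state function
#'
#' Maps the accumulated interface deformation `g_d` (damage) to the current
#' bonding state `phi in [0, phi0]`. The bond is intact (`phi = phi0`) while
#' `g_d < a_s`, decays along a smooth sine ramp over the transition zone
#' `a_s <= g_d <= a_s (1 + 2 b_s)`, and is fully broken beyond it:
#' \deqn{\phi = \phi_0 \cdot \begin{cases}
#'   1 & c_1 < 1 \\
#'   \tfrac12 - \tfrac12 \sin\!\big(\tfrac{\pi}{2 b_s}(c_1 - b_s - 1)\big)
#'     & 1 \le c_1 \le 1 + 2 b_s \\
#'   0 & c_1 > 1 + 2 b_s
#' \end{cases}, \qquad c_1 = g_d / a_s.}
#' The function is continuous and non-increasing in `g_d`.
#'
#' @param g_d Accumulated interface deformation (m), `>= 0`. Vectorised.
#' @param phi0 Initial degree of osseointegration in `[0, 1]`.
#' @param a_s,b_s State-function parameters, see
#'   [adhesive_friction_params()].
#' @return `phi`, same length as `g_d`.
#' @examples
#' state_function(0, phi0 = 1, a_s = 22e-6, b_s = 0.74)          # 1
#' state_function(22e-6 * 1.74, phi0 = 1, a_s = 22e-6, b_s = 0.74) # 0.5
#' @export
state_function <- function(g_d, phi0, a_s, b_s) {
  if (any(g_d < -1e-30) || any(is.na(g_d)))
    stop("g_d must be non-negative")
  if (any(phi0 < 0) || any(phi0 > 1))
    stop("phi0 must lie in [0, 1]")
  if (a_s <= 0 || b_s <= 0)
    stop("a_s and b_s must be positive")
  c1 <- g_d / a_s
  w <- 0.5 - 0.5 * sin(pi / (2 * b_s) * (c1 - b_s - 1))
  w[c1 < 1] <- 1
  w[c1 > 1 + 2 * b_s] <- 0
  phi0 * w
}

#' State-dependent friction coefficient
#'
#' Convex blend of the unbroken and broken friction coefficients,
#' `mu(phi) = phi * mu_ub + (1 - phi) * mu_b`.
#'
#' @param phi Current bonding state in `[0, 1]`. Vectorised.
#' @param mu_ub,mu_b Friction coefficients of the unbroken / broken state.
#' @return Friction coefficient, same length as `phi`.
#' @examples
#' friction_coefficient(c(0, 0.5, 1), mu_ub = 0.44, mu_b = 0.3)
#' @export
friction_coefficient <- function(phi, mu_ub, mu_b) {
  if (any(phi < -1e-12) || any(phi > 1 + 1e-12))
    stop("phi must lie in [0, 1]")
  phi * mu_ub + (1 - phi) * mu_b
}

#' Normal contact traction (penalty compression + cohesive tension)
#'
#' Signed scalar normal traction along the outward master normal; tension is
#' positive, compression negative. For penetration (`g_n < 0`) all laws use
#' the linear penalty `eps_n * g_n` (i.e. a compressive, repulsive traction
#' of magnitude `eps_n * |g_n|`). For the extended law (`"emc"`) a positive
#' gap within the cohesive range carries the exponential tensile traction
#' \deqn{t_n = \phi_0\, t_0 \frac{g_n}{g_0} \exp(1 - g_n/g_0), \qquad
#'   0 \le g_n < g_b,\ \phi > 0,}
#' which peaks at `phi0 * t0` for `g_n = g0` and drops sharply to zero at the
#' cutoff `g_b` or once the bond is fully broken (`phi = 0`). The `"mc"` and
#' `"coulomb"` laws carry no tension.
#'
#' @param g_n Signed normal gap (m), negative in penetration. Vectorised.
#' @param phi Current bonding state (gates the tensile branch). Vectorised.
#' @param params An [adhesive_friction_params()] object.
#' @param phi0 Initial bonding state entering the cohesive amplitude
#'   `phi0 * t0`. Defaults to `phi` recovered at zero damage, i.e. callers
#'   tracking damage should pass the stored per-point `phi0`.
#' @return Signed normal traction (Pa), same length as `g_n`.
#' @examples
#' p <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, t0 = 1.8e6,
#'                               g0 = 66e-6, g_b = 66e-6, eps_n = 1.8e12,
#'                               law = "emc")
#' normal_traction(66e-6, phi = 1, p)   # = t0
#' normal_traction(-1e-6, phi = 1, p)   # = -1.8 MPa (compression)
#' @export
normal_traction <- function(g_n, phi, params, phi0 = phi) {
  n <- max(length(g_n), length(phi), length(phi0))
  g_n <- rep_len(g_n, n); phi <- rep_len(phi, n); phi0 <- rep_len(phi0, n)
  tn <- numeric(n)
  pen <- g_n < 0
  tn[pen] <- params$eps_n * g_n[pen]
  if (params$law == "emc") {
    coh <- !pen & g_n < params$g_b & phi > 0
    x <- g_n[coh] / params$g0
    tn[coh] <- phi0[coh] * params$t0 * x * exp(1 - x)
  }
  tn
}

#' Sliding limit of the tangential traction
#'
#' Magnitude of the tangential traction at which sliding occurs. For the
#' classical and modified Coulomb laws this is `mu * p` with the contact
#' pressure `p = -t_n >= 0` (zero when the interface is not compressed). For
#' the extended law the limit is shifted by the adhesive capacity,
#' `mu(phi) * (t0 - t_n)`, so that sliding resistance persists under tensile
#' normal traction; it is clamped at zero from below.
#'
#' @param t_n Signed normal traction (Pa, tension positive). Vectorised.
#' @param phi Current bonding state. Vectorised.
#' @param params An [adhesive_friction_params()] object.
#' @return Sliding limit (Pa, `>= 0`), same length as `t_n`.
#' @examples
#' p <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, t0 = 1.8e6,
#'                               g0 = 66e-6, eps_n = 1.8e12, law = "emc")
#' sliding_limit(t_n = 0, phi = 0, p)      # mu_b * t0
#' sliding_limit(t_n = 1.8e6, phi = 1, p)  # 0: adhesion fully mobilised
#' @export
sliding_limit <- function(t_n, phi, params) {
  mu <- switch(params$law,
    coulomb = rep_len(params$mu_b, max(length(t_n), length(phi))),
    friction_coefficient(phi, params$mu_ub, params$mu_b)
  )
  if (params$law == "emc") {
    pmax(0, mu * (params$t0 - t_n))
  } else {
    p <- pmax(0, -t_n)
    mu * p
  }
}

#' Stick-slip return mapping
#'
#' Radial return of a trial tangential traction onto the slip surface:
#' if the trial magnitude does not exceed the sliding limit the point sticks
#' and the trial is kept; otherwise the traction is scaled back to the limit
#' along its own direction and the point slides. The slip criterion
#' `f_s = ||t_t|| - t_slide <= 0` holds on return; the tie `f_s = 0` is
#' classified as sliding.
#'
#' @param trial Trial tangential traction vector (Pa), length-3 numeric (or a
#'   matrix with 3 columns for several points).
#' @param limit Sliding limit(s) (Pa, `>= 0`).
#' @return A list with `traction` (same shape as `trial`) and `status`
#'   (`"stick"` or `"slip"`, one per point).
#' @examples
#' slip_update(c(0.2e6, 0, 0), limit = 0.54e6)  # stick, unchanged
#' slip_update(c(1.0e6, 0, 0), limit = 0.54e6)  # slip, scaled to limit
#' @export
slip_update <- function(trial, limit) {
  if (any(limit < 0)) stop("limit must be >= 0")
  m <- if (is.matrix(trial)) trial else matrix(trial, ncol = 3)
  nrm <- sqrt(rowSums(m^2))
  limit <- rep_len(limit, nrow(m))
  slip <- nrm >= limit
  scale <- ifelse(slip & nrm > 0, limit / pmax(nrm, .Machine$double.xmin), 1)
  out <- m * scale
  out[slip & nrm == 0, ] <- 0
  res <- if (is.matrix(trial)) out else drop(out)
  list(traction = res, status = ifelse(slip, "slip", "stick"))
}

#' Slope-continuous normal penalty
#'
#' Penalty modulus that makes the normal traction curve `t_n(g_n)` slope
#' continuous at `g_n = 0`, i.e. the penalty stiffness equals the initial
#' slope of the exponential cohesive branch: `eps_n = phi0 * e * t0 / g0`.
#' For `phi0 = 0` this degenerates to zero and callers must substitute a
#' floor penalty (the scenario builders use `E_b / L0` throughout, treating
#' this value as an optional override).
#'
#' @param phi0 Initial bonding state.
#' @param t0 Peak adhesive traction (Pa).
#' @param g0 Gap at peak traction (m), `> 0`.
#' @return Penalty modulus (Pa/m).
#' @examples
#' smooth_penalty(1, 1.8e6, 66e-6)  # ~7.414e10
#' @export
smooth_penalty <- function(phi0, t0, g0) {
  if (any(g0 <= 0)) stop("g0 must be > 0")
  phi0 * exp(1) * t0 / g0
}

#' Calibrate the peak adhesive traction from a pull-out force
#'
#' Inverts the uniform-separation peak pull-out force of a circular bonded
#' interface, `F_max = phi0 * t0 * pi * R^2`, for the cohesive amplitude
#' `t0`. This is the calibration used for polished coin-shaped implants,
#' where an average osseointegration of 0.26 and a mean peak pull-out force
#' of 9 N give `t0 ~ 1.8 MPa`.
#'
#' @param F_max Measured peak pull-out force (N).
#' @param phi0 Degree of osseointegration of the specimen, `> 0`.
#' @param R Interface radius (m), `> 0`.
#' @return Peak adhesive traction `t0` (Pa).
#' @seealso [uniform_pullout_peak()] for the forward evaluation.
#' @examples
#' calibrate_t0(9, phi0 = 0.26, R = 2.5e-3)   # ~1.76e6 Pa
#' calibrate_t0(35, phi0 = 1, R = 2.5e-3)     # ~1.78e6 Pa
#' @export
calibrate_t0 <- function(F_max, phi0, R) {
  if (phi0 <= 0) stop("phi0 must be > 0: an unbonded interface cannot be calibrated")
  if (R <= 0) stop("R must be > 0")
  F_max / (phi0 * pi * R^2)
}

#' Peak pull-out force of a uniformly separating circular interface
#'
#' Forward form of the calibration in [calibrate_t0()]: when a circular
#' bonded interface of radius `R` separates uniformly, every point reaches
#' the cohesive peak `phi0 * t0` simultaneously and the total peak force is
#' `F = phi0 * t0 * pi * R^2`.
#'
#' @param phi0 Initial degree of osseointegration.
#' @param t0 Peak adhesive traction (Pa).
#' @param R Interface radius (m).
#' @return Peak pull-out force (N).
#' @examples
#' uniform_pullout_peak(0.26, 1.8e6, 2.5e-3)  # ~9.2 N
#' @export
uniform_pullout_peak <- function(phi0, t0, R) {
  phi0 * t0 * pi * R^2
}

#' Initialise per-point bonding state
#'
#' Creates the history record carried by every contact quadrature point:
#' initial bonding `phi0`, the accumulated tangential slip `g_s`, the
#' accumulated normal-gap change `g_sn`, their sum `g_d`, the current state
#' `phi = state_function(g_d)`, the reference normal gap of the last
#' converged step (`g_en_prev`), and the stick/slip/open status.
#'
#' @param n Number of points.
#' @param phi0 Initial bonding state, scalar or length `n`.
#' @param params An [adhesive_friction_params()] object.
#' @return A tibble with one row per point.
#' @export
bond_state_init <- function(n, phi0, params) {
  phi0 <- rep_len(phi0, n)
  tibble::tibble(
    phi0 = phi0,
    g_s = 0, g_sn = 0, g_d = 0,
    phi = state_function(0, phi0, params$a_s, params$b_s),
    g_en_prev = 0,
    status = rep("open", n)
  )
}

#' Accumulate interface damage at a contact point
#'
#' Updates a bonding-state record after a converged load step. The damage is
#' composed of the accumulated, irreversible tangential slip and the
#' accumulated change of the normal gap,
#' `g_d = g_s + g_sn`, with
#' `g_s += ||x_l(xi_now) - x_l(xi_prev)||` (current positions of the current
#' and previous interacting points) and `g_sn += |g_en_now - g_en_prev|`.
#' Both contributions are non-negative, so `g_d` grows monotonically even
#' when the loading reverses; during sticking with an unchanged normal gap
#' the state does not change. `phi` is recomputed through
#' [state_function()].
#'
#' @param state A one-row (or `n`-row) bonding-state tibble, see
#'   [bond_state_init()].
#' @param slip_inc Incremental sliding path length(s) `>= 0` (m): the current
#'   distance between the current and previous interacting points.
#' @param g_en Current normal component of the elastic gap (m).
#' @param params An [adhesive_friction_params()] object.
#' @return The updated state tibble.
#' @examples
#' p <- adhesive_friction_params(22e-6, 0.74, 0.44, 0.3, eps_n = 1.8e12)
#' s <- bond_state_init(1, phi0 = 1, p)
#' s <- update_damage(s, slip_inc = 10e-6, g_en = 0, p)  # +10 um slip
#' s <- update_damage(s, slip_inc = 10e-6, g_en = 0, p)  # reversed leg
#' s$g_s  # 20e-6: slip accumulates under reversal
#' @export
update_damage <- function(state, slip_inc, g_en, params) {
  if (any(slip_inc < 0)) stop("slip_inc must be >= 0")
  state$g_s <- state$g_s + slip_inc
  state$g_sn <- state$g_sn + abs(g_en - state$g_en_prev)
  state$g_en_prev <- g_en
  state$g_d <- state$g_s + state$g_sn
  state$phi <- state_function(state$g_d, state$phi0, params$a_s, params$b_s)
  state
}

#' Point-model traction curves of the contact law
#'
#' Evaluates the constitutive curves of the law on a grid, without any
#' finite elements: the normal traction-separation curve `t_n(g_n)` and the
#' sliding limit as a function of the normal traction. Useful for inspecting
#' a parameter set before running a scenario.
#'
#' @param params An [adhesive_friction_params()] object.
#' @param phi Bonding state at which to evaluate (default 1).
#' @param n Number of grid points per curve.
#' @return A tibble with columns `curve` (`"normal"` or `"sliding_limit"`),
#'   `x` (gap in m, resp. normal traction in Pa) and `value` (Pa).
#' @export
law_curves <- function(params, phi = 1, n = 401) {
  gn <- seq(-0.2 * params$g_b, 1.2 * params$g_b, length.out = n)
  tn <- normal_traction(gn, phi = phi, params, phi0 = phi)
  tt_x <- seq(-2 * params$t0 - 1e6, max(params$t0, 1e5), length.out = n)
  tt <- sliding_limit(tt_x, phi = phi, params)
  dplyr::bind_rows(
    tibble::tibble(curve = "normal", x = gn, value = tn),
    tibble::tibble(curve = "sliding_limit", x = tt_x, value = tt)
  )
}
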