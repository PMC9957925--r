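# Ready-made boundary-value problems: the coin-shaped implant (CSI) debonding
# tests and the acetabular cup implant (ACI) insertion/removal protocol.

#' Coin-shaped implant scenario configuration
#'
#' Default geometry, materials and contact parameters of the standardized
#' coin-shaped implant debonding tests: a titanium cylinder (radius 2.5 mm,
#' height 3 mm) on a trabecular bone block (12.5 x 12.5 x 5 mm), with the
#' state-function parameters `a_s = 22 um`, `b_s = 0.74`, friction
#' coefficients 0.44/0.3, cohesive peak `t0 = 1.8 MPa` at `g0 = g_b = 3 a_s`,
#' and penalties `eps = E_b / 0.01 m`. Step sizes are 0.65 um per
#' displacement step and 0.1 degree per rotation step.
#'
#' @param law Contact law: `"mc"`, `"emc"` or `"coulomb"`.
#' @param phi0 Initial degree of osseointegration applied before removal.
#' @param preload Vertical preload (N): -70 (compression), +20 (tension,
#'   reached by pulling after the -70 N press) or 0.
#' @param alpha Mixed-mode pull angle (degrees, measured from the interface
#'   plane in the x-z plane).
#' @param t0 Cohesive peak traction (Pa).
#' @param refine Integer mesh-refinement factor (1 = 18 implant + 450 bone
#'   bulk elements).
#' @param du Displacement step (m).
#' @param dtheta Rotation step (rad).
#' @param n_slide,n_rot,n_mixed Step counts of the removal ramps.
#' @param ngp Contact Gauss points per facet direction.
#' @return A list of class `"csi_config"`.
#' @export
csi_config <- function(law = c("mc", "emc", "coulomb"), phi0 = 1,
                       preload = -70, alpha = 45, t0 = 1.8e6, refine = 1,
                       du = 0.65e-6, dtheta = 0.1 * pi / 180,
                       n_slide = 140, n_rot = 32, n_mixed = 260, ngp = 5) {
  law <- match.arg(law)
  E_b <- 18e9
  a_s <- 22e-6
  structure(list(
    law = law, phi0 = phi0, preload = preload, alpha = alpha,
    R_i = 2.5e-3, H_i = 3e-3, bone = c(12.5e-3, 12.5e-3, 5e-3),
    E_i = 113e9, nu_i = 0.3, E_b = E_b, nu_b = 0.3,
    a_s = a_s, b_s = 0.74, mu_ub = 0.44, mu_b = 0.3,
    t0 = t0, g0 = 3 * a_s, g_b = 3 * a_s,
    eps = E_b / 0.01,
    du = du, dtheta = dtheta, refine = as.integer(refine),
    n_slide = n_slide, n_rot = n_rot, n_mixed = n_mixed, ngp = ngp
  ), class = "csi_config")
}

csi_law <- function(cfg) {
  adhesive_friction_params(
    a_s = cfg$a_s, b_s = cfg$b_s, mu_ub = cfg$mu_ub, mu_b = cfg$mu_b,
    t0 = if (cfg$law == "emc") cfg$t0 else 0,
    g0 = cfg$g0, g_b = cfg$g_b,
    eps_n = cfg$eps, eps_t = cfg$eps, law = cfg$law
  )
}

#' Build the coin-shaped implant model
#'
#' Meshes the bone block (15 x 15 x 2 elements at `refine = 1`) and the
#' implant cylinder (3 x 3 x 2), places the implant at the centre of the
#' upper bone surface, and sets up the contact pair with the bone top as
#' slave and the implant base as master. The bone base is clamped and the
#' implant top surface is the driven set.
#'
#' @param cfg A [csi_config()].
#' @return A [bi_model()].
#' @export
build_csi <- function(cfg = csi_config()) {
  r <- cfg$refine
  bone <- mesh_block(cfg$bone[1], cfg$bone[2], cfg$bone[3],
                     15L * r, 15L * r, 2L * r, body = 1L)
  imp <- mesh_cylinder(cfg$R_i, cfg$H_i, 3L * r, 2L * r, body = 2L,
                       equal_area = TRUE)
  msh <- mesh_join(bone, imp, "bone_", "imp_")
  # contact candidates: bone top facets beneath (or near) the implant disc
  top <- msh$surfaces$bone_top
  cenr <- apply(top, 1, function(f) sqrt(sum(colMeans(msh$nodes[f, ])[1:2]^2)))
  h <- cfg$bone[1] / (15 * r)
  keep <- cenr <= cfg$R_i + 0.8 * h
  msh$surfaces$bone_top <- top[keep, , drop = FALSE]
  interface <- cenr[keep] <= cfg$R_i
  bi_model(
    msh,
    materials = list("1" = elastic_params(cfg$E_b, cfg$nu_b),
                     "2" = elastic_params(cfg$E_i, cfg$nu_i)),
    slave = "bone_top", master = "imp_bottom",
    law = csi_law(cfg), phi0 = cfg$phi0,
    fixed = "bone_bottom", driven = "imp_top",
    interface = interface, ngp = cfg$ngp
  )
}

finish_history <- function(parts, d0 = NA_real_, config = NULL) {
  h <- dplyr::bind_rows(parts)
  h$step <- seq_len(nrow(h))
  attr(h, "d0") <- d0
  attr(h, "config") <- config
  class(h) <- c("response_history", class(h))
  h
}

#' Run a coin-shaped implant debonding test
#'
#' Executes the staged protocol of one CSI test family and returns the full
#' response history:
#' * `"IIa"` -- press to -70 N, osseointegrate, slide in x under the
#'   constant -70 N hold;
#' * `"IIb"` -- press to -70 N, osseointegrate, pull up to +20 N, slide in x
#'   under the constant +20 N tension (extended law only);
#' * `"IIIa"`/`"IIIb"` -- as above but rotating about z in 0.1 degree steps;
#' * `"I+II"` -- optional preload, osseointegrate, then pull at angle
#'   `alpha` in the x-z plane (no force hold).
#'
#' @param model A [build_csi()] model (or `NULL` to build from `cfg`).
#' @param test One of `"IIa"`, `"IIb"`, `"IIIa"`, `"IIIb"`, `"I+II"`.
#' @param cfg The [csi_config()] used to build the model.
#' @return A `response_history` tibble (one row per converged step) with
#'   attribute `d0` and the peak metrics accessible via [peak_metrics()].
#' @export
run_csi_test <- function(model = NULL, test = c("IIa", "IIb", "IIIa", "IIIb", "I+II"),
                         cfg = csi_config()) {
  test <- match.arg(test)
  if (is.null(model)) model <- build_csi(cfg)
  parts <- list()
  d0 <- NA_real_
  tension <- test %in% c("IIb", "IIIb")
  if (test %in% c("IIa", "IIb", "IIIa", "IIIb") || cfg$preload < 0) {
    pr <- stage_to_force(model, target = -70, du = -cfg$du, stage = "press")
    model <- pr$model; parts$press <- pr$history; d0 <- pr$d
  }
  model <- stage_set_phi0(model, cfg$phi0)
  if (tension) {
    pl <- stage_to_force(model, target = 20, du = cfg$du, stage = "pull")
    model <- pl$model; parts$pull <- pl$history
  }
  gone <- function(row) row$phi_bar < 1e-12 && abs(row$F_x) < 1e-3 &&
    abs(row$F_z) < 1e-3 && abs(row$M_z) < 1e-6
  if (test %in% c("IIa", "IIb")) {
    hold <- if (tension) 20 else -70
    rm <- stage_ramp(model, du = c(cfg$du, 0, 0), n_steps = cfg$n_slide,
                     hold = hold, stage = "slide",
                     stop_when = if (tension) gone else NULL)
    model <- rm$model; parts$removal <- rm$history
  } else if (test %in% c("IIIa", "IIIb")) {
    hold <- if (tension) 20 else -70
    rm <- stage_ramp(model, dtheta = cfg$dtheta, n_steps = cfg$n_rot,
                     hold = hold, stage = "rotate",
                     stop_when = if (tension) gone else NULL)
    model <- rm$model; parts$removal <- rm$history
  } else {
    a <- cfg$alpha * pi / 180
    rm <- stage_ramp(model, du = cfg$du * c(cos(a), 0, sin(a)),
                     n_steps = cfg$n_mixed, stage = "mixed",
                     stop_when = function(row)
                       row$step > 30 && abs(row$F_x) < 0.02 && abs(row$F_z) < 0.02)
    model <- rm$model; parts$removal <- rm$history
  }
  h <- finish_history(parts, d0 = d0, config = cfg)
  attr(h, "model") <- model
  h
}

#' Acetabular cup implant scenario configuration
#'
#' Geometry, materials and protocol of the cup insertion/removal simulation:
#' a trabecular bone cylinder (radius 50 mm, height 40 mm) with a
#' hemispherical cavity `R_b = R_i - IF/2` for the titanium cup of outer
#' radius `R_i = 25.5 mm`; insertion to `F0 = -2500 N`, homogeneous
#' osseointegration, then removal by normal pull-out (mode I), lateral
#' lever-out (mode II) or torsion about the implant axis (mode III, 10
#' degrees). Contact parameters: `a_s = 128 um`, `b_s = 1.84`,
#' `mu_ub = 1.5 mu_b`, `t0 = 1.8 MPa`, `g0 = g_b = 3 a_s`, penalties
#' `E_b / 0.0255 m`. The reference case is `E_b = 0.2 GPa`, `IF = 1 mm`,
#' `mu_b = 0.3`.
#'
#' @param E_b Trabecular Young's modulus (Pa), range 0.1-0.6 GPa.
#' @param IF Interference fit (m), range 0-2 mm.
#' @param mu_b Broken-state friction coefficient, range 0-0.7.
#' @param mu_ub Unbroken-state friction coefficient (default `1.5 mu_b`).
#' @param phi0 Initial degree of osseointegration.
#' @param law `"mc"`, `"emc"` or `"coulomb"`.
#' @param F0 Insertion force target (N).
#' @param mesh_scale Scaling of the surface-grid resolution (1 = the
#'   desk-scale default of a 16 x 16 cavity grid with 7 graded radial
#'   layers, about a tenth of the full-study element count).
#' @param du_insert Insertion displacement step (m).
#' @param n_removal Steps of the mode I/III removal ramps.
#' @param n_lever Steps of the mode II lever ramp.
#' @param theta_removal Total mode III rotation (rad).
#' @param ngp Contact Gauss points per facet direction.
#' @return A list of class `"aci_config"`.
#' @export
aci_config <- function(E_b = 0.2e9, IF = 1e-3, mu_b = 0.3, mu_ub = 1.5 * mu_b,
                       phi0 = 1, law = c("mc", "emc", "coulomb"), F0 = -2500,
                       mesh_scale = 1, du_insert = 50e-6, n_removal = 100,
                       n_lever = 150, theta_removal = 10 * pi / 180, ngp = 5) {
  law <- match.arg(law)
  a_s <- 128e-6
  R_i <- 25.5e-3
  structure(list(
    law = law, phi0 = phi0, E_b = E_b, nu_b = 0.3, IF = IF,
    mu_b = mu_b, mu_ub = mu_ub, F0 = F0,
    R_i = R_i, R_b = R_i - IF / 2, R_cyl = 50e-3, H = 40e-3,
    cup_thickness = 3e-3, E_i = 113e9, nu_i = 0.3,
    a_s = a_s, b_s = 1.84, t0 = 1.8e6, g0 = 3 * a_s, g_b = 3 * a_s,
    eps = E_b / R_i,
    n_bone = max(8L, as.integer(round(16 * mesh_scale))),
    nl_bone = max(3L, as.integer(round(7 * mesh_scale))),
    n_cup = max(6L, as.integer(round(12 * mesh_scale))),
    nl_cup = 2L, grading = 1.6, fillet = 2e-3, rim_exp = 2,
    du_insert = du_insert, n_removal = n_removal, n_lever = n_lever,
    theta_removal = theta_removal, ngp = ngp
  ), class = "aci_config")
}

aci_law <- function(cfg) {
  adhesive_friction_params(
    a_s = cfg$a_s, b_s = cfg$b_s, mu_ub = cfg$mu_ub, mu_b = cfg$mu_b,
    t0 = if (cfg$law == "emc") cfg$t0 else 0,
    g0 = cfg$g0, g_b = cfg$g_b,
    eps_n = cfg$eps, eps_t = cfg$eps, law = cfg$law
  )
}

#' Build the acetabular cup implant model
#'
#' Meshes the bone cylinder with its hemispherical cavity (radius
#' `R_b = R_i - IF/2`) by graded radial rays and the cup as a hemispherical
#' shell, positions the cup so that it just touches the cavity pole, and
#' sets up the contact pair (bone cavity + top-rim annulus as slave, cup
#' outer surface as master). The bone bottom is clamped; the cup inner
#' surface is the driven set (rigid ancillary).
#'
#' @param cfg An [aci_config()].
#' @return A [bi_model()].
#' @export
build_aci <- function(cfg = aci_config()) {
  if (cfg$R_b >= cfg$R_cyl) stop("cavity exceeds the bone cylinder")
  if (cfg$R_b <= 0.5 * cfg$R_i)
    stop("interference fit too large: the cup cannot seat in the cavity")
  bone <- mesh_socket(cfg$R_b, cfg$R_cyl, cfg$H, cfg$n_bone, cfg$nl_bone,
                      grading = cfg$grading, fillet = cfg$fillet,
                      rim_exp = cfg$rim_exp,
                      annulus_rmax = cfg$R_i + 2.5e-3, body = 1L)
  # with an interference fit the rigid shapes can only meet at the cavity
  # rim: first contact occurs with the cup centre sqrt(R_i^2 - R_b^2) above
  # the cavity centre, and insertion slides the cup in from there
  lift <- sqrt(max(0, cfg$R_i^2 - cfg$R_b^2)) + 2e-5
  cup <- mesh_cup(cfg$R_i, cfg$cup_thickness, cfg$n_cup, cfg$nl_cup,
                  centre = c(0, 0, lift), body = 2L, rim_exp = cfg$rim_exp)
  msh <- mesh_join(bone, cup, "bone_", "cup_")
  ncav <- nrow(bone$surfaces$cavity)
  nann <- nrow(bone$surfaces$annulus)
  slave <- "bone_cavity"
  if (nann > 0) slave <- c(slave, "bone_annulus")
  bi_model(
    msh,
    materials = list("1" = elastic_params(cfg$E_b, cfg$nu_b),
                     "2" = elastic_params(cfg$E_i, cfg$nu_i)),
    slave = slave, master = "cup_outer",
    law = aci_law(cfg), phi0 = cfg$phi0,
    fixed = "bone_bottom", driven = "cup_inner",
    interface = c(rep(TRUE, ncav), rep(FALSE, nann)), ngp = cfg$ngp
  )
}

#' Run an acetabular cup removal simulation
#'
#' Executes the three-stage protocol: (1) insertion by pushing the cup down
#' until the vertical reaction reaches `F0` (the attained displacement is
#' `d0`), (2) homogeneous osseointegration `phi0` with interface-history
#' reset, (3) removal by the selected mode: `"I"` pulls the cup up by `d0`,
#' `"II"` displaces the lever point laterally, `"III"` rotates about z by 10
#' degrees.
#'
#' @param model A [build_aci()] model (or `NULL` to build from `cfg`).
#' @param mode `"I"`, `"II"` or `"III"`.
#' @param cfg The [aci_config()] used to build the model.
#' @return A `response_history` tibble with attribute `d0`.
#' @export
run_aci_removal <- function(model = NULL, mode = c("I", "II", "III"),
                            cfg = aci_config()) {
  mode <- match.arg(mode)
  if (is.null(model)) model <- build_aci(cfg)
  parts <- list()
  ins <- stage_to_force(model, target = cfg$F0, du = -cfg$du_insert,
                        max_steps = 600, stage = "insertion")
  model <- ins$model; parts$insertion <- ins$history
  d0 <- -ins$d
  model <- stage_set_phi0(model, cfg$phi0)
  if (mode == "I") {
    rm <- stage_ramp(model, du = c(0, 0, d0 / cfg$n_removal),
                     n_steps = cfg$n_removal, stage = "removal",
                     stop_when = function(row)
                       row$step > 10 && abs(row$F_z) < 1e-4 * abs(cfg$F0))
  } else if (mode == "III") {
    # torsion at the seated depth: the vertical position reached by the
    # insertion is clamped, the press-fit pressures persist, and the torque
    # settles at the Coulomb level of the maintained compressive press-fit
    rm <- stage_ramp(model, dtheta = cfg$theta_removal / cfg$n_removal,
                     n_steps = cfg$n_removal, stage = "removal")
  } else {
    rm <- stage_lever(model, dux = d0 / cfg$n_lever, n_steps = cfg$n_lever,
                      lever_z = 0.1, stage = "removal",
                      stop_when = function(row)
                        row$step > 10 && abs(row$F_x) < 1e-4 * abs(cfg$F0))
  }
  model <- rm$model; parts$removal <- rm$history
  h <- finish_history(parts, d0 = d0, config = cfg)
  attr(h, "model") <- model
  h
}

#' Peak stability metrics of a response history
#'
#' @param history A `response_history` tibble.
#' @param stage Stages to include (default: the removal/slide/rotate/mixed
#'   stages, excluding preload and insertion).
#' @return A one-row tibble with `F_x_max`, `F_z_max`, `M_z_max`, the
#'   post-peak plateau torque `M_z_plateau` (mean torque over the last
#'   quarter of the stage), and `d0`.
#' @export
peak_metrics <- function(history,
                         stage = c("removal", "slide", "rotate", "mixed")) {
  h <- history[history$stage %in% stage, , drop = FALSE]
  if (!nrow(h)) stop("history has no rows in stages: ", paste(stage, collapse = ", "))
  tail_q <- h[h$step >= stats::quantile(h$step, 0.75), , drop = FALSE]
  tibble::tibble(
    F_x_max = max(h$F_x), F_z_max = max(h$F_z), M_z_max = max(h$M_z),
    M_z_plateau = mean(tail_q$M_z),
    d0 = attr(history, "d0") %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep peak metrics over scenario configurations
#'
#' Runs [run_aci_removal()] (or [run_csi_test()] for CSI configs) over a
#' list of configurations and collects the peak metrics; individual
#' failures are recorded and the sweep continues. Results are cached on
#' disk keyed by the configuration hash when `cache_dir` is given.
#'
#' @param configs List of `aci_config()`/`csi_config()` objects.
#' @param mode Removal mode passed to the runner (ACI) or test id (CSI).
#' @param cache_dir Optional directory for resumable caching.
#' @return A tibble with one row per configuration: the varied parameters,
#'   peak metrics, and an `error` column (NA on success).
#' @export
sweep_peaks <- function(configs, mode = "I", cache_dir = NULL) {
  rows <- lapply(seq_along(configs), function(i) {
    cfg <- configs[[i]]
    key <- rlang::hash(list(cfg, mode))
    cache <- if (!is.null(cache_dir)) file.path(cache_dir, paste0(key, ".csv"))
    if (!is.null(cache) && file.exists(cache))
      return(tibble::as_tibble(read.csv(cache)))
    base <- tibble::tibble(
      phi0 = cfg$phi0, law = cfg$law,
      E_b = cfg$E_b %||% NA_real_, IF = cfg$IF %||% NA_real_,
      mu_b = cfg$mu_b
    )
    out <- tryCatch({
      h <- if (inherits(cfg, "aci_config"))
        run_aci_removal(mode = mode, cfg = cfg)
      else run_csi_test(test = mode, cfg = cfg)
      dplyr::bind_cols(base, peak_metrics(h), tibble::tibble(error = NA_character_))
    }, error = function(e)
      dplyr::bind_cols(base, tibble::tibble(
        F_x_max = NA_real_, F_z_max = NA_real_, M_z_max = NA_real_,
        M_z_plateau = NA_real_, d0 = NA_real_, error = conditionMessage(e))))
    if (!is.null(cache)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(out, cache, row.names = FALSE)
    }
    out
  })
  dplyr::bind_rows(rows)
}
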