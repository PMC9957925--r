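#' Write a response history to CSV (with a JSON peak sidecar)
#'
#' Writes the per-step records as a deterministic CSV (columns `step`,
#' `stage`, `u_x`, `u_z`, `theta_deg`, `F_x`, `F_z`, `M_z`, `phi_bar`, SI
#' units except the angle) and a JSON sidecar `<path>.json` holding the peak
#' metrics and the insertion displacement `d0`.
#'
#' @param history A `response_history` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  if (!nrow(history)) stop("empty history")
  out <- data.frame(
    step = history$step, stage = history$stage,
    u_x = history$u_x, u_z = history$u_z,
    theta_deg = history$theta * 180 / pi,
    F_x = history$F_x, F_z = history$F_z, M_z = history$M_z,
    phi_bar = history$phi_bar
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  side <- as.list(peak_metrics(history))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a response history written by [write_history()]
#'
#' @param path CSV path.
#' @return A `response_history` tibble.
#' @export
read_history <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  h <- tibble::tibble(
    step = d$step, stage = d$stage, u_x = d$u_x, u_z = d$u_z,
    theta = d$theta_deg * pi / 180, F_x = d$F_x, F_z = d$F_z, M_z = d$M_z,
    phi_bar = d$phi_bar
  )
  class(h) <- c("response_history", class(h))
  h
}

#' Tidy a response history
#'
#' Long-format view of the reaction outputs, one row per step and quantity,
#' convenient for faceted plotting and dplyr summaries.
#'
#' @param x A `response_history` tibble.
#' @param ... Unused.
#' @return A tibble with columns `step`, `stage`, `control`, `quantity`,
#'   `value`.
#' @export
tidy.response_history <- function(x, ...) {
  ctrl <- ifelse(abs(x$theta) > 0, x$theta, ifelse(abs(x$u_x) > 0, x$u_x, x$u_z))
  dplyr::bind_rows(lapply(c("F_x", "F_z", "M_z", "phi_bar"), function(q)
    tibble::tibble(step = x$step, stage = x$stage, control = ctrl,
                   quantity = q, value = x[[q]])))
}

#' One-row summary of a response history
#'
#' @param x A `response_history` tibble.
#' @param ... Unused.
#' @return A one-row tibble: step count, stages, peak metrics, final mean
#'   bonding.
#' @export
glance.response_history <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_steps = nrow(x),
                   stages = paste(unique(x$stage), collapse = "+"),
                   phi_bar_final = x$phi_bar[nrow(x)]),
    peak_metrics(x)
  )
}

# make tidy()/glance() usable without broom/generics on the search path
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a response history
#'
#' Load-displacement (or torque-rotation) curves of the removal stages plus
#' the mean bonding state, in the style of the standard removal-test figure:
#' reaction force/torque against the control variable.
#'
#' @param object A `response_history` tibble.
#' @param stages Stages to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.response_history <- function(object, stages = unique(object$stage), ...) {
  h <- object[object$stage %in% stages, , drop = FALSE]
  rot <- any(abs(h$theta) > 0)
  xvar <- if (rot) h$theta * 180 / pi else
    (if (max(abs(h$u_x)) >= max(abs(h$u_z))) h$u_x else h$u_z) * 1e3
  xlab <- if (rot) "rotation (deg)" else "displacement (mm)"
  d <- dplyr::bind_rows(
    tibble::tibble(x = xvar, value = h$F_x, quantity = "F_x (N)"),
    tibble::tibble(x = xvar, value = h$F_z, quantity = "F_z (N)"),
    tibble::tibble(x = xvar, value = h$M_z, quantity = "M_z (N m)"),
    tibble::tibble(x = xvar, value = h$phi_bar, quantity = "mean bonding")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot the constitutive curves of a contact law
#'
#' Normal traction-separation curve and sliding limit of an
#' [adhesive_friction_params()] set (the point model, no finite elements).
#'
#' @param params An [adhesive_friction_params()] object.
#' @param phi Bonding state (default 1).
#' @return A ggplot object.
#' @export
plot_law_curves <- function(params, phi = 1) {
  d <- law_curves(params, phi = phi)
  d$x <- ifelse(d$curve == "normal", d$x * 1e6, d$x * 1e-6)
  d$curve <- ifelse(d$curve == "normal", "normal traction vs gap (um)",
                    "sliding limit vs normal traction (MPa)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$value * 1e-6)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free") +
    ggplot2::labs(x = NULL, y = "traction (MPa)") +
    ggplot2::theme_minimal()
}
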