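#' Isotropic elastic parameters
#'
#' Converts Young's modulus and Poisson ratio to the Lame constants used by
#' the compressible Neo-Hookean model: `G = E / (2 (1 + nu))` and
#' `Lambda = 2 G nu / (1 - 2 nu)`.
#'
#' @param E Young's modulus (Pa), `> 0`.
#' @param nu Poisson ratio, `0 <= nu < 0.5`.
#' @return An object of class `"elastic_params"` with fields `E`, `nu`, `G`,
#'   `Lambda`.
#' @examples
#' elastic_params(18e9, 0.3)
#' @export
elastic_params <- function(E, nu) {
  stopifnot(E > 0, nu >= 0, nu < 0.5)
  G <- E / (2 * (1 + nu))
  structure(
    list(E = E, nu = nu, G = G, Lambda = 2 * G * nu / (1 - 2 * nu)),
    class = "elastic_params"
  )
}

#' @export
print.elastic_params <- function(x, ...) {
  cat(sprintf("<elastic_params: E = %.4g Pa, nu = %.3g, G = %.4g Pa, Lambda = %.4g Pa>\n",
              x$E, x$nu, x$G, x$Lambda))
  invisible(x)
}

#' Neo-Hookean Cauchy stress
#'
#' Evaluates the compressible Neo-Hookean stress
#' \deqn{\sigma = \frac{\Lambda}{J}(\ln J)\,I + \frac{G}{J}(b - I)}
#' with `J = det(F)` and the left Cauchy-Green tensor `b = F F'`. The
#' reference configuration (`F = I`) is stress free.
#'
#' @param F Deformation gradient, 3x3 matrix with `det(F) > 0`.
#' @param mat An [elastic_params()] object.
#' @return The symmetric 3x3 Cauchy stress tensor (Pa).
#' @examples
#' neo_hookean_stress(diag(3), elastic_params(18e9, 0.3))  # zero
#' @export
neo_hookean_stress <- function(F, mat) {
  J <- det(F)
  if (J <= 0) stop("element inversion: det(F) <= 0")
  b <- F %*% t(F)
  (mat$Lambda / J) * log(J) * diag(3) + (mat$G / J) * (b - diag(3))
}
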