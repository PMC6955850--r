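# Modified Gasser-Ogden-Holzapfel fiber-reinforced hyperelastic energy for
# glutaraldehyde-treated porcine pericardium. Energy evaluation only; no
# stress-tensor derivation and no finite-element constitutive update.

#' Material parameters for the modified GOH strain energy
#'
#' @param C10 isotropic coefficient (kPa).
#' @param C01 dimensionless isotropic exponent coefficient.
#' @param k1 fiber stiffness-like coefficient (kPa).
#' @param k2 dimensionless fiber exponent coefficient (> 0).
#' @param D incompressibility penalty coefficient (> 0). Smaller D enforces
#'   incompressibility more strongly; its value is not fixed by the
#'   constitutive data, default 1e-4.
#' @param kappa fiber dispersion, in `[0, 1/3]` (0 = perfectly aligned,
#'   1/3 = isotropic).
#' @param theta_fiber fiber angle, degrees.
#' @return An object of class `tav_material`.
#' @export
material_params <- function(C10, C01, k1, k2, D = 1e-4,
                            kappa = 0, theta_fiber = 0) {
  if (!is.finite(k2) || k2 <= 0) stop("material_params: k2 must be > 0", call. = FALSE)
  if (!is.finite(D) || D <= 0) stop("material_params: D must be > 0", call. = FALSE)
  if (!is.finite(kappa) || kappa < 0 || kappa > 1 / 3 + 1e-12) {
    stop("material_params: kappa must lie in [0, 1/3]", call. = FALSE)
  }
  structure(list(C10 = C10, C01 = C01, k1 = k1, k2 = k2, D = D,
                 kappa = kappa, theta_fiber = theta_fiber),
            class = "tav_material")
}

#' Porcine-pericardium material constants
#'
#' The biaxial-test-derived constants for chemically treated porcine
#' pericardium used for TAV leaflets: C01 = 13.48, C10 = 2.196 kPa,
#' k1 = 22.14 kPa, k2 = 107.27, fiber dispersion kappa = 1.16e-7, fiber
#' angle 7.81 degrees. D is a penalty constant, not a measured property;
#' the default 1e-4 gives near-incompressible behavior.
#'
#' @param D incompressibility penalty override.
#' @return A [material_params()] object.
#' @export
default_porcine_params <- function(D = 1e-4) {
  material_params(C10 = 2.196, C01 = 13.48, k1 = 22.14, k2 = 107.27,
                  D = D, kappa = 1.16e-7, theta_fiber = 7.81)
}

#' @export
print.tav_material <- function(x, ...) {
  cat(sprintf(
    "Modified GOH material: C10=%.4g kPa, C01=%.4g, k1=%.4g kPa, k2=%.4g, D=%.3g, kappa=%.3g, theta=%.3g deg\n",
    x$C10, x$C01, x$k1, x$k2, x$D, x$kappa, x$theta_fiber))
  invisible(x)
}

#' Strain-energy density of the modified GOH model
#'
#' Evaluates
#' \deqn{W = C_{10}\{e^{C_{01}(\bar I_1 - 3)} - 1\}
#'       + \frac{k_1}{2 k_2} \sum_{i=1}^{2}\{e^{k_2 (\bar I_{4i}-1)^2} - 1\}
#'       + \frac{1}{D}(J - 1)^2}
#' for deviatoric invariants \eqn{\bar I_1} (isotropic) and
#' \eqn{\bar I_{41}, \bar I_{42}} (one per fiber family) and volume ratio J.
#' With `dispersion = TRUE` the fiber argument is replaced by the GOH
#' dispersion blend \eqn{E_i = \kappa(\bar I_1 - 3) + (1 - 3\kappa)(\bar
#' I_{4i} - 1)}, the form the unmodified GOH model uses to mix isotropic and
#' fiber stretch; the default evaluates the modified energy exactly as
#' written above.
#'
#' @param I1bar deviatoric first invariant (dimensionless).
#' @param I4bar length-2 numeric: deviatoric fourth invariants of the two
#'   fiber families.
#' @param J volume ratio (> 0).
#' @param mp a [material_params()] object.
#' @param dispersion logical; use the GOH kappa-dispersion fiber argument.
#' @return energy density W (kPa).
#' @examples
#' strain_energy(3, c(1, 1), 1, default_porcine_params())  # 0 at identity
#' @export
strain_energy <- function(I1bar, I4bar, J, mp = default_porcine_params(),
                          dispersion = FALSE) {
  stopifnot(inherits(mp, "tav_material"), length(I4bar) == 2L)
  if (!is.finite(J) || J <= 0) {
    stop("strain_energy: invalid deformation, J must be > 0", call. = FALSE)
  }
  if (!is.finite(I1bar) || any(!is.finite(I4bar))) {
    stop("strain_energy: invariants must be finite", call. = FALSE)
  }
  fib_arg <- if (dispersion) {
    mp$kappa * (I1bar - 3) + (1 - 3 * mp$kappa) * (I4bar - 1)
  } else {
    I4bar - 1
  }
  mp$C10 * expm1(mp$C01 * (I1bar - 3)) +
    mp$k1 / (2 * mp$k2) * sum(expm1(mp$k2 * fib_arg^2)) +
    (1 / mp$D) * (J - 1)^2
}
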