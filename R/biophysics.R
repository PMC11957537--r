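#' Young-Laplace pressure jump for a thin elastic shell
#'
#' Relates the pressure discontinuity across the cell wall to membrane
#' tension `T` and radius of curvature `R`. A sphere has two identical
#' curvature radii, giving `dP = 2 T / R`; a cylinder has one finite radius,
#' giving `dP = T / R`. Any consistent unit system may be used.
#'
#' @param shape `"sphere"` or `"cylinder"`.
#' @param tension membrane tension (force/length), positive.
#' @param radius radius of curvature, positive.
#' @return pressure jump across the wall.
#' @examples
#' laplacePressure("sphere", tension = 1, radius = 2)    # 1
#' laplacePressure("cylinder", tension = 1, radius = 1)  # 1
#' @export
laplacePressure <- function(shape = c("sphere", "cylinder"), tension,
                            radius) {
  shape <- match.arg(shape)
  if (any(!is.finite(tension) | tension <= 0))
    stop("domain error: tension must be positive")
  if (any(!is.finite(radius) | radius <= 0))
    stop("domain error: radius must be positive")
  if (shape == "sphere") 2 * tension / radius else tension / radius
}

#' Equilibrium sphere radius of a rod that loses its cylindrical geometry
#'
#' Equating the sphere and cylinder Laplace relations at equal turgor
#' pressure jump and equal membrane tension (`2T/Rs = T/Rc`) gives
#' `Rs = 2 Rc`: a cylinder of radius `Rc` that rounds up while keeping its
#' wall mechanics settles at twice the radius.
#'
#' @param Rc cylinder radius (um), positive.
#' @return equilibrium sphere radius `2 * Rc` (um).
#' @export
equilibriumSphereRadius <- function(Rc) {
  if (any(!is.finite(Rc) | Rc <= 0))
    stop("domain error: Rc must be positive")
  2 * Rc
}

#' Predicted volume factor for the rod-to-sphere transition
#'
#' Ratio of the equilibrium sphere volume to the original cylinder volume at
#' constant turgor pressure and membrane tension:
#' \deqn{V_s / V_c = \frac{(4/3)\pi (2R_c)^3}{\pi R_c^2 L} = \frac{32 R_c}{3 L}}
#' For a rod of diameter 1 um (`Rc = 0.5`) and length 3 um this predicts a
#' volume increase by a factor 1.78. The cylinder volume is the pure cylinder
#' `pi * Rc^2 * L` (not a spherocylinder); the ratio is invariant under joint
#' rescaling of `Rc` and `L` and proportional to `1/L`.
#'
#' @param Rc cylinder radius (um), positive.
#' @param L cylinder length (um), positive.
#' @return dimensionless volume ratio `Vs / Vc`.
#' @examples
#' sphereToCylinderVolumeRatio(0.5, 3)   # 1.778
#' @export
sphereToCylinderVolumeRatio <- function(Rc, L) {
  if (any(!is.finite(Rc) | Rc <= 0) || any(!is.finite(L) | L <= 0))
    stop("domain error: Rc and L must be positive")
  32 * Rc / (3 * L)
}
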