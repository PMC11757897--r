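#' Rheology parameters
#'
#' Bundle of physical constants entering the single-vessel flow law. Only the
#' plasma viscosity is tunable; it cancels from the dimensionless network
#' equations (all residuals are flow ratios), so the default of 1 is used
#' throughout unless an absolute viscosity scale is wanted.
#'
#' @param mu_p Plasma viscosity, in any consistent viscosity unit. Must be
#'   strictly positive.
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(mu_p = 1) {
  stopifnot(is.numeric(mu_p), length(mu_p) == 1L, is.finite(mu_p), mu_p > 0)
  structure(list(mu_p = mu_p), class = "rheology_params")
}

#' Relative apparent blood viscosity at 45% haematocrit
#'
#' Empirical in-vivo fit of the Fahraeus-Lindqvist effect: the relative
#' apparent viscosity of blood at discharge haematocrit 0.45 as a function of
#' vessel diameter,
#' \deqn{\mu_{45}(D) = 6 e^{-0.085 D} + 3.2 - 2.44 e^{-0.06 D^{0.645}}.}
#' Tends to 3.2 for large diameters.
#'
#' @param D Vessel diameter in micrometres; must exceed 1.1 (the singular
#'   diameter of the full viscosity law).
#' @return Dimensionless relative viscosity, strictly positive. Vectorised in
#'   `D`.
#' @export
mu_45 <- function(D) {
  check_diameter(D)
  6 * exp(-0.085 * D) + 3.2 - 2.44 * exp(-0.06 * D^0.645)
}

#' Haematocrit-dependence shape coefficient of the viscosity law
#'
#' \deqn{C(D) = (0.8 + e^{-0.075 D})\left(-1 + \frac{1}{1 + 10^{-11} D^{12}}\right)
#'   + \frac{1}{1 + 10^{-11} D^{12}}.}
#' Tends to -0.8 for large `D` and to 1 as `D` tends to zero.
#'
#' @param D Vessel diameter in micrometres, positive.
#' @return Dimensionless coefficient. Vectorised in `D`.
#' @export
coeff_C <- function(D) {
  stopifnot(is.numeric(D), all(is.finite(D)), all(D > 0))
  f <- 1 / (1 + 1e-11 * D^12)
  (0.8 + exp(-0.075 * D)) * (f - 1) + f
}

#' In-vivo apparent viscosity of blood
#'
#' Apparent viscosity of blood flowing in a vessel of diameter `D` micrometres
#' at tube haematocrit `H`:
#' \deqn{\mu(H, D) = \mu_p\left[1 + (\mu_{45} - 1)
#'   \frac{(1-H)^C - 1}{0.55^C - 1}\left(\frac{D}{D-1.1}\right)^2\right]
#'   \left(\frac{D}{D-1.1}\right)^2.}
#' At `H = 0` this reduces to `mu_p * (D/(D-1.1))^2`.
#'
#' @param H Haematocrit fraction in `[0, 1)`.
#' @param D Vessel diameter in micrometres, `> 1.1`.
#' @param params A [rheology_params()] object.
#' @return Viscosity in the units of `mu_p`. Vectorised over `H` and `D`.
#' @export
apparent_viscosity <- function(H, D, params = rheology_params()) {
  check_diameter(D)
  if (any(!is.finite(H)) || any(H < 0) || any(H >= 1)) {
    stop("haematocrit must lie in [0, 1)", call. = FALSE)
  }
  C <- coeff_C(D)
  wall <- (D / (D - 1.1))^2
  params$mu_p * (1 + (mu_45(D) - 1) * ((1 - H)^C - 1) / (0.55^C - 1) * wall) * wall
}

#' Hydraulic resistance of a vessel
#'
#' Poiseuille resistance with the in-vivo apparent viscosity:
#' \deqn{R = \frac{128 L \mu(H, D)}{\pi D^4}.}
#'
#' @param H Haematocrit fraction in `[0, 1)`.
#' @param D Vessel diameter in micrometres, `> 1.1`.
#' @param L Vessel length (any consistent length unit; the package works in
#'   multiples of a reference length), strictly positive.
#' @param params A [rheology_params()] object.
#' @return Resistance (pressure per volumetric flow); linear in `L`.
#' @export
hydraulic_resistance <- function(H, D, L, params = rheology_params()) {
  stopifnot(is.numeric(L), all(is.finite(L)), all(L > 0))
  128 * L * apparent_viscosity(H, D, params) / (pi * D^4)
}

#' Poiseuille flow through a vessel
#'
#' Signed volumetric flow `Q = (P_up - P_down) / R`. Positive when the
#' upstream pressure exceeds the downstream pressure.
#'
#' @param P_upstream,P_downstream Pressures at the two vessel ends.
#' @param R Hydraulic resistance, strictly positive.
#' @return Signed volumetric flow.
#' @export
poiseuille_flow <- function(P_upstream, P_downstream, R) {
  stopifnot(all(R > 0))
  (P_upstream - P_downstream) / R
}

check_diameter <- function(D) {
  if (any(!is.finite(D)) || any(D <= 1.1)) {
    stop("diameter must exceed 1.1 micrometres (singular diameter of the viscosity law)",
         call. = FALSE)
  }
  invisible(D)
}
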