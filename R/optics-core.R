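#' Construct a homogeneous scattering slab (phantom description)
#'
#' An `optical_slab` bundles the geometry and bulk optical properties of a
#' plane-parallel, homogeneous turbid medium: thickness `d` (mm), effective
#' (reduced) scattering coefficient \eqn{\mu_s' = \mu_s (1-g)} (1/mm),
#' absorption coefficient \eqn{\mu_a} (1/mm), Henyey-Greenstein anisotropy
#' `g`, and the refractive indices of the slab and the surrounding medium.
#' Derived quantities are stored alongside: the scattering coefficient
#' \eqn{\mu_s = \mu_s'/(1-g)}, the attenuation coefficient
#' \eqn{\mu_t = \mu_s + \mu_a}, the transport mean free path
#' \eqn{\ell' = 1/\mu_s'} and the transport optical thickness
#' \eqn{\tau = \mu_s' d}.
#'
#' Units are fixed package-wide: lengths in mm, coefficients in 1/mm,
#' angles in radians.
#'
#' @param d slab thickness in mm, > 0.
#' @param mus_prime effective scattering coefficient in 1/mm, >= 0.
#' @param mua absorption coefficient in 1/mm, >= 0.
#' @param g Henyey-Greenstein anisotropy factor, 0 <= g < 1.
#' @param n_slab refractive index of the slab medium (default 1.552,
#'   epoxy-resin at 633 nm).
#' @param n_ambient refractive index of the surroundings (default 1, air).
#' @param id optional sample identifier string.
#' @return An object of class `optical_slab`.
#' @examples
#' s <- optical_slab(d = 0.947, mus_prime = 3.781, mua = 0.0020, g = 0.6)
#' s$tau            # transport optical thickness mus_prime * d
#' @export
optical_slab <- function(d, mus_prime, mua, g = 0.6,
                         n_slab = 1.552, n_ambient = 1.0, id = NULL) {
  stopifnot(is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(mus_prime), length(mus_prime) == 1L,
            is.numeric(mua), length(mua) == 1L,
            is.numeric(g), length(g) == 1L)
  if (d <= 0) stop("slab thickness 'd' must be > 0")
  if (mus_prime < 0) stop("'mus_prime' must be >= 0")
  if (mua < 0) stop("'mua' must be >= 0")
  if (g < 0 || g >= 1) stop("anisotropy 'g' must satisfy 0 <= g < 1")
  if (n_slab < 1 || n_ambient < 1) stop("refractive indices must be >= 1")
  dc <- derive_coefficients(mus_prime, g, mua, d)
  structure(list(
    id = id, d = d, mus_prime = mus_prime, mua = mua, g = g,
    n_slab = n_slab, n_ambient = n_ambient,
    mus = dc[["mus"]], mut = dc[["mut"]],
    l_transport = dc[["l_transport"]], tau = dc[["tau"]]
  ), class = "optical_slab")
}

#' @export
print.optical_slab <- function(x, ...) {
  cat(sprintf("optical_slab%s: d = %g mm, mus' = %g /mm, mua = %g /mm, g = %g\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$d, x$mus_prime, x$mua, x$g))
  cat(sprintf("  n_slab = %g, n_ambient = %g | mus = %g /mm, mut = %g /mm, tau = %g\n",
              x$n_slab, x$n_ambient, x$mus, x$mut, x$tau))
  invisible(x)
}

#' Derived transport coefficients
#'
#' From \eqn{(\mu_s', g, \mu_a, d)} compute the scattering coefficient
#' \eqn{\mu_s = \mu_s'/(1-g)}, attenuation coefficient
#' \eqn{\mu_t = \mu_s + \mu_a}, transport mean free path
#' \eqn{\ell' = 1/\mu_s'} (`Inf` for a non-scattering slab) and transport
#' optical thickness \eqn{\tau = \mu_s' d}.
#'
#' @param mus_prime effective scattering coefficient (1/mm).
#' @param g anisotropy, 0 <= g < 1.
#' @param mua absorption coefficient (1/mm).
#' @param d thickness (mm).
#' @return Named numeric vector `(mus, mut, l_transport, tau)`.
#' @export
derive_coefficients <- function(mus_prime, g, mua, d) {
  stopifnot(mus_prime >= 0, mua >= 0, d > 0)
  if (g >= 1 || g < 0) stop("anisotropy 'g' must satisfy 0 <= g < 1")
  mus <- mus_prime / (1 - g)
  c(mus = mus, mut = mus + mua,
    l_transport = if (mus_prime > 0) 1 / mus_prime else Inf,
    tau = mus_prime * d)
}

#' Detection aperture
#'
#' The angular acceptance of a collecting objective, defined by its numerical
#' aperture `na` on the ambient (detection) side: the maximum accepted polar
#' angle is \eqn{\theta_{max} = \arcsin(NA / n_{ambient})}.
#'
#' @param na numerical aperture, 0 < na <= n_ambient.
#' @param n_ambient refractive index of the detection-side medium (default 1).
#' @return Object of class `detection_aperture` with fields `na`, `n_ambient`
#'   and `theta_max` (radians).
#' @examples
#' detection_aperture(0.8)$theta_max   # 0.9273 rad = 53.13 deg
#' @export
detection_aperture <- function(na, n_ambient = 1.0) {
  th <- aperture_angle(na, n_ambient)
  structure(list(na = na, n_ambient = n_ambient, theta_max = th),
            class = "detection_aperture")
}

#' Maximum accepted polar angle of a numerical aperture
#'
#' @param na numerical aperture, 0 < na <= n_ambient.
#' @param n_ambient refractive index of the medium the objective sits in.
#' @return \eqn{\theta_{max} = \arcsin(NA/n_{ambient})} in radians.
#' @export
aperture_angle <- function(na, n_ambient = 1.0) {
  stopifnot(is.numeric(na), length(na) == 1L, is.numeric(n_ambient))
  if (na <= 0) stop("numerical aperture must be > 0")
  if (na > n_ambient) stop("numerical aperture cannot exceed n_ambient")
  asin(na / n_ambient)
}

#' Unpolarized Fresnel power reflectance
#'
#' Average of the s- and p-polarized Fresnel power reflectances for light
#' incident from a medium of index `n_incident` onto a medium of index
#' `n_transmitted` at direction cosine `mu` (cosine of the incidence angle,
#' measured from the interface normal). Beyond the critical angle the
#' reflectance is 1 (total internal reflection).
#'
#' @param n_incident refractive index on the incidence side.
#' @param n_transmitted refractive index on the transmission side.
#' @param mu cosine of the incidence angle, 0 < mu <= 1 (vectorized).
#' @return Power reflectance in `[0, 1]`, same length as `mu`.
#' @examples
#' fresnel_reflectance(1.0, 1.552, 1.0)           # normal incidence, 0.0468
#' fresnel_reflectance(1.552, 1.0, cos(80 * pi / 180))  # TIR, 1
#' @export
fresnel_reflectance <- function(n_incident, n_transmitted, mu) {
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu > 1))
    stop("'mu' must satisfy 0 < mu <= 1")
  if (n_incident <= 0 || n_transmitted <= 0)
    stop("refractive indices must be positive")
  sin_i2 <- 1 - mu^2
  sin_t2 <- (n_incident / n_transmitted)^2 * sin_i2
  r <- numeric(length(mu))
  tir <- sin_t2 >= 1
  r[tir] <- 1
  ok <- !tir
  if (any(ok)) {
    ci <- mu[ok]
    ct <- sqrt(1 - sin_t2[ok])
    rs <- (n_incident * ci - n_transmitted * ct) /
          (n_incident * ci + n_transmitted * ct)
    rp <- (n_incident * ct - n_transmitted * ci) /
          (n_incident * ct + n_transmitted * ci)
    r[ok] <- 0.5 * (rs^2 + rp^2)
  }
  r
}

# cosine of the internal critical angle for slab -> ambient transmission;
# 0 when no total internal reflection occurs (n_slab <= n_ambient)
critical_mu <- function(n_slab, n_ambient) {
  if (n_slab <= n_ambient) return(0)
  sqrt(1 - (n_ambient / n_slab)^2)
}
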