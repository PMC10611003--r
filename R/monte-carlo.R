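#' Photon-transport Monte Carlo simulation of a slab
#'
#' Launches a normally incident pencil beam of unit power onto the top face
#' of the slab and tracks photon packets until they escape or are absorbed.
#' Free path lengths are sampled with rate \eqn{\mu_t}; scattering angles are
#' drawn from the Henyey-Greenstein phase function; absorption uses implicit
#' capture (weight reduction by the single-scattering albedo at each
#' collision) with compensated Russian roulette, so the transmitted,
#' reflected and absorbed tallies sum to 1 exactly. Each boundary crossing
#' is decided probabilistically with the angle-dependent unpolarized Fresnel
#' reflectance. Photons that reach the lower boundary without a single
#' scattering event form the ballistic tally; scattered transmitted photons
#' are histogrammed by their refracted exit angle in the ambient medium.
#'
#' Serves as the stochastic verification oracle for the deterministic P_N
#' solver ([solve_pn()]) and as an alternative forward engine for the
#' integrating-sphere look-up table ([build_lut()]).
#'
#' @param slab an [optical_slab()].
#' @param n_photons number of photon packets (>= 1).
#' @param seed mandatory integer RNG seed, recorded in the result.
#' @param n_angle_bins number of uniform exit-angle bins over `[0, pi/2]`
#'   (default 90, resolving the NA = 0.8 acceptance edge at 53.13 degrees).
#' @param n_z_bins optional number of depth bins for a track-length estimate
#'   of the diffuse (post-first-scatter) fluence; 0 disables the tally.
#' @param w_roulette weight threshold below which Russian roulette is played.
#' @param p_survive roulette survival probability.
#' @return An object of class `mc_result`: fractions `t_total`, `r_total`,
#'   `a_total`, `t_ballistic` of the unit incident power with standard errors
#'   (`se_*`), the per-bin scattered transmission `t_angular` with
#'   `se_angular` and bin edges `theta_edges` (ambient-medium radians),
#'   optionally `fluence_diffuse` on depth grid `z_mid`, plus `n_photons`
#'   and `seed`.
#' @examples
#' s <- optical_slab(d = 1, mus_prime = 0, mua = 0.5, g = 0)
#' m <- mc_simulate(s, n_photons = 1e4, seed = 1)
#' m$t_total + m$r_total + m$a_total   # exactly 1
#' @export
mc_simulate <- function(slab, n_photons, seed, n_angle_bins = 90L,
                        n_z_bins = 0L, w_roulette = 1e-4, p_survive = 0.1) {
  stopifnot(inherits(slab, "optical_slab"))
  if (!is.numeric(n_photons) || length(n_photons) != 1L || n_photons < 1)
    stop("'n_photons' must be a positive count")
  if (missing(seed) || !is.numeric(seed))
    stop("an explicit integer 'seed' is required")
  n_photons <- as.integer(round(n_photons))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  raw <- .mc_slab(slab$d, slab$mus, slab$mua, slab$g,
                  slab$n_slab, slab$n_ambient,
                  n_photons, as.integer(n_angle_bins), as.integer(n_z_bins),
                  w_roulette, p_survive)
  n <- n_photons
  mv <- function(s, s2) {           # mean and standard error of the mean
    m <- s / n
    v <- pmax(0, s2 / n - m^2)
    list(mean = m, se = sqrt(v / n))
  }
  t_ <- mv(raw$sum_t, raw$sum2_t); r_ <- mv(raw$sum_r, raw$sum2_r)
  a_ <- mv(raw$sum_a, raw$sum2_a); b_ <- mv(raw$sum_b, raw$sum2_b)
  bins <- mv(raw$bins, raw$bins2)
  edges <- seq(0, pi / 2, length.out = n_angle_bins + 1L)
  out <- list(
    n_photons = n, seed = as.integer(seed),
    t_total = t_$mean, se_t = t_$se,
    r_total = r_$mean, se_r = r_$se,
    a_total = a_$mean, se_a = a_$se,
    t_ballistic = b_$mean, se_ballistic = b_$se,
    t_angular = bins$mean, se_angular = bins$se,
    theta_edges = edges,
    balance = raw$sum_total / n    # conservation diagnostic, should be 1
  )
  if (n_z_bins > 0) {
    dz <- slab$d / n_z_bins
    out$z_mid <- (seq_len(n_z_bins) - 0.5) * dz
    fm <- mv(raw$fluence, raw$fluence2)
    out$fluence_diffuse <- fm$mean / dz
    out$se_fluence <- fm$se / dz
  }
  class(out) <- "mc_result"
  out
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("mc_result: %g photons (seed %d)\n", x$n_photons, x$seed))
  cat(sprintf("  T = %.5f (%.1e)  R = %.5f (%.1e)  A = %.5f (%.1e)  T_ball = %.5f\n",
              x$t_total, x$se_t, x$r_total, x$se_r, x$a_total, x$se_a,
              x$t_ballistic))
  invisible(x)
}

#' Inverse-CDF sample of the Henyey-Greenstein scattering cosine
#'
#' Maps a uniform variate `u` in `[0, 1)` to the cosine of the polar
#' scattering angle of the Henyey-Greenstein phase function with anisotropy
#' `g`; for `g = 0` this reduces to the isotropic `2 u - 1`.
#'
#' @param g anisotropy, 0 <= g < 1.
#' @param u uniform variate(s) in `[0, 1)`.
#' @return Scattering-angle cosine(s) in `[-1, 1]`.
#' @export
hg_sample <- function(g, u) {
  stopifnot(g >= 0, g < 1, all(u >= 0), all(u < 1))
  if (g == 0) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Partial angular transmittance from Monte Carlo tallies
#'
#' Sums the scattered angular-bin tallies whose ambient exit angle lies
#' inside the acceptance cone of `aperture` (the partially covered edge bin
#' contributes its covered angular fraction) and adds the ballistic tally,
#' which at normal incidence always falls inside any positive aperture.
#'
#' @param result an `mc_result` from [mc_simulate()].
#' @param aperture a [detection_aperture()].
#' @return Named list `t_na_diffuse`, `t_na`, `se` (standard error of
#'   `t_na`).
#' @export
mc_integrate_na <- function(result, aperture) {
  stopifnot(inherits(result, "mc_result"))
  if (!inherits(aperture, "detection_aperture"))
    stop("'aperture' must be a detection_aperture")
  th <- aperture$theta_max
  edges <- result$theta_edges
  full <- edges[-1] <= th
  frac <- pmin(1, pmax(0, (th - edges[-length(edges)]) / diff(edges)))
  w <- ifelse(full, 1, frac)
  t_diff <- sum(w * result$t_angular)
  se2 <- sum((w * result$se_angular)^2) + result$se_ballistic^2
  list(t_na_diffuse = t_diff,
       t_na = t_diff + result$t_ballistic,
       se = sqrt(se2))
}
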