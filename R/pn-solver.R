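# P_N (spherical-harmonic) solution of the radiative transfer equation in a
# plane-parallel slab under normally incident, unit-power plane-wave
# illumination, with Henyey-Greenstein scattering and refractive-index
# mismatched boundaries.
#
# The collimated beam is kept as a separate unscattered component (a delta
# in angle cannot be represented by a truncated Legendre series); the P_N
# system is solved for the scattered (diffuse) radiance only, driven by the
# first-scatter source of the exponentially attenuated beam including its
# specular internal reflections. Boundary conditions are Marshak half-range
# moments weighted by the angle-dependent Fresnel reflectance.
#
# The exiting radiance is NOT obtained by summing the truncated Legendre
# series at the boundary (which rings); instead the P_N-reconstructed source
# function is inserted into the characteristic (integral) form of the RTE
# and integrated analytically along exit rays, with the internal-reflection
# exchange between the two faces summed in closed form. The boundary values
# so obtained satisfy the exact Fresnel boundary condition
# L(inward mu) = R_F(mu) * L(outward mu) by construction.

# Legendre polynomials P_0..P_lmax at points x: matrix length(x) x (lmax+1)
legendre_table <- function(lmax, x) {
  P <- matrix(0, length(x), lmax + 1L)
  P[, 1L] <- 1
  if (lmax >= 1L) P[, 2L] <- x
  if (lmax >= 2L) for (l in 1L:(lmax - 1L))
    P[, l + 2L] <- ((2 * l + 1) * x * P[, l + 1L] - l * P[, l]) / (l + 1)
  P
}

# cache for boundary-condition matrices (depend only on order and indices)
.pn_cache <- new.env(parent = emptyenv())

# Marshak half-range matrices:
#   H[m, l]  = int_0^1 P_m P_l dmu
#   HR[m, l] = int_0^1 R(mu) P_m P_l dmu   (R = internal Fresnel reflectance)
# for the odd test orders m = 1, 3, ..., order.
marshak_matrices <- function(order, n_slab, n_ambient) {
  key <- sprintf("%d|%.12g|%.12g", order, n_slab, n_ambient)
  if (!is.null(.pn_cache[[key]])) return(.pn_cache[[key]])
  mu_c <- critical_mu(n_slab, n_ambient)
  segs <- if (mu_c > 0) list(c(0, mu_c), c(mu_c, 1)) else list(c(0, 1))
  nodes <- do.call(rbind, lapply(segs, function(ab) {
    q <- pracma::gaussLegendre(128, ab[1], ab[2])
    cbind(q$x, q$w)
  }))
  x <- nodes[, 1]; w <- nodes[, 2]
  R <- ifelse(x <= mu_c, 1,
              fresnel_reflectance(n_slab, n_ambient, pmax(x, 1e-14)))
  P <- legendre_table(order, x)
  m_odd <- seq(1L, order, by = 2L)
  H  <- t(P[, m_odd + 1L, drop = FALSE] * w)     %*% P
  HR <- t(P[, m_odd + 1L, drop = FALSE] * (w * R)) %*% P
  out <- list(H = H, HR = HR, m_odd = m_odd)
  .pn_cache[[key]] <- out
  out
}

#' Solve the P_N system for the scattered radiance in a slab
#'
#' Expands the azimuthally symmetric scattered radiance in Legendre moments
#' \eqn{\psi_l(z)}, \eqn{l = 0, \dots, N} (odd truncation order `N`), and
#' solves the coupled moment system
#' \deqn{(l+1)\psi'_{l+1} + l\,\psi'_{l-1} + (2l+1)(\mu_t - \mu_s g^l)\psi_l
#'   = (2l+1)\, q_l(z)}
#' where \eqn{g^l} are the Henyey-Greenstein phase-function moments and
#' \eqn{q_l} is the first-scatter source fed by the exponentially attenuated
#' collimated beam (both its downward pass and the specular internal
#' reflections between the faces). The homogeneous part is diagonalized via
#' a symmetrized eigenproblem (eigenvalues come in \eqn{\pm} pairs); growing
#' modes are anchored at the lower boundary so all basis amplitudes stay
#' of order one regardless of optical thickness. Boundary conditions are
#' Marshak half-range moments incorporating the angle-dependent internal
#' Fresnel reflectance at both interfaces.
#'
#' A slab with `mus_prime = 0` has no scattered field; the returned solution
#' is identically zero (the collimated component is handled in closed form
#' by [ballistic_transmittance()]).
#'
#' @param slab an [optical_slab()].
#' @param order odd P_N truncation order (default 15).
#' @return Object of class `pn_solution` holding the eigenmodes
#'   (`lambda`, `modes`), mode amplitudes `coef`, the particular solution
#'   (`part_p`, `part_r` for the `exp(-mut z)` / `exp(+mut z)` drives), the
#'   collimated amplitudes `A_plus`, `A_minus`, and solver metadata.
#' @export
solve_pn <- function(slab, order = 15L) {
  stopifnot(inherits(slab, "optical_slab"))
  order <- as.integer(order)
  if (order < 1L || order %% 2L == 0L)
    stop("P_N truncation 'order' must be an odd integer >= 1")
  d <- slab$d
  # tiny absorption floor regularizes the conservative (mua = 0) case, whose
  # exact P_N system has a degenerate zero eigenvalue pair
  mua <- max(slab$mua, 1e-9)
  mus <- slab$mus
  mut <- mus + mua
  g <- slab$g
  lvec <- 0:order
  n <- order + 1L
  gl <- g^lvec
  sigma <- mut - mus * gl

  # collimated (unscattered) beam inside the slab, unit incident power:
  #   C+(z) = A_plus exp(-mut z), C-(z) = A_minus exp(+mut z)
  Rn <- fresnel_reflectance(slab$n_ambient, slab$n_slab, 1)
  Tn <- 1 - Rn
  E2 <- exp(-2 * mut * d)
  D0 <- 1 - Rn^2 * E2
  A_plus <- Tn / D0
  A_minus <- Tn * Rn * E2 / D0

  base <- list(slab = slab, order = order, mua_eff = mua, mut = mut,
               mus = mus, gl = gl, A_plus = A_plus, A_minus = A_minus,
               Rn_int = fresnel_reflectance(slab$n_slab, slab$n_ambient, 1))

  if (mus == 0) {
    sol <- c(base, list(lambda = numeric(0),
                        modes = matrix(0, n, 0), coef = numeric(0),
                        part_p = numeric(0) * NA, zero = TRUE))
    sol$part_p <- rep(0, n); sol$part_r <- rep(0, n)
    class(sol) <- "pn_solution"
    return(sol)
  }

  # symmetrized eigenproblem: C u = alpha u with C = S^-1/2 B S^-1/2,
  # B tridiagonal streaming matrix in normalized moments, S = diag(sigma_l);
  # spatial rates lambda = -1/alpha
  bvec <- (1:order) / sqrt((2 * (0:(order - 1)) + 1) * (2 * (0:(order - 1)) + 3))
  s12 <- 1 / sqrt(sigma)
  Cmat <- matrix(0, n, n)
  idx <- cbind(1:(n - 1L), 2:n)
  Cmat[idx] <- bvec * s12[-n] * s12[-1]
  Cmat[idx[, 2:1, drop = FALSE]] <- Cmat[idx]
  es <- eigen(Cmat, symmetric = TRUE)
  if (any(abs(es$values) < 1e-300))
    stop("P_N eigen-solve failed (singular streaming spectrum); ",
         "the slab parameters are numerically degenerate")
  lambda <- -1 / es$values
  modes <- (s12 * es$vectors) / sqrt(2 * lvec + 1)  # psi-space eigenvectors

  # particular solutions for the two exponential drives
  Amat <- matrix(0, n, n)
  Amat[idx] <- 1:(n - 1L)            # (l+1) psi'_{l+1}
  Amat[idx[, 2:1, drop = FALSE]] <- 1:(n - 1L)     # l psi'_{l-1}
  Dmat <- diag((2 * lvec + 1) * sigma, n)
  solve_part <- function(rate, rhs) {
    M <- rate * Amat + Dmat
    p <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(p) || any(!is.finite(p))) {
      # resonance of the drive rate with an eigenmode: detune infinitesimally
      p <- solve(rate * (1 + 1e-8) * Amat + Dmat, rhs)
    }
    p
  }
  part_p <- solve_part(-mut, (2 * lvec + 1) * mus * gl * A_plus)
  part_r <- if (A_minus > 0)
    solve_part(+mut, (2 * lvec + 1) * mus * gl * (-1)^lvec * A_minus)
  else rep(0, n)

  # boundary systems: Marshak half-range moments with Fresnel weighting
  mm <- marshak_matrices(order, slab$n_slab, slab$n_ambient)
  two_l1 <- 2 * lvec + 1
  sgn <- (-1)^lvec
  Wtop <- sweep(mm$H, 2L, two_l1, `*`) -
          sweep(mm$HR, 2L, two_l1 * sgn, `*`)
  Wbot <- sweep(mm$H, 2L, two_l1 * sgn, `*`) -
          sweep(mm$HR, 2L, two_l1, `*`)

  neg <- lambda <= 0
  e0 <- ifelse(neg, 1, exp(-lambda * d))           # basis value at z = 0
  ed <- ifelse(neg, exp(lambda * d), 1)            # basis value at z = d
  part0 <- part_p + part_r
  rd <- if (A_minus > 0) part_r * exp(mut * d) else rep(0, n)
  partd <- part_p * exp(-mut * d) + rd

  M <- rbind(Wtop %*% sweep(modes, 2L, e0, `*`),
             Wbot %*% sweep(modes, 2L, ed, `*`))
  b <- -c(Wtop %*% part0, Wbot %*% partd)
  coef <- tryCatch(solve(M, b), error = function(e)
    stop("P_N boundary system is singular; increase the order or check ",
         "the slab parameters (extreme optical thickness?)"))
  if (any(!is.finite(coef)))
    stop("P_N boundary solve produced non-finite amplitudes")

  sol <- c(base, list(lambda = lambda, modes = modes, coef = coef,
                      part_p = part_p, part_r = part_r, zero = FALSE))
  class(sol) <- "pn_solution"
  sol
}

#' @export
print.pn_solution <- function(x, ...) {
  cat(sprintf("pn_solution: P_%d, slab d = %g mm, mus' = %g, mua = %g, g = %g\n",
              x$order, x$slab$d, x$slab$mus_prime, x$slab$mua, x$slab$g))
  invisible(x)
}

# Legendre moments psi_l(z) of the scattered radiance: matrix (order+1) x nz
pn_moments <- function(sol, z) {
  n <- sol$order + 1L
  if (sol$zero) return(matrix(0, n, length(z)))
  d <- sol$slab$d
  neg <- sol$lambda <= 0
  E <- vapply(seq_along(sol$lambda), function(j) {
    if (neg[j]) exp(sol$lambda[j] * z) else exp(sol$lambda[j] * (z - d))
  }, numeric(length(z)))
  E <- matrix(E, nrow = length(z))
  psi <- sol$modes %*% (t(E) * sol$coef)
  psi <- psi + outer(sol$part_p, exp(-sol$mut * z))
  if (sol$A_minus > 0)
    psi <- psi + outer(sol$part_r, exp(sol$mut * z))
  psi
}

# analytic exit-ray integrals of the P_N source function.
# For outward cosines mu in (0,1] returns the interior radiance leaving
# through the bottom, L(d, mu), and through the top, L(0, -mu), with the
# face-to-face internal-reflection exchange summed in closed form.
pn_exit_radiance <- function(sol, mu) {
  nmu <- length(mu)
  if (sol$zero) return(list(bottom = rep(0, nmu), top = rep(0, nmu)))
  d <- sol$slab$d
  mut <- sol$mut
  lvec <- 0:sol$order
  wl <- sol$mus * (2 * lvec + 1) * sol$gl / (4 * pi)

  # z-expansion of the source coefficients: one column per exponential term
  kap <- c(sol$lambda, -mut, mut)
  off <- c(ifelse(sol$lambda <= 0, 0, -sol$lambda * d), 0, 0)
  Cf <- cbind(sweep(sol$modes, 2L, sol$coef, `*`),
              sol$part_p + sol$A_plus,
              sol$part_r + (-1)^lvec * sol$A_minus)

  P <- legendre_table(sol$order, mu)
  Bp <- (P %*% (wl * Cf))                      # beta_t(+mu)
  Bm <- (sweep(P, 2L, (-1)^lvec, `*`) %*% (wl * Cf))  # beta_t(-mu)

  h <- mut / mu
  # J+ = int_0^d exp(kap z + off) exp(-(d - z) h) dz  (per mu x term)
  KD <- outer(rep(1, nmu), kap * d + off)
  HD <- outer(h * d, rep(1, length(kap)))
  OF <- outer(rep(1, nmu), off)
  DEN_p <- outer(h, kap, `+`)
  Jp <- (exp(KD) - exp(OF - HD)) / DEN_p
  small <- abs(DEN_p * d) < 1e-9
  if (any(small)) Jp[small] <- (exp(OF - HD) * d)[small]
  # J- = int_0^d exp(kap z + off) exp(-z h) dz
  DEN_m <- outer(-h, kap, `+`)
  Jm <- (exp(KD - HD) - exp(OF)) / DEN_m
  small <- abs(DEN_m * d) < 1e-9
  if (any(small)) Jm[small] <- (exp(OF) * d)[small]

  Ip <- rowSums(Bp * Jp) / mu
  Im <- rowSums(Bm * Jm) / mu
  a <- exp(-h * d)
  R <- fresnel_reflectance(sol$slab$n_slab, sol$slab$n_ambient, mu)
  den <- 1 - (R * a)^2
  list(bottom = (Ip + R * a * Im) / den,
       top    = (Im + R * a * Ip) / den)
}

#' Scattered radiance at a slab boundary
#'
#' Evaluates the diffuse (scattered) interior radiance at the top or bottom
#' face. The default `"hybrid"` method integrates the P_N-reconstructed
#' source function along exit characteristics (see [solve_pn()]); it is free
#' of truncation ringing and satisfies the exact Fresnel boundary condition
#' \eqn{L(\mathrm{inward}\ \mu) = R_F(\mu) L(\mathrm{outward}\ \mu)}
#' identically. The `"series"` method sums the truncated Legendre series at
#' the boundary and is provided for comparison (it rings and violates the
#' boundary condition at finite order).
#'
#' @param solution a `pn_solution` from [solve_pn()].
#' @param boundary `"bottom"` (z = d, detection side) or `"top"` (z = 0).
#' @param mu interior direction cosine(s) in `[-1, 1]`, positive = outward
#'   at the chosen boundary; `mu = 0` returns the grazing limit.
#' @param method `"hybrid"` (default) or `"series"`.
#' @return Radiance per unit solid angle, for unit incident power.
#' @export
boundary_radiance <- function(solution, boundary = c("bottom", "top"), mu,
                              method = c("hybrid", "series")) {
  stopifnot(inherits(solution, "pn_solution"))
  boundary <- match.arg(boundary)
  method <- match.arg(method)
  if (any(abs(mu) > 1)) stop("direction cosine 'mu' must lie in [-1, 1]")
  if (method == "series") {
    z <- if (boundary == "bottom") solution$slab$d else 0
    psi <- pn_moments(solution, z)[, 1]
    # global-frame cosine: outward at bottom = +mu, outward at top = -mu
    mu_g <- if (boundary == "bottom") mu else -mu
    P <- legendre_table(solution$order, mu_g)
    return(as.numeric(P %*% ((2 * (0:solution$order) + 1) * psi)) / (4 * pi))
  }
  out <- numeric(length(mu))
  am <- abs(mu)
  pos <- am > 0
  if (any(pos)) {
    ex <- pn_exit_radiance(solution, am[pos])
    Lout <- if (boundary == "bottom") ex$bottom else ex$top
    R <- fresnel_reflectance(solution$slab$n_slab, solution$slab$n_ambient,
                             am[pos])
    out[pos] <- ifelse(mu[pos] > 0, Lout, R * Lout)
  }
  if (any(!pos)) {
    # grazing limit: L -> Q(z_boundary, 0) / mut
    z <- if (boundary == "bottom") solution$slab$d else 0
    if (solution$zero) {
      out[!pos] <- 0
    } else {
      psi <- pn_moments(solution, z)[, 1]
      lvec <- 0:solution$order
      wl <- solution$mus * (2 * lvec + 1) * solution$gl / (4 * pi)
      Cb <- exp(-solution$mut * z) * solution$A_plus
      Cb2 <- if (solution$A_minus > 0) solution$A_minus * exp(solution$mut * z) else 0
      P0 <- legendre_table(solution$order, 0)[1, ]
      Q0 <- sum(wl * P0 * psi) + sum(wl * P0 * Cb) +
            sum(wl * P0 * (-1)^lvec * Cb2)
      out[!pos] <- Q0 / solution$mut
    }
  }
  out
}

#' Ballistic (unscattered) transmittance of a slab
#'
#' Closed form for the collimated delta component transmitted through the
#' lower face at normal incidence, including the full geometric series of
#' specular internal reflections:
#' \deqn{T_{ball} = \frac{T_F^2 e^{-\mu_t d}}{1 - R_F^2 e^{-2 \mu_t d}}}
#' with normal-incidence Fresnel coefficients \eqn{R_F, T_F = 1 - R_F}.
#' For any positive numerical aperture the forward delta falls inside the
#' acceptance cone, so the value is independent of the aperture.
#'
#' @param slab an [optical_slab()].
#' @param aperture optional [detection_aperture()]; only validated, the
#'   ballistic delta is inside any NA > 0.
#' @param single_pass if `TRUE`, drop the internal-reflection series and
#'   return the single-pass value \eqn{T_F^2 e^{-\mu_t d}}.
#' @return Ballistic transmittance fraction of the unit incident power.
#' @export
ballistic_transmittance <- function(slab, aperture = NULL,
                                    single_pass = FALSE) {
  stopifnot(inherits(slab, "optical_slab"))
  if (!is.null(aperture) && !inherits(aperture, "detection_aperture"))
    stop("'aperture' must be a detection_aperture")
  Rf <- fresnel_reflectance(slab$n_ambient, slab$n_slab, 1)
  Tf <- 1 - Rf
  e1 <- exp(-slab$mut * slab$d)
  if (single_pass) return(Tf^2 * e1)
  Tf^2 * e1 / (1 - Rf^2 * e1^2)
}

# specular (unscattered) reflectance at normal incidence, full series
specular_reflectance <- function(slab) {
  Rf <- fresnel_reflectance(slab$n_ambient, slab$n_slab, 1)
  Tf <- 1 - Rf
  e2 <- exp(-2 * slab$mut * slab$d)
  Rf + Tf^2 * Rf * e2 / (1 - Rf^2 * e2)
}

#' Angular transmittance table of a slab
#'
#' Solves the P_N system, maps the exiting diffuse radiance through Snell
#' refraction and Fresnel transmission into ambient-medium exit angles
#' (using the \eqn{n^2} radiance transformation, which conserves flux), and
#' integrates the hemispherical energy balance.
#'
#' @param slab an [optical_slab()].
#' @param order odd P_N truncation order.
#' @param n_angles number of points of the uniform ambient exit-angle grid.
#' @return Object of class `transmittance_table`: `angles` (radians, ambient
#'   medium), `t_diffuse` (scattered transmitted flux per unit solid angle),
#'   scalars `t_total`, `r_total`, `a_total`, `t_ballistic`, and the
#'   underlying `pn_solution`.
#' @export
angular_transmittance <- function(slab, order = 15L, n_angles = 91L) {
  stopifnot(inherits(slab, "optical_slab"))
  if (n_angles < 2L) stop("'n_angles' must be >= 2")
  sol <- solve_pn(slab, order)
  scal <- pn_hemispheric_fluxes(sol)
  theta <- seq(0, pi / 2, length.out = n_angles)
  ratio <- slab$n_ambient / slab$n_slab
  sin_i <- ratio * sin(theta)
  mu_i <- sqrt(pmax(0, 1 - sin_i^2))
  Lb <- pn_exit_radiance(sol, pmax(mu_i, 1e-12))$bottom
  Tf <- 1 - fresnel_reflectance(slab$n_slab, slab$n_ambient, pmax(mu_i, 1e-12))
  t_diff <- ratio^2 * Tf * Lb * cos(theta)
  structure(list(angles = theta, t_diffuse = t_diff,
                 t_total = scal$t_total, r_total = scal$r_total,
                 a_total = scal$a_total, t_ballistic = scal$t_ball,
                 t_diffuse_total = scal$t_diff,
                 solution = sol),
            class = "transmittance_table")
}

#' @export
print.transmittance_table <- function(x, ...) {
  cat(sprintf("transmittance_table: T = %.5f (ball %.5f)  R = %.5f  A = %.5f\n",
              x$t_total, x$t_ballistic, x$r_total, x$a_total))
  invisible(x)
}

# hemispherical energy balance of a pn_solution:
# diffuse T and R by Fresnel-weighted flux integrals of the exit radiance,
# absorption by analytic depth integration of the scalar fluence
pn_hemispheric_fluxes <- function(sol) {
  slab <- sol$slab
  t_ball <- ballistic_transmittance(slab)
  r_spec <- specular_reflectance(slab)
  mu_c <- critical_mu(slab$n_slab, slab$n_ambient)
  q <- pracma::gaussLegendre(96, mu_c, 1)
  ex <- pn_exit_radiance(sol, q$x)
  Tf <- 1 - fresnel_reflectance(slab$n_slab, slab$n_ambient, q$x)
  t_diff <- 2 * pi * sum(q$w * Tf * ex$bottom * q$x)
  r_diff <- 2 * pi * sum(q$w * Tf * ex$top * q$x)

  # absorbed fraction: mua * int_0^d [psi_0 + C+ + C-] dz, analytic
  d <- slab$d; mut <- sol$mut; mua <- sol$mua_eff
  if (sol$zero) {
    int_psi0 <- 0
  } else {
    neg <- sol$lambda <= 0
    intE <- ifelse(abs(sol$lambda * d) < 1e-12, d,
                   ifelse(neg,
                          (exp(sol$lambda * d) - 1) / sol$lambda,
                          (1 - exp(-sol$lambda * d)) / sol$lambda))
    int_modes <- sum(sol$modes[1, ] * sol$coef * intE)
    int_p <- sol$part_p[1] * (1 - exp(-mut * d)) / mut
    int_r <- if (sol$A_minus > 0)
      (sol$part_r[1] * exp(mut * d) - sol$part_r[1]) / mut else 0
    int_psi0 <- int_modes + int_p + int_r
  }
  Rn <- fresnel_reflectance(slab$n_ambient, slab$n_slab, 1)
  Tn <- 1 - Rn
  E1 <- exp(-mut * d); E2 <- E1^2
  D0 <- 1 - Rn^2 * E2
  int_cplus <- Tn / D0 * (1 - E1) / mut
  int_cminus <- Tn * Rn * E1 * (1 - E1) / (D0 * mut)
  a_tot <- mua * (int_psi0 + int_cplus + int_cminus) +
           slab$mua / mut * 0    # mua floor: difference is O(1e-9)
  list(t_diff = t_diff, r_diff = r_diff, t_ball = t_ball, r_spec = r_spec,
       t_total = t_diff + t_ball, r_total = r_diff + r_spec,
       a_total = a_tot)
}

#' Converged P_N order by successive doubling
#'
#' Doubles the truncation order (15, 31, 63, ...) until the partial angular
#' transmittance into the reference aperture changes by less than `tol`
#' relative, and returns the first converged order.
#'
#' @param slab an [optical_slab()].
#' @param na numerical aperture of the reference detection cone.
#' @param start starting odd order.
#' @param tol relative convergence tolerance on T_NA.
#' @param max_order upper bound on the search.
#' @return The selected odd order (integer).
#' @export
pn_auto_order <- function(slab, na = 0.8, start = 15L, tol = 1e-4,
                          max_order = 255L) {
  ap <- detection_aperture(na, slab$n_ambient)
  ord <- as.integer(start)
  t_prev <- partial_transmittance(slab, ap, order = ord)$t_na
  while (ord < max_order) {
    ord2 <- 2L * ord + 1L
    t_new <- partial_transmittance(slab, ap, order = ord2)$t_na
    if (abs(t_new - t_prev) <= tol * max(abs(t_new), 1e-300)) return(ord2)
    ord <- ord2
    t_prev <- t_new
  }
  ord
}

#' Partial angular transmittance into a detection aperture
#'
#' Integrates the diffuse exit flux over the acceptance cone of the
#' detection objective: interior directions with
#' \eqn{\mu \ge \sqrt{1 - (NA/n_{slab})^2}} refract into ambient angles
#' below \eqn{\theta_{max} = \arcsin(NA/n_{ambient})}. The ballistic delta
#' exits exactly forward and is inside any positive aperture.
#'
#' @param slab an [optical_slab()].
#' @param aperture a [detection_aperture()].
#' @param order odd P_N truncation order.
#' @param solution optional precomputed `pn_solution` (skips the solve).
#' @return Named list `t_na_diffuse`, `t_na_ballistic`, `t_na`.
#' @export
partial_transmittance <- function(slab, aperture, order = 15L,
                                  solution = NULL) {
  stopifnot(inherits(slab, "optical_slab"))
  if (!inherits(aperture, "detection_aperture"))
    stop("'aperture' must be a detection_aperture")
  if (aperture$na <= 0) stop("numerical aperture must be > 0")
  sol <- if (is.null(solution)) solve_pn(slab, order) else solution
  mu_min <- sqrt(max(0, 1 - (aperture$na / slab$n_slab)^2))
  q <- pracma::gaussLegendre(96, mu_min, 1)
  ex <- pn_exit_radiance(sol, q$x)
  Tf <- 1 - fresnel_reflectance(slab$n_slab, slab$n_ambient, q$x)
  t_diff <- 2 * pi * sum(q$w * Tf * ex$bottom * q$x)
  t_ball <- ballistic_transmittance(slab)
  list(t_na_diffuse = t_diff, t_na_ballistic = t_ball,
       t_na = t_diff + t_ball)
}
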