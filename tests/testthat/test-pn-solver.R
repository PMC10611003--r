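test_that("a non-scattering slab has an identically zero diffuse field", {
  s <- optical_slab(d = 1, mus_prime = 0, mua = 0.3, g = 0)
  sol <- solve_pn(s, 15)
  mu <- seq(-1, 1, by = 0.25)
  expect_true(all(boundary_radiance(sol, "bottom", mu) == 0))
  expect_true(all(boundary_radiance(sol, "top", mu) == 0))
  # matched-index absorber: pure Beer-Lambert ballistic transmission
  sm <- optical_slab(d = 1, mus_prime = 0, mua = 0.5, g = 0,
                     n_slab = 1, n_ambient = 1)
  tab <- angular_transmittance(sm, order = 15, n_angles = 31)
  expect_true(all(tab$t_diffuse == 0))
  expect_equal(tab$t_total, exp(-0.5), tolerance = 1e-9)
})

test_that("even truncation orders are rejected", {
  s <- table1_slab("1.2")
  expect_error(solve_pn(s, 16), "odd")
  expect_error(solve_pn(s, 0), "odd")
})

test_that("hybrid boundary radiance satisfies the exact Fresnel condition", {
  sol <- solve_pn(table1_slab("1.3"), 15)
  mu <- seq(0.01, 1, length.out = 120)
  R <- fresnel_reflectance(1.552, 1.0, mu)
  for (side in c("bottom", "top")) {
    L_out <- boundary_radiance(sol, side, mu)
    L_in <- boundary_radiance(sol, side, -mu)
    expect_lt(max(abs(L_in - R * L_out)), 1e-10 * max(L_out))
  }
  # grazing direction: finite limit, no crash
  expect_true(is.finite(boundary_radiance(sol, "bottom", 0)))
})

test_that("truncated-series boundary radiance rings; the hybrid does not", {
  sol <- solve_pn(table1_slab("1.3"), 15)
  mu <- seq(0.01, 1, length.out = 200)
  hyb <- boundary_radiance(sol, "bottom", mu)
  ser <- boundary_radiance(sol, "bottom", mu, method = "series")
  # the series-minus-hybrid residue oscillates across the hemisphere while
  # the hybrid curve itself is monotone smooth
  n_extrema <- function(v) sum(diff(sign(diff(v))) != 0)
  expect_gte(n_extrema(ser - hyb), 3)
  expect_equal(n_extrema(hyb), 0)
  # and the series violates the exact boundary condition badly
  R <- fresnel_reflectance(1.552, 1.0, mu)
  ser_in <- boundary_radiance(sol, "bottom", -mu, method = "series")
  expect_gt(max(abs(ser_in - R * ser)) / max(ser), 1e3 * 1e-10)
})

test_that("diffuse fluence is nonnegative and matches Monte Carlo", {
  s <- table1_slab("1.2")
  sol <- solve_pn(s, 15)
  z <- seq(0, s$d, length.out = 41)
  psi0 <- phantomlight:::pn_moments(sol, z)[1, ]
  expect_true(all(psi0 >= -1e-10))
  m <- mc_simulate(s, 1e5, seed = 51, n_z_bins = 20)
  pn_flu <- phantomlight:::pn_moments(sol, m$z_mid)[1, ]
  depths <- c(3, 7, 10, 14, 18)  # five interior depths
  zscore <- (pn_flu[depths] - m$fluence_diffuse[depths]) / m$se_fluence[depths]
  expect_true(all(abs(zscore) < 3))
})

test_that("energy balance closes for the bundled phantoms", {
  for (id in names(TABLE1)) {
    s <- table1_slab(id)
    tab <- angular_transmittance(s, order = 31, n_angles = 2)
    expect_lt(abs(tab$t_total + tab$r_total + tab$a_total - 1), 1e-3)
  }
  # closure tightens with order (mismatched-index phantom)
  tab63 <- angular_transmittance(table1_slab("1.3"), order = 63, n_angles = 2)
  expect_lt(abs(tab63$t_total + tab63$r_total + tab63$a_total - 1), 1e-4)
})

test_that("diffuse angular table integrates to the diffuse hemispheric flux", {
  tab <- angular_transmittance(table1_slab("2.1"), order = 15, n_angles = 721)
  th <- tab$angles
  mid <- (tab$t_diffuse[-1] + tab$t_diffuse[-length(th)]) / 2
  integral <- sum(mid * diff(th) * 2 * pi * sin((th[-1] + th[-length(th)]) / 2))
  expect_equal(integral, tab$t_diffuse_total, tolerance = 1e-5)
  expect_equal(tab$t_total - tab$t_ballistic, tab$t_diffuse_total,
               tolerance = 1e-12)
})

test_that("ballistic transmittance matches its closed forms", {
  # matched indices, mut d = 1: Beer-Lambert
  s <- optical_slab(d = 1, mus_prime = 0.5, mua = 0.5, g = 0,
                    n_slab = 1, n_ambient = 1)
  expect_equal(ballistic_transmittance(s), exp(-1), tolerance = 1e-12)
  # transparent mismatched slab: Fresnel specular series
  sv <- optical_slab(d = 1, mus_prime = 0, mua = 1e-300, g = 0)
  Rf <- fresnel_reflectance(1, 1.552, 1)
  expect_equal(ballistic_transmittance(sv), (1 - Rf)^2 / (1 - Rf^2),
               tolerance = 1e-12)
  expect_equal(ballistic_transmittance(sv), 0.91062, tolerance = 2e-5)
  # the single-pass flag drops the internal-reflection series
  s11 <- table1_slab("1.1")
  expect_lt(ballistic_transmittance(s11, single_pass = TRUE),
            ballistic_transmittance(s11))
})

test_that("partial transmittance covers limits and monotonicities", {
  s <- table1_slab("1.2")
  tab <- angular_transmittance(s, order = 31, n_angles = 2)
  # full-hemisphere aperture recovers the total transmittance
  full <- partial_transmittance(s, detection_aperture(1.0), order = 31)
  expect_equal(full$t_na, tab$t_total, tolerance = 1e-6)
  # T_NA nondecreasing in NA
  nas <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  tna <- vapply(nas, function(na)
    partial_transmittance(s, detection_aperture(na), order = 31)$t_na,
    numeric(1))
  expect_true(all(diff(tna) > 0))
  # vanishing thickness: Fresnel-limited ballistic value below 1
  s0 <- optical_slab(d = 1e-9, mus_prime = 3.688, mua = 0.0034, g = 0.6)
  p0 <- partial_transmittance(s0, detection_aperture(0.8), order = 15)
  expect_equal(p0$t_na, 0.91061, tolerance = 1e-4)
  expect_lt(p0$t_na, 1)
  expect_error(partial_transmittance(s, detection_aperture(0.8), order = 16))
})

test_that("T_NA decreases strictly with absorption", {
  ap <- detection_aperture(0.8)
  tna <- vapply(c(0.002, 0.01, 0.03, 0.06, 0.1), function(mua) {
    s <- optical_slab(d = 1.0, mus_prime = 2.75, mua = mua, g = 0.6)
    partial_transmittance(s, ap, order = 15)$t_na
  }, numeric(1))
  expect_true(all(diff(tna) < 0))
})

test_that("low and high orders agree in the diffusion regime", {
  s <- optical_slab(d = 10 / 3.8, mus_prime = 3.8, mua = 0.002, g = 0.6)
  t1 <- angular_transmittance(s, order = 1, n_angles = 2)$t_total
  t31 <- angular_transmittance(s, order = 31, n_angles = 2)$t_total
  expect_lt(abs(t1 / t31 - 1), 0.05)
})

test_that("P_N transmittances agree with the Monte Carlo oracle", {
  ap <- detection_aperture(0.8)
  # one phantom per set at the default anisotropy; the full 6 x 3 sweep is
  # exercised by the acceptance suite
  for (id in c("1.4", "2.2")) {
    s <- table1_slab(id)
    m <- mc_simulate(s, 1e5, seed = 77 + match(id, names(TABLE1)))
    pn <- partial_transmittance(s, ap, order = 31)
    mc <- mc_integrate_na(m, ap)
    expect_lt(abs(pn$t_na - mc$t_na), 3 * mc$se)
    tab <- angular_transmittance(s, order = 31, n_angles = 2)
    expect_lt(abs(tab$t_total - m$t_total), 3 * m$se_t)
    expect_lt(abs(tab$r_total - m$r_total), 3 * m$se_r)
  }
})

test_that("exit angular distribution matches the MC histogram", {
  s <- table1_slab("2.1")
  m <- mc_simulate(s, 1e5, seed = 21, n_angle_bins = 18)
  sol <- solve_pn(s, 31)
  edges <- m$theta_edges
  ratio <- s$n_ambient / s$n_slab
  bin_pn <- vapply(seq_len(18), function(b) {
    q <- pracma::gaussLegendre(24, edges[b], edges[b + 1])
    si <- ratio * sin(q$x); mi <- sqrt(pmax(0, 1 - si^2))
    L <- phantomlight:::pn_exit_radiance(sol, pmax(mi, 1e-9))$bottom
    Tf <- 1 - fresnel_reflectance(s$n_slab, s$n_ambient, pmax(mi, 1e-9))
    sum(q$w * ratio^2 * Tf * L * cos(q$x) * 2 * pi * sin(q$x))
  }, numeric(1))
  z <- (bin_pn - m$t_angular) / pmax(m$se_angular, 1e-12)
  expect_true(all(abs(z) < 3))
})

test_that("order doubling converges quickly for table-1 phantoms", {
  ord <- pn_auto_order(table1_slab("1.2"), na = 0.8)
  expect_lte(ord, 127L)
  # a looser tolerance settles one doubling earlier
  expect_lte(pn_auto_order(table1_slab("1.2"), na = 0.8, tol = 5e-4), 63L)
})
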