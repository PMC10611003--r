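test_that("a pure absorber follows Beer-Lambert and conserves weight", {
  s <- optical_slab(d = 1, mus_prime = 0, mua = 0.5, g = 0,
                    n_slab = 1, n_ambient = 1)
  m <- mc_simulate(s, 2e5, seed = 1)
  expect_lt(abs(m$t_total - exp(-0.5)), 3 * m$se_t)
  expect_lt(abs(m$t_total + m$r_total + m$a_total - 1), 1e-12)
  expect_equal(m$t_ballistic, m$t_total)   # nothing ever scatters
})

test_that("weight bookkeeping is exact for scattering slabs too", {
  for (id in c("1.1", "2.2")) {
    m <- mc_simulate(table1_slab(id), 5e4, seed = 3)
    expect_lt(abs(m$t_total + m$r_total + m$a_total - 1), 1e-12)
    expect_true(all(c(m$t_total, m$r_total, m$a_total, m$t_ballistic) >= 0))
    expect_lte(m$t_ballistic, m$t_total)
  }
})

test_that("identical seed and inputs give bit-identical tallies", {
  s <- table1_slab("1.2")
  m1 <- mc_simulate(s, 2e4, seed = 99)
  m2 <- mc_simulate(s, 2e4, seed = 99)
  expect_identical(m1$t_total, m2$t_total)
  expect_identical(m1$t_angular, m2$t_angular)
  expect_identical(m1$a_total, m2$a_total)
  m3 <- mc_simulate(s, 2e4, seed = 100)
  expect_false(identical(m1$t_total, m3$t_total))
  expect_error(mc_simulate(s, 0, seed = 1), "positive")
  expect_error(mc_simulate(s, 100), "seed")
})

test_that("Henyey-Greenstein sampling has the right CDF and moments", {
  expect_equal(hg_sample(0, 0.25), -0.5)
  expect_equal(hg_sample(0, 0.75), 0.5)
  # forward limit
  expect_equal(hg_sample(0.9, 1 - 1e-12), 1, tolerance = 1e-6)
  # first moment of HG equals g
  set.seed(7)
  for (g in c(0.3, 0.6, 0.9)) {
    x <- hg_sample(g, runif(2e5))
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se)
  }
})

test_that("aperture integration covers its limiting cases", {
  s <- table1_slab("1.2")
  m <- mc_simulate(s, 5e4, seed = 11)
  full <- mc_integrate_na(m, detection_aperture(1.0))
  expect_equal(full$t_na, m$t_total, tolerance = 1e-12)
  # non-scattering slab: no diffuse component in any aperture
  s0 <- optical_slab(d = 0.5, mus_prime = 0, mua = 0.2, g = 0)
  m0 <- mc_simulate(s0, 2e4, seed = 12)
  na <- mc_integrate_na(m0, detection_aperture(0.4))
  expect_equal(na$t_na_diffuse, 0)
  expect_error(mc_integrate_na(m, list(na = 0.8)), "aperture")
})

test_that("ballistic tally matches the closed-form specular series", {
  for (id in c("1.1", "1.2")) {
    s <- table1_slab(id)
    m <- mc_simulate(s, 2e5, seed = 31 + match(id, names(TABLE1)))
    expect_lt(abs(m$t_ballistic - ballistic_transmittance(s)),
              3 * max(m$se_ballistic, 1e-12))
  }
})

test_that("standard errors shrink like one over root n", {
  s <- table1_slab("2.1")
  m1 <- mc_simulate(s, 2e4, seed = 41)
  m2 <- mc_simulate(s, 8e4, seed = 42)
  # quadrupling the photons should halve the SE (within stochastic slack)
  expect_lt(abs(m1$se_t / m2$se_t - 2), 0.35)
})

test_that("diffusion-regime similarity holds approximately at tau >= 5", {
  # same (mus', mua), very different anisotropy: total transmittance within
  # 5% once the slab is several transport lengths thick
  t_tot <- vapply(c(0, 0.9), function(g) {
    s <- optical_slab(d = 2.0, mus_prime = 2.75, mua = 0.005, g = g)
    mc_simulate(s, 5e4, seed = 55)$t_total
  }, numeric(1))
  expect_lt(abs(t_tot[1] / t_tot[2] - 1), 0.05)
})

test_that("transmission is invariant under flipping the slab", {
  # homogeneous slab at normal incidence: illuminating either face is the
  # same experiment (optical reciprocity sanity check)
  s <- optical_slab(d = 1.2, mus_prime = 2.0, mua = 0, g = 0.6)
  m_up <- mc_simulate(s, 5e4, seed = 61)
  m_dn <- mc_simulate(s, 5e4, seed = 62)
  expect_lt(abs(m_up$t_total - m_dn$t_total),
            3 * sqrt(m_up$se_t^2 + m_dn$se_t^2))
})
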