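test_that("forward observables cover the transparent limits", {
  # vacuum slab: everything transmitted
  v <- forward_tr(optical_slab(1, 0, 0, 0, n_slab = 1, n_ambient = 1))
  expect_equal(v[["T"]], 1, tolerance = 1e-8)
  expect_equal(v[["R"]], 0, tolerance = 1e-8)
  # transparent mismatched slab: Fresnel specular series
  f <- forward_tr(optical_slab(1, 0, 0, 0))
  expect_equal(f[["T"]], 0.91061, tolerance = 1e-4)
  expect_equal(f[["T"]] + f[["R"]], 1, tolerance = 1e-8)
  expect_error(forward_tr(optical_slab(1, 1, 0.01, 0.6), engine = "mcmc"))
})

test_that("pn and mc forward engines agree within Monte Carlo error", {
  s <- table1_slab("1.3")
  pn <- forward_tr(s, "pn", 31)
  m <- mc_simulate(s, 1e5, seed = 13)
  expect_lt(abs(pn[["T"]] - m$t_total), 3 * m$se_t)
  expect_lt(abs(pn[["R"]] - m$r_total), 3 * m$se_r)
})

test_that("LUT construction validates axes and is monotone and reproducible", {
  expect_error(build_lut(c(2, 3), 0.01, d = 1), "2 nodes")
  expect_error(build_lut(c(3, 2), c(0.01, 0.1), d = 1), "increasing")
  lut <- build_lut(c(2, 3), c(0.005, 0.05), d = 1, engine = "pn", budget = 15)
  expect_equal(dim(lut$table_T), c(2L, 2L))
  # T decreases along the mua axis at fixed mus'
  expect_true(all(lut$table_T[, 2] < lut$table_T[, 1]))
  # mc-built tables are bit-identical under the same seed
  l1 <- build_lut(c(2, 3), c(0.005, 0.05), d = 1, engine = "mc",
                  budget = 5e3, seed = 4)
  l2 <- build_lut(c(2, 3), c(0.005, 0.05), d = 1, engine = "mc",
                  budget = 5e3, seed = 4)
  expect_identical(l1$table_T, l2$table_T)
})

test_that("inversion round-trips grid nodes to interpolation accuracy", {
  lut <- build_lut(seq(2, 5, length.out = 9), 10^seq(-3, -1, length.out = 9),
                   d = 1, engine = "pn", budget = 31)
  for (ij in list(c(3, 4), c(5, 2), c(7, 8))) {
    iv <- lut_invert(lut$table_T[ij[1], ij[2]], lut$table_R[ij[1], ij[2]], lut)
    expect_equal(iv$mus_prime, lut$grid_mus_prime[ij[1]], tolerance = 1e-9)
    expect_equal(iv$mua, lut$grid_mua[ij[2]], tolerance = 1e-9)
    expect_lt(iv$diagnostics$residual, 1e-10)
  }
})

test_that("the interpolated forward map is locally invertible", {
  lut <- build_lut(seq(2, 5, length.out = 9), 10^seq(-3, -1, length.out = 9),
                   d = 1, engine = "pn", budget = 31)
  set.seed(5)
  for (k in 1:25) {
    ip <- phantomlight:::lut_interp(lut, runif(1, 2.1, 4.9),
                                    10^runif(1, -2.9, -1.1))
    detJ <- ip$T$dx * ip$R$dy - ip$T$dy * ip$R$dx
    expect_gt(abs(detJ), 1e-8)
  }
})

test_that("noise-free off-node round trips hit the stated accuracy", {
  lut <- build_lut(seq(2, 5, length.out = 16),
                   10^seq(-3, -1, length.out = 16),
                   d = 1, engine = "pn", budget = 31)
  set.seed(9)
  errs <- t(replicate(12, {
    mus <- runif(1, 2.2, 4.8)          # tau = mus' * 1 mm > 1 throughout
    mua <- 10^runif(1, -2.7, -1.2)
    tr <- forward_tr(optical_slab(1, mus, mua, 0.6), "pn", 31)
    iv <- lut_invert(tr[["T"]], tr[["R"]], lut)
    c(abs(iv$mus_prime - mus) / mus, abs(iv$mua - mua) / mua)
  }))
  expect_lt(median(errs[, 1]), 0.01)
  expect_lt(median(errs[, 2]), 0.03)
})

test_that("infeasible or out-of-range observables are rejected clearly", {
  lut <- build_lut(c(2, 3, 4), c(0.005, 0.02, 0.08), d = 1,
                   engine = "pn", budget = 15)
  expect_error(lut_invert(0.99, 0.99, lut), "infeasible")
  expect_error(lut_invert(-0.1, 0.3, lut), "infeasible")
  expect_error(lut_invert(0.9, 0.05, lut), "range")
})

test_that("a LUT survives a CSV write/read round trip", {
  lut <- build_lut(c(2, 3, 4), c(0.005, 0.02, 0.08), d = 1,
                   engine = "pn", budget = 15)
  path <- tempfile(fileext = ".csv")
  write_lut(lut, path)
  lut2 <- read_lut(path)
  expect_equal(lut2$table_T, lut$table_T, tolerance = 1e-10)
  expect_equal(lut2$grid_mua, lut$grid_mua, tolerance = 1e-12)
  expect_equal(lut2$fixed$d, lut$fixed$d)
})
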