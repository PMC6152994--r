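test_that("estimators are exact on constant and Gaussian work distributions", {
  kT <- 0.6
  path <- structure(list(lambda = c(0, 0.5, 1),
                         dU_fwd = list(rep(1.5, 50), rep(-0.5, 50)),
                         dU_rev = list(rep(-1.5, 50), rep(0.5, 50)),
                         kT = kT, from = "A", to = "B"),
                    class = "alchemical_path")
  for (meth in c("BAR", "EXP")) {
    e <- fep_estimate(path, method = meth, n_boot = 10)
    expect_equal(e$dG, 1.0, tolerance = 1e-6)
  }
  expect_error(fep_estimate(structure(list(lambda = c(0, 1),
    dU_fwd = list(rep(0, 5)), dU_rev = list(rep(0, 5)), kT = kT),
    class = "alchemical_path")), "at least 10 samples")

  # 1D harmonic k -> 4k at kBT = 0.6: dG = 0.3 * ln 4 per dof
  set.seed(5)
  k <- 1
  x0 <- rnorm(40000, sd = sqrt(kT / k))       # samples from state 0
  x1 <- rnorm(40000, sd = sqrt(kT / (4 * k))) # samples from state 1
  dUf <- 0.5 * (4 * k - k) * x0^2
  dUr <- 0.5 * (k - 4 * k) * x1^2
  p <- structure(list(lambda = c(0, 1), dU_fwd = list(dUf),
                      dU_rev = list(dUr), kT = kT, from = "k", to = "4k"),
                 class = "alchemical_path")
  exact <- 0.3 * log(4)
  eb <- fep_estimate(p, "BAR", n_boot = 30, block = 1)
  expect_equal(eb$dG, exact, tolerance = 0.02)
  ee <- fep_estimate(p, "EXP", n_boot = 0)
  expect_equal(ee$dG, exact, tolerance = 0.05)
})

test_that("identity transformation and ideal-gas ion give zero", {
  m <- build_model()
  site <- fep_site()
  p <- transform_species(m, site, "Na", "Na", n_windows = 3, n_equil = 200,
                         n_sample = 600, sample_stride = 10, seed = 2)
  expect_true(all(abs(unlist(p$dU_fwd)) < 1e-12))
  expect_equal(fep_estimate(p, n_boot = 0)$dG, 0)

  # non-interacting ion: swapping sigma changes nothing
  mi <- build_model(ion_species = list(
    Na = list(charge = 0, sigma = 2.3, amplitude = 0),
    K = list(charge = 0, sigma = 2.9, amplitude = 0)))
  si <- fep_site(beads = data.frame(x = numeric(0), y = numeric(0),
                                    z = numeric(0), charge = numeric(0),
                                    k = numeric(0)),
                 center = c(0, 0, 0))
  pi0 <- transform_species(mi, si, "Na", "K", n_windows = 3, n_equil = 200,
                           n_sample = 600, sample_stride = 10, seed = 3)
  expect_equal(fep_estimate(pi0, n_boot = 0)$dG, 0, tolerance = 1e-10)
})

test_that("BAR matches the quadrature oracle and the cycle closes", {
  m <- build_model()
  site <- fep_site()
  dq <- site_dG_quadrature(m, site, "Na", "K")
  fwd <- fep_estimate(transform_species(m, site, "Na", "K", seed = 8))
  rev <- fep_estimate(transform_species(m, site, "K", "Na", seed = 9))
  expect_lt(abs(fwd$dG - dq), 2 * fwd$se)
  expect_lt(abs(fwd$dG + rev$dG), 2 * sqrt(fwd$se^2 + rev$se^2))
  # with the default sigma ordering the site favors the Na-like species
  expect_gt(dq, 0)
})

test_that("restraint corrections reduce to the known closed forms", {
  m <- build_model()
  # engaged-free case: the site itself confines the ion inside the flat bottom
  site <- fep_site()
  expect_equal(restraint_correction(m, site, "Na", standard_radius = 4), 0,
               tolerance = 1e-9)
  # harmonic restraint on a free particle released into a sphere
  mi <- build_model(ion_species = list(Na = list(charge = 0, sigma = 2.3,
                                                 amplitude = 0)))
  fs <- fep_site(beads = data.frame(x = numeric(0), y = numeric(0),
                                    z = numeric(0), charge = numeric(0),
                                    k = numeric(0)),
                 center = c(0, 0, 0), radius = 0, k = 2)
  rc <- restraint_correction(mi, fs, "Na", standard_radius = 6, spacing = 0.1)
  kT <- kBT(); V <- 4 / 3 * pi * 6^3
  expect_equal(rc, -kT * log(V / (2 * pi * kT / 2)^1.5), tolerance = 0.01)
  # species independence when the restraint is never engaged
  m2 <- build_model()
  c_na <- restraint_correction(m2, site, "Na", standard_radius = 4)
  c_k <- restraint_correction(m2, site, "K", standard_radius = 4)
  expect_equal(c_na, c_k, tolerance = 1e-9)
  expect_error(restraint_correction(m2, site, "Na"), "standard_radius")
})

test_that("cycle bookkeeping combines legs and propagates errors", {
  res <- fep_cycle(dG_site = c(3.0, 0.3), dG_bulk = c(1.0, 0.4),
                   correction = c(0.25, 0.05))
  expect_equal(res$raw, 2.0)
  expect_equal(res$raw_se, sqrt(0.3^2 + 0.4^2))
  expect_equal(res$corrected, res$raw + res$correction)
  expect_equal(res$corrected_se, sqrt(res$raw_se^2 + 0.05^2))
})
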