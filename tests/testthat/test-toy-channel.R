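test_that("model construction, validation and JSON round-trip", {
  m <- build_model()
  expect_s3_class(m, "channel_model")
  expect_equal(nrow(m$carb_sites), 8)
  expect_equal(sort(unique(m$carb_sites$ring)), c("inner", "outer"))
  expect_lt(m$ion_species$Na$sigma, m$ion_species$K$sigma)

  # errors name the offending field
  expect_error(build_model(lys_site = list(x = 0, y = 0, k_lat = 2,
                                           z_up = -2, z_down = 2,
                                           barrier = 2, charge = 1)),
               "z_down")
  bad <- ionperm:::default_carb_sites(); bad$k[1] <- -1
  expect_error(build_model(carb_sites = bad), "stiffness")
  expect_error(build_model(dielectric = 0), "dielectric")

  tf <- tempfile(fileext = ".json")
  model_to_json(m, tf)
  m2 <- model_from_json(tf)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12)

  # external field survives the round trip too
  m3 <- build_model(external_field = list(type = "double_well",
                                          z_minima = c(-6, 6), barrier = 2))
  m4 <- model_from_json(model_to_json(m3))
  expect_equal(m4$external_field$z_minima, c(-6, 6))
})

test_that("potential energy matches closed forms and a term-wise oracle", {
  # two +1e ions at 10 A, eps = 40, no short-range terms
  m <- bare_ion_model(charge = 1)
  m$dielectric <- 40
  r <- particle_roster(m, c(Na = 2))
  x <- matrix(0, nrow(r), 3); x[2, 3] <- 10
  expect_equal(energy_terms(m, x, r)[["coulomb"]], 332.0636 / 400,
               tolerance = 1e-10)

  # harmonic tether: 1 A displacement at k = 2 -> 1 kcal/mol
  mt <- build_model(carb_sites = data.frame(ring = "inner", domain = "I",
                                            x = 0, y = 0, z = 0, k = 2,
                                            charge = 0),
                    lys_site = NULL)
  rt <- particle_roster(mt, c(Na = 0))
  xt <- matrix(c(1, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(energy_terms(mt, xt, rt)[["tether"]], 1.0, tolerance = 1e-10)

  # sigma overrides are reflected at contact: repulsion = sqrt(amp) at r = sigma
  ms <- build_model(ion_species = list(
    Na = list(charge = 1, sigma = 2.3, amplitude = 1),
    K = list(charge = 1, sigma = 2.9, amplitude = 1)))
  for (sp in c("Na", "K")) {
    sig <- ms$ion_species[[sp]]$sigma
    rs <- particle_roster(ms, setNames(1, sp))
    nn <- nrow(rs)
    xs <- matrix(0, nn, 3)
    xs[1, ] <- c(0, 0, sig)            # ion at contact with first carb
    icarb <- which(rs$type == "carb")
    xs[icarb, ] <- as.matrix(ms$carb_sites[, c("x", "y", "z")])
    xs[icarb[1], ] <- c(0, 0, 0)       # move first carb to origin
    ilys <- which(rs$type == "lys")
    xs[ilys, ] <- c(0, 0, -30)         # park the lysine bead far away
    terms <- energy_terms(ms, xs, rs)
    # direct formula for every pair against the C++ evaluator
    rad <- rs$radius; amp <- rs$amplitude
    rep_direct <- 0
    for (i in 1:(nn - 1)) for (j in (i + 1):nn) {
      A <- sqrt(amp[i] * amp[j]); s <- rad[i] + rad[j]
      d <- sqrt(sum((xs[i, ] - xs[j, ])^2))
      if (A > 0 && s > 0) rep_direct <- rep_direct + A * (s / max(d, ms$r_cap))^12
    }
    expect_equal(terms[["repulsion"]], rep_direct, tolerance = 1e-9)
  }

  # full default model, random configuration: term-wise independent oracle
  m <- build_model()
  ro <- particle_roster(m, c(Na = 2, K = 1))
  set.seed(42)
  n <- nrow(ro)
  x <- matrix(rnorm(3 * n, sd = 4), n, 3)
  terms <- energy_terms(m, x, ro)
  expect_equal(potential_energy(m, x, ro), sum(terms), tolerance = 1e-8)
  kC <- 332.0636
  coul <- 0; repE <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- max(sqrt(sum((x[i, ] - x[j, ])^2)), m$r_cap)
    coul <- coul + kC * ro$charge[i] * ro$charge[j] / (m$dielectric * d)
    A <- sqrt(ro$amplitude[i] * ro$amplitude[j])
    s <- ro$radius[i] + ro$radius[j]
    if (A > 0 && s > 0) repE <- repE + A * (s / d)^12
  }
  expect_equal(terms[["coulomb"]], coul, tolerance = 1e-8)
  expect_equal(terms[["repulsion"]], repE, tolerance = 1e-8)
  teth <- sum(0.5 * m$carb_sites$k *
              rowSums((x[ro$type == "carb", ] -
                       as.matrix(m$carb_sites[, c("x", "y", "z")]))^2)) +
          0.5 * 50 * sum(x[ro$type == "reference", ]^2)
  expect_equal(terms[["tether"]], teth, tolerance = 1e-8)
  il <- which(ro$type == "lys")
  ls <- m$lys_site
  a <- (ls$z_up - ls$z_down) / 2; z0 <- (ls$z_up + ls$z_down) / 2
  lysE <- 0.5 * ls$k_lat * sum((x[il, 1:2] - c(ls$x, ls$y))^2) +
    ls$barrier * ((x[il, 3] - z0)^2 - a^2)^2 / a^4
  expect_equal(terms[["lysine"]], lysE, tolerance = 1e-8)

  # coincident charged particles stay finite (capped), with a warning
  xc <- x; xc[2, ] <- xc[1, ]
  expect_warning(u <- potential_energy(m, xc, ro), "cap")
  expect_true(is.finite(u))
})

test_that("samplers reproduce equilibrium statistics and are deterministic", {
  # single particle in an isotropic harmonic well: var = kBT/k per axis
  mh <- build_model(carb_sites = data.frame(ring = "site", domain = "I",
                                            x = 0, y = 0, z = 0, k = 1.2,
                                            charge = 0),
                    lys_site = NULL)
  rh <- particle_roster(mh, c(Na = 0))
  kT <- 0.6
  TT <- kT / ionperm:::.kB
  cfg <- simulation_config(c(Na = 0), n_steps = 2e5, timestep = 0.02,
                           diffusion_coeff = 0.5, temperature = TT,
                           save_stride = 20, seed = 7)
  tr <- run_sampler(mh, cfg)
  bead <- which(tr$roles == "carb:site:I")
  v <- mean(apply(tr$coords[bead, , ], 1, var))
  expect_equal(v, kT / 1.2, tolerance = 0.1)

  # determinism: same seed, bit-identical frames; different seed differs
  cfg2 <- simulation_config(c(Na = 1), n_steps = 500, save_stride = 10,
                            seed = 7)
  mb <- bare_ion_model()
  expect_identical(run_sampler(mb, cfg2)$coords, run_sampler(mb, cfg2)$coords)
  cfg3 <- cfg2; cfg3$seed <- 8L
  expect_false(identical(run_sampler(mb, cfg2)$coords,
                         run_sampler(mb, cfg3)$coords))

  # metropolis matches exact enumeration on a discretized profile
  edges <- seq(-10.5, 10.5, by = 1)
  zmid <- edges[-22] + 0.5
  U <- 1.2 * sin(zmid / 2.5)
  mp <- bare_ion_model(external_field = list(type = "profile", edges = edges,
                                             values = U))
  cfgm <- simulation_config(c(Na = 1), n_steps = 2e5, save_stride = 200,
                            seed = 11, sampler = "metropolis", step_sd = 1.2,
                            p_big = 0.3, step_big = 8)
  z <- run_sampler(mp, cfgm)$coords[1, 3, ]
  cnt <- tabulate(findInterval(z, edges, rightmost.closed = TRUE), nbins = 21)
  p_exact <- exp(-U / kBT()); p_exact <- p_exact / sum(p_exact)
  pval <- suppressWarnings(stats::chisq.test(cnt, p = p_exact)$p.value)
  expect_gt(pval, 0.01)
})

test_that("langevin and metropolis agree on the stationary 1D marginal", {
  ef <- list(type = "double_well", z_minima = c(-4, 4), barrier = 1.5)
  m <- bare_ion_model(external_field = ef)
  cl <- simulation_config(c(Na = 1), n_steps = 4e5, timestep = 0.05,
                          diffusion_coeff = 1.5, save_stride = 10, seed = 3)
  cm <- simulation_config(c(Na = 1), n_steps = 2e5, save_stride = 20,
                          seed = 4, sampler = "metropolis", step_sd = 1,
                          p_big = 0.2, step_big = 6)
  zl <- run_sampler(m, cl)$coords[1, 3, ]
  zm <- run_sampler(m, cm)$coords[1, 3, ]
  edges <- seq(-8, 8, by = 1)
  hl <- tabulate(findInterval(zl, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1)
  hm <- tabulate(findInterval(zm, edges, rightmost.closed = TRUE),
                 nbins = length(edges) - 1)
  Wl <- -kBT() * log(hl / sum(hl)); Wm <- -kBT() * log(hm / sum(hm))
  ok <- hl > 200 & hm > 200
  d <- (Wl - Wm)[ok]; d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 0.12)
})

test_that("smaller ion-carboxylate contact distance increases bound fraction", {
  frac_bound <- function(sig) {
    m <- build_model(ion_species = list(X = list(charge = 1, sigma = sig,
                                                 amplitude = 1)))
    cfg <- simulation_config(c(X = 1), n_steps = 2e4, save_stride = 10,
                             seed = 31, sampler = "metropolis")
    tr <- run_sampler(m, cfg)
    carb <- grep("^carb", tr$roles)
    mean(vapply(seq_len(n_frames(tr)), function(t)
      any(sqrt(colSums((t(tr$coords[carb, , t]) - tr$coords[1, , t])^2)) < 3.8),
      TRUE))
  }
  f <- vapply(c(2.3, 2.9, 3.5), frac_bound, 0)
  expect_true(all(diff(f) < 0))
})
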