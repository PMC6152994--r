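test_that("rdf normalization: fixed pair and ideal gas", {
  # two particles fixed 5 A apart -> a single occupied bin at 5 A
  tr <- trajectory(array(c(0, 0, 0, 0, 0, 5), c(2, 3, 1)),
                   c("ion:Na:1", "ion:Na:2"), 1, c(30, 30, 30))
  pr <- rdf(tr, c("ion", "ion"), r_max = 8, bin = 0.1)
  occ <- which(pr$g > 0)
  expect_length(occ, 1)
  expect_equal(pr$r[occ], 5.05, tolerance = 0.1)

  # ideal gas: g(r) ~ 1 beyond short range
  set.seed(3)
  nf <- 40; np <- 60; L <- 20
  co <- array(runif(np * 3 * nf, -L / 2, L / 2), c(np, 3, nf))
  trg <- trajectory(co, sprintf("ion:Na:%d", 1:np), 1:nf, rep(L, 3))
  pg <- rdf(trg, c("ion", "ion"), r_max = 9, bin = 0.25)
  ok <- pg$r > 2
  expect_equal(mean(pg$g[ok]), 1, tolerance = 0.05)
  expect_true(all(pg$g >= 0))
})

test_that("first_minimum finds the shell boundary and rejects flat profiles", {
  r <- seq(0.025, 8, by = 0.05)
  flat <- structure(data.frame(r = r, g = rep(1, length(r))),
                    class = c("rdf_profile", "data.frame"))
  expect_error(first_minimum(flat), "no shell structure")

  # two-Gaussian analytic profile with minimum at 3.2 A
  g2 <- 2 * exp(-(r - 2.4)^2 / 0.08) + 1.2 * exp(-(r - 4.0)^2 / 0.18)
  prof <- structure(data.frame(r = r, g = g2),
                    class = c("rdf_profile", "data.frame"))
  expect_equal(first_minimum(prof), 3.2, tolerance = 0.1)

  # noisy sampled version lands in the same bin after smoothing
  set.seed(8)
  noisy <- prof; noisy$g <- pmax(g2 + rnorm(length(r), sd = 0.05), 0)
  expect_equal(first_minimum(noisy), 3.2, tolerance = 0.15)
})

test_that("frame classification follows the cutoff definitions", {
  m <- build_model()
  roster <- particle_roster(m, c(Na = 2))
  n <- nrow(roster)
  mk <- function(ion1, ion2, carbs) {
    co <- matrix(0, n, 3)
    co[1, ] <- ion1; co[2, ] <- ion2
    co[2 + seq_len(nrow(carbs)), ] <- as.matrix(carbs)
    ic <- which(roster$type == "carb")
    rest <- ic[ic > 2 + nrow(carbs)]
    co[rest, ] <- matrix(rep(c(0, 0, 30), length(rest)), ncol = 3,
                         byrow = TRUE) # park far away (outside everything)
    il <- which(roster$type == "lys"); co[il, ] <- c(0, 0, -30)
    co
  }
  # two ions 4 A apart, both within 3.5 A of two carbs -> tight-multi
  co1 <- mk(c(0, 0, 2), c(0, 0, 6),
            data.frame(x = c(2.6, -2.6), y = 0, z = c(4, 4)))
  # one ion >= 10 A from every carb -> unbound
  co2 <- mk(c(0, 0, 14), c(0, 0, 22), # second ion outside channel
            data.frame(x = c(2.6, -2.6), y = 0, z = c(2, 2)))
  co <- array(c(co1, co2), c(n, 3, 2))
  tr <- trajectory(co, roster$role, 1:2, m$box)
  cls <- classify_frames(tr, complex_cutoffs())
  expect_equal(cls$state[1], "tight-multi")
  expect_equal(cls$state[2], "unbound")

  expect_error(classify_frames(
    trajectory(co, sub("Na", "Cs", roster$role), 1:2, m$box),
    complex_cutoffs()), "missing cutoffs")
})

test_that("classifier agrees with the brute-force oracle and partitions", {
  tr <- random_classification_traj(1500, seed = 14)
  cls <- classify_frames(tr, complex_cutoffs())
  oracle <- brute_classify(tr, complex_cutoffs())
  expect_identical(cls$state, oracle)
  # exhaustive and exclusive: exactly one known label per frame
  expect_true(all(cls$state %in%
    c("unbound", "single", "multi", "tight-multi", "ion+Lys")))
})

test_that("enlarging the binding cutoff never decreases bound fractions", {
  tr <- random_classification_traj(800, seed = 15)
  bound_frac <- function(scale) {
    cc <- complex_cutoffs(
      Na = c(ion_ion = 4.7, ion_carb = 3.8 * scale),
      K = c(ion_ion = 5.5, ion_carb = 4.2 * scale))
    cls <- classify_frames(tr, cc)
    c(any_bound = mean(cls$state != "unbound"),
      multi = mean(cls$state %in% c("multi", "tight-multi", "ion+Lys")))
  }
  f1 <- bound_frac(1); f2 <- bound_frac(1.1); f3 <- bound_frac(1.2)
  expect_true(all(f2 >= f1))
  expect_true(all(f3 >= f2))
})

test_that("ion-ion distance statistics match a direct recount", {
  roles <- c("ion:Na:1", "ion:Na:2", "reference")
  co <- array(0, c(3, 3, 4))
  co[1, 3, ] <- c(0, 0, 2, 2)
  co[2, 3, ] <- c(6, 6, 10, 6)   # distances 6, 6, 8, 4
  tr <- trajectory(co, roles, 1:4, c(40, 40, 60))
  st <- ion_ion_distance_stats(tr, "Na", n_boot = 0)
  expect_equal(st$mean, 6)
  expect_equal(st$n_frames, 4)
  expect_error(ion_ion_distance_stats(tr, "K"), "at least two ions")
})

test_that("coordination numbers match the analytic ideal-gas count", {
  set.seed(21)
  L <- 20; rho <- 0.0334; np <- round(rho * L^3); nf <- 25
  co <- array(runif((np + 1) * 3 * nf, -L / 2, L / 2), c(np + 1, 3, nf))
  co[1, , ] <- 0   # center particle at the origin
  tr <- trajectory(co, c("center", sprintf("wat:%d", 1:np)), 1:nf, rep(L, 3))
  cn <- coordination_number(tr, "center", "wat", cutoff = 3.5)
  expect_equal(cn$mean, 4 / 3 * pi * 3.5^3 * rho, tolerance = 0.15)
  # zero partners
  tr0 <- trajectory(array(c(0, 0, 0, 9, 9, 9), c(2, 3, 1)),
                    c("center", "wat:1"), 1, rep(40, 3))
  expect_equal(coordination_number(tr0, "center", "wat", 3.5)$mean, 0)
  expect_error(coordination_number(tr0, "center", "wat", -1), "cutoff")
  # relative-to-bulk scaling
  expect_equal(relative_to_bulk(2.835, 5.67), 0.5)
})

test_that("rdf first peak sits at the pair-potential minimum", {
  # numerically minimize the toy Na-carboxylate pair potential
  m <- build_model()
  kC <- 332.0636
  u <- function(r) -kC / (m$dielectric * r) + (2.3 / r)^12
  rmin <- optimize(u, c(1.5, 5))$minimum
  cfg <- simulation_config(c(Na = 1), n_steps = 4e4, save_stride = 10,
                           seed = 17, sampler = "metropolis")
  tr <- run_sampler(m, cfg)
  pr <- rdf(tr, c("ion:Na", "carb"), r_max = 8, bin = 0.05)
  peak <- pr$r[which.max(pr$g)]
  expect_equal(peak, rmin, tolerance = 0.11)
})
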