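make_states <- function(z1, n = 1) {
  data.frame(frame = seq_along(z1), time = seq_along(z1), n = n,
             z1 = z1, z2 = NA_real_, z3 = NA_real_,
             z12 = NA_real_, z23 = NA_real_, zLys = NA_real_)
}

test_that("axial states implement the rank-sorted coordinate definitions", {
  # hand-built 2-frame trajectory: ions at known z, reference at origin
  roles <- c("ion:Na:1", "ion:Na:2", "ion:Na:3", "reference")
  co <- array(0, c(4, 3, 2))
  co[1:3, 3, 1] <- c(-20, 8, 3)     # one ion outside the channel range
  co[1:3, 3, 2] <- c(2, -1, 7)
  tr <- trajectory(co, roles, 1:2, c(40, 40, 60))
  st <- axial_states(tr, channel_range = c(-15, 15))
  expect_equal(st$n, c(2L, 3L))
  expect_equal(st$z1, c(3, -1))
  expect_equal(st$z2, c(8, 2))
  expect_equal(st$z12, c(5.5, 0.5))
  expect_equal(st$z23[2], (2 + 7) / 2)
  expect_true(is.na(st$z3[1]))

  # equilibration discard drops the right number of frames
  co2 <- array(0, c(4, 3, 1000))
  co2[1:3, 3, ] <- rnorm(3000)
  tr2 <- trajectory(co2, roles, 1:1000, c(40, 40, 60))
  expect_equal(nrow(axial_states(tr2, equil_discard = 0.25)), 750)

  # occupancy series equals an independent per-frame recount
  m <- build_model()
  cfg <- simulation_config(c(Na = 2), n_steps = 5000, save_stride = 10,
                           seed = 6, sampler = "metropolis")
  tr3 <- run_sampler(m, cfg)
  st3 <- axial_states(tr3)
  ii <- grep("^ion:", tr3$roles)
  iref <- which(tr3$roles == "reference")
  recount <- vapply(seq_len(n_frames(tr3)), function(t) {
    z <- tr3$coords[ii, 3, t] - tr3$coords[iref, 3, t]
    sum(z > -15 & z < 15)
  }, 0L)
  expect_equal(st3$n, recount)
})

test_that("Boltzmann inversion recovers flat and Gaussian densities", {
  set.seed(1)
  flat <- make_states(runif(40000, -10, 10))
  g <- pmf(flat, "z1", occupancy = 1, kT = 0.6, n_boot = 50, block = 1)
  inner <- abs(g$axes[[1]]$centers) < 9
  expect_lt(max(abs(g$W[inner] - mean(g$W[inner]))), 3 * max(g$se[inner]) + 0.05)

  gauss <- make_states(rnorm(60000))
  g2 <- pmf(gauss, "z1", kT = 0.6, n_boot = 50, block = 1)
  ctr <- g2$axes[[1]]$centers
  ok <- abs(ctr) <= 2
  expect_lt(max(abs(g2$W[ok] - 0.3 * ctr[ok]^2)), 0.12)

  # density normalization: sum(rho * binwidth) = 1
  expect_equal(sum(g2$density) * g2$bin_width, 1, tolerance = 1e-12)
  expect_equal(min(g2$W, na.rm = TRUE), 0)
  expect_error(pmf(flat, "z1", occupancy = 3), "no frames at occupancy")
})

test_that("the offset constant is immaterial and ion ids do not matter", {
  set.seed(2)
  st <- make_states(rnorm(5000))
  g <- pmf(st, "z1", kT = 0.6, n_boot = 0)
  # re-normalizing an already min-zero grid is idempotent
  W2 <- (g$W + 3.7) - min(g$W + 3.7, na.rm = TRUE)
  expect_equal(W2, g$W)

  # permuting ion ids leaves the PMF bit-identical (rank relabeling)
  roles <- c("ion:Na:1", "ion:Na:2", "reference")
  co <- array(0, c(3, 3, 400))
  co[1:2, 3, ] <- rnorm(800, sd = 3)
  tr <- trajectory(co, roles, 1:400, c(40, 40, 60))
  co_perm <- co[c(2, 1, 3), , ]
  trp <- trajectory(co_perm, roles, 1:400, c(40, 40, 60))
  g1 <- pmf(axial_states(tr), c("z1", "z2"), occupancy = 2, n_boot = 10,
            seed = 3)
  g2 <- pmf(axial_states(trp), c("z1", "z2"), occupancy = 2, n_boot = 10,
            seed = 3)
  expect_identical(g1$W, g2$W)
  expect_identical(g1$se, g2$se)
})

test_that("bootstrap SE shrinks like 1/sqrt(N)", {
  ses <- vapply(c(1e3, 1e4, 1e5), function(N) {
    set.seed(7)
    g <- pmf(make_states(rnorm(N)), "z1", kT = 0.6, n_boot = 60, block = 1,
             range = list(c(-3, 3)))
    stats::median(g$se[g$counts > 20], na.rm = TRUE)
  }, 0)
  for (k in 1:2) {
    ratio <- ses[k] / ses[k + 1]
    expect_gt(ratio, sqrt(10) / 2)
    expect_lt(ratio, sqrt(10) * 2)
  }
})

test_that("minimax barrier matches hand values and the flood-fill oracle", {
  mk1d <- function(W) {
    structure(list(
      axes = list(list(name = "z1", edges = seq(0, length(W)),
                       centers = seq_along(W) - 0.5)),
      counts = ifelse(is.na(W), 0L, 1L), density = NULL, W = W,
      se = W * 0, kT = 0.6, bin_width = 1, n_frames = 10L),
      class = "pmf_grid")
  }
  g <- mk1d(c(0, 1, 0.2, 2, 0))
  res <- mfep_barrier(g, start = c(0, 1), end = c(4, 5))
  expect_equal(res$barrier, 2.0)
  # symmetric profile: same barrier both ways
  gs <- mk1d(c(0, 2, 1, 2, 0))
  expect_equal(mfep_barrier(gs, c(0, 1), c(4, 5))$barrier,
               mfep_barrier(gs, c(4, 5), c(0, 1))$barrier)
  # masked bins are impassable
  gm <- mk1d(c(0, NA, 0, 0, 0))
  expect_error(mfep_barrier(gm, c(0, 1), c(4, 5)), "disconnected")

  # randomized 2D grids vs the independent threshold-connectivity oracle
  set.seed(9)
  for (rep in 1:25) {
    d1 <- sample(3:7, 1); d2 <- sample(3:7, 1)
    W <- matrix(round(runif(d1 * d2), 3), d1, d2)
    W[sample(d1 * d2, d1 * d2 %/% 5)] <- NA
    W[1, 1] <- 0; W[d1, d2] <- 0.01
    g2 <- structure(list(
      axes = list(list(name = "z1", edges = 0:d1, centers = 1:d1 - 0.5),
                  list(name = "z2", edges = 0:d2, centers = 1:d2 - 0.5)),
      counts = ifelse(is.na(W), 0L, 1L), density = NULL, W = W, se = W * 0,
      kT = 0.6, bin_width = 1, n_frames = 10L), class = "pmf_grid")
    sb <- 1L; eb <- d1 * d2
    oracle <- brute_bottleneck(as.vector(W), sb, eb, c(d1, d2))
    got <- try(mfep_barrier(g2, list(c(0, 1), c(0, 1)),
                            list(c(d1 - 1, d1), c(d2 - 1, d2))),
               silent = TRUE)
    if (is.na(oracle)) {
      expect_s3_class(got, "try-error")
    } else {
      expect_equal(got$path_max, oracle, tolerance = 1e-12)
    }
  }
})

test_that("occupancy distribution summarizes correctly", {
  st <- make_states(rep(0, 10), n = 2)
  od <- occupancy_distribution(st, n_boot = 0)
  expect_equal(unname(od$prob["2"]), 1)
  expect_equal(od$mean, 2)
  st2 <- make_states(rep(0, 100), n = rep(c(1, 3), 50))
  od2 <- occupancy_distribution(st2, n_boot = 20, block = 2)
  expect_equal(od2$mean, 2)
  expect_equal(unname(od2$prob[c("1", "3")]), c(0.5, 0.5))
})

test_that("a BD run in a known two-well profile recovers the input potential", {
  ef <- list(type = "double_well", z_minima = c(-6, 6), barrier = 2)
  m <- bare_ion_model(external_field = ef)
  cfg <- simulation_config(c(Na = 1), n_steps = 3e5, timestep = 0.05,
                           diffusion_coeff = 1.5, save_stride = 1, seed = 12)
  tr <- run_sampler(m, cfg)
  st <- data.frame(n = 1, z1 = tr$coords[1, 3, ])
  g <- pmf(st, "z1", occupancy = 1, kT = kBT(), n_boot = 0)
  ctr <- g$axes[[1]]$centers
  U <- 2 * ((ctr^2 - 36)^2) / 36^2
  ok <- !is.na(g$W) & g$counts >= 100
  d <- (g$W - U)[ok]; d <- d - mean(d)
  expect_lt(sqrt(mean(d^2)), 0.15)
})
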