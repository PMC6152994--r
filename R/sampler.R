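#' Simulation configuration
#'
#' @param n_ions named integer vector of ions per species, e.g. \code{c(Na = 2)}.
#' @param n_steps number of integration steps (Langevin) or sweeps (Metropolis).
#' @param timestep Langevin timestep in ps.
#' @param diffusion_coeff isotropic diffusion coefficient in A^2/ps. For
#'   equilibrium sampling this only sets the rate at which configuration
#'   space is explored, not the sampled distribution.
#' @param temperature temperature in K; sets kB*T.
#' @param save_stride save every this many steps/sweeps.
#' @param seed integer RNG seed; identical seeds give bit-identical runs.
#' @param sampler "langevin" (Euler-Maruyama overdamped dynamics) or
#'   "metropolis" (single-particle Gaussian-displacement Monte Carlo).
#' @param step_sd Metropolis proposal standard deviation per axis (A).
#' @param p_big probability of drawing a large-displacement Metropolis
#'   proposal (symmetric mixture; preserves detailed balance). Default 0.
#' @param step_big standard deviation of the large proposals (A).
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_ions = c(Na = 2), n_steps = 1e5,
                              timestep = 0.02, diffusion_coeff = 0.2,
                              temperature = 323.15, save_stride = 10,
                              seed = 1, sampler = c("langevin", "metropolis"),
                              step_sd = 0.3, p_big = 0, step_big = 0) {
  sampler <- match.arg(sampler)
  if (timestep <= 0) stop("timestep must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (save_stride < 1 || save_stride > n_steps)
    stop("save_stride must be in 1..n_steps")
  if (diffusion_coeff <= 0) stop("diffusion_coeff must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  structure(list(n_ions = n_ions, n_steps = as.integer(n_steps),
                 timestep = timestep, diffusion_coeff = diffusion_coeff,
                 temperature = temperature,
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed), sampler = sampler,
                 step_sd = step_sd, p_big = p_big, step_big = step_big),
            class = "simulation_config")
}

# deterministic default start: ions on-axis spread over the upper filter and
# vestibule, carboxylates at their anchors, lysine in the up rotamer
default_start <- function(m, roster) {
  n <- nrow(roster)
  x <- matrix(0, n, 3)
  ii <- which(roster$type == "ion")
  if (length(ii)) {
    zs <- seq(6, 14, length.out = max(length(ii), 2))[seq_along(ii)]
    x[ii, 3] <- zs
    x[ii, 1] <- 0.25 * seq_along(ii)   # break exact axial symmetry
  }
  ic <- which(roster$type == "carb")
  if (length(ic)) x[ic, ] <- as.matrix(m$carb_sites[, c("x", "y", "z")])
  il <- which(roster$type == "lys")
  if (length(il)) x[il, ] <- c(m$lys_site$x, m$lys_site$y, m$lys_site$z_up)
  x  # reference bead starts at its origin anchor (already zero)
}

#' Sample an equilibrium trajectory of the toy channel
#'
#' Runs either overdamped Langevin dynamics (Euler-Maruyama, fixed timestep,
#' reflecting box walls) or Metropolis Monte Carlo (symmetric single-particle
#' Gaussian displacement proposals; moves leaving the box are rejected, which
#' preserves detailed balance) on the toy-channel Hamiltonian.
#'
#' @param m a \code{channel_model}.
#' @param config a \code{simulation_config}.
#' @param x0 optional n x 3 start coordinates; defaults to a deterministic
#'   placement with ions in the upper filter.
#' @return an \code{ion_trajectory} (see [trajectory()]); for Metropolis runs
#'   the attribute \code{acceptance} holds the move acceptance rate.
#' @examples
#' m <- build_model()
#' cfg <- simulation_config(c(Na = 2), n_steps = 200, save_stride = 10, seed = 1)
#' tr <- run_sampler(m, cfg)
#' dim(tr$coords)   # particles x 3 x frames
#' @export
run_sampler <- function(m, config, x0 = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  roster <- particle_roster(m, config$n_ions)
  sys <- flatten_system(m, roster)
  if (is.null(x0)) x0 <- default_start(m, roster)
  x0 <- as.matrix(x0)
  kT <- kBT(config$temperature)
  set.seed(config$seed)
  if (config$sampler == "langevin") {
    out <- .cpp_langevin(sys, x0, config$n_steps, config$timestep,
                         config$diffusion_coeff, kT, config$save_stride)
    times <- seq_len(dim(out$frames)[3]) * config$save_stride * config$timestep
  } else {
    out <- .cpp_metropolis(sys, x0, config$n_steps, config$step_sd, kT,
                           config$save_stride, config$p_big, config$step_big)
    times <- as.numeric(seq_len(dim(out$frames)[3]) * config$save_stride)
  }
  tr <- trajectory(out$frames, roster$role, times, m$box)
  attr(tr, "config") <- config
  if (!is.null(out$acceptance)) attr(tr, "acceptance") <- out$acceptance
  if (!is.null(out$energy)) attr(tr, "energy") <- out$energy
  tr
}
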