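#' Define a binding site for alchemical transformations
#'
#' A site is a small standalone system: one or more carboxylate beads (by
#' default a two-carboxylate pair, the minimal high-field-strength motif)
#' plus one mobile ion held near the site by a spherical flat-bottom
#' restraint. Beads can be frozen (exact quadrature then covers the single
#' mobile ion) or tethered.
#'
#' @param beads data.frame with \code{x}, \code{y}, \code{z}, \code{charge}
#'   and optionally \code{k} (tether stiffness when not frozen). Default:
#'   two -1e beads 4 A apart.
#' @param center restraint center (length-3), default the bead centroid.
#' @param radius flat-bottom restraint radius (A), default 4.
#' @param k restraint wall stiffness (kcal/mol/A^2), default 10.
#' @param frozen freeze the beads (default TRUE).
#' @param n_ions number of site ions transformed/restrained jointly is not
#'   supported; one mobile ion per site (fixed at 1).
#' @return object of class \code{fep_site}.
#' @export
fep_site <- function(beads = data.frame(x = c(-2, 2), y = 0, z = 0,
                                        charge = -1, k = 5),
                     center = NULL, radius = 4, k = 10, frozen = TRUE,
                     n_ions = 1) {
  if (is.null(beads$k)) beads$k <- 5
  if (is.null(center)) center <- c(mean(beads$x), mean(beads$y), mean(beads$z))
  if (radius < 0 || k <= 0)
    stop("restraint radius must be >= 0 (0 = harmonic) and k > 0")
  structure(list(beads = beads, center = as.numeric(center), radius = radius,
                 k = k, frozen = isTRUE(frozen)),
            class = "fep_site")
}

# standalone mini-model for a site: the parent model contributes species,
# dielectric and contact radii; no lysine, no confinement funnel, wide box
site_model <- function(m, site) {
  beads <- site$beads
  cs <- if (nrow(beads)) data.frame(ring = "site",
                                    domain = as.character(seq_len(nrow(beads))),
                                    x = beads$x, y = beads$y, z = beads$z,
                                    k = beads$k, charge = beads$charge)
        else data.frame(ring = character(0), domain = character(0),
                        x = numeric(0), y = numeric(0), z = numeric(0),
                        k = numeric(0), charge = numeric(0))
  build_model(
    pore_axis_range = c(-15, 15),
    radial_profile = data.frame(z = c(-20, 20), r = c(15, 15)),
    carb_sites = cs,
    lys_site = NULL,
    ion_species = m$ion_species,
    dielectric = m$dielectric,
    box = c(40, 40, 40),
    carb_radius = m$carb_radius,
    lys_radius = m$lys_radius,
    k_wall = m$k_wall,
    r_cap = m$r_cap,
    coulomb_k = m$coulomb_k)
}

# flattened system for the site with the ion's short-range parameters set to
# the lambda-interpolated values
site_system <- function(sm, site, rad, amp) {
  roster <- particle_roster(sm, stats::setNames(1L, names(sm$ion_species)[1]))
  roster$radius[1] <- rad
  roster$amplitude[1] <- amp
  # order: ion, beads, reference bead (pinned, non-interacting)
  mobile <- c(1L, rep(if (site$frozen) 0L else 1L, nrow(site$beads)), 0L)
  flatten_system(sm, roster, mobile = mobile,
                 restraint = list(index = 1L, center = site$center,
                                  radius = site$radius, k = site$k))
}

# coordinate stack for a site system: ion at each grid point, beads at their
# anchors, reference bead at the origin
site_frames <- function(site, pts) {
  nb <- nrow(site$beads)
  frames <- array(0, c(nb + 2L, 3, nrow(pts)))
  for (k in 1:3) frames[1, k, ] <- pts[, k]
  if (nb) {
    B <- as.matrix(site$beads[, c("x", "y", "z")])
    for (b in seq_len(nb)) for (k in 1:3) frames[1 + b, k, ] <- B[b, k]
  }
  frames
}

ion_pars <- function(m, species) {
  s <- m$ion_species[[species]]
  if (is.null(s)) stop("unknown species: ", species)
  c(rad = s$sigma - m$carb_radius, amp = s$amplitude)
}

#' Staged alchemical transformation of an ion species in a site
#'
#' Interpolates the transformed ion's short-range parameters (contact
#' distance and repulsion amplitude; the charge is unchanged at +1e) along a
#' lambda schedule. At each window the site is sampled by Metropolis Monte
#' Carlo with the ion restrained to the site, and the potential-energy
#' differences to both neighboring windows are recorded, giving matched
#' forward and reverse work samples for each window pair.
#'
#' @param m the parent \code{channel_model} (supplies species parameters and
#'   dielectric).
#' @param site a [fep_site()].
#' @param from_species,to_species species labels declared in the model.
#' @param n_windows number of lambda windows (default 12, equally spaced).
#' @param n_equil,n_sample equilibration and production sweeps per window and
#'   replica.
#' @param sample_stride sweeps between recorded samples.
#' @param n_replicas independent chains per window (default 4); replicate
#'   spread exposes slow coordination-basin modes that a single chain hides.
#' @param step_sd Metropolis proposal width (A).
#' @param temperature temperature (K).
#' @param seed RNG seed.
#' @return object of class \code{alchemical_path}: lambda schedule, lists
#'   \code{dU_fwd} and \code{dU_rev} of per-pair work samples (kcal/mol),
#'   \code{kT}, and the species tags.
#' @export
transform_species <- function(m, site, from_species, to_species,
                              n_windows = 12, n_equil = 2000,
                              n_sample = 10000, sample_stride = 20,
                              n_replicas = 4, step_sd = 0.3,
                              temperature = 323.15, seed = 1) {
  if (n_windows < 2) stop("need at least 2 lambda windows")
  p0 <- ion_pars(m, from_species)
  p1 <- ion_pars(m, to_species)
  lam <- seq(0, 1, length.out = n_windows)
  sm <- site_model(m, site)
  # species list of the mini model is irrelevant to the energy once the
  # roster radius/amplitude are overridden; use the parent's first species
  kT <- kBT(temperature)
  sys_at <- function(l) site_system(sm, site,
                                    rad = (1 - l) * p0["rad"] + l * p1["rad"],
                                    amp = (1 - l) * p0["amp"] + l * p1["amp"])
  systems <- lapply(lam, sys_at)
  x0_init <- rbind(site$center + c(0, 0, 0.5),
                   as.matrix(site$beads[, c("x", "y", "z")]),
                   c(0, 0, 0))
  dU_fwd <- rep(list(list()), n_windows - 1L)
  dU_rev <- rep(list(list()), n_windows - 1L)
  set.seed(seed)
  for (rep_i in seq_len(n_replicas)) {
    x0 <- x0_init
    for (w in seq_len(n_windows)) {
      # 20% large-displacement proposals decorrelate hops between the
      # degenerate coordination basins of the site
      run <- .cpp_metropolis(systems[[w]], x0, n_equil + n_sample, step_sd,
                             kT, 1L, 0.2, 2.5)
      nf <- dim(run$frames)[3]
      keep <- seq(n_equil + sample_stride, nf, by = sample_stride)
      fr <- run$frames[, , keep, drop = FALSE]
      # restraint escape diagnostic: the wall keeps the ion at the site
      dmax <- max(sqrt(colSums((fr[1, , ] - site$center)^2)))
      if (dmax > site$radius + 3)
        stop(sprintf("window %d: ion escaped the site restraint (max distance %.1f A)",
                     w, dmax))
      u_here <- .cpp_energy_frames(systems[[w]], fr)
      if (w < n_windows)
        dU_fwd[[w]][[rep_i]] <- .cpp_energy_frames(systems[[w + 1L]], fr) - u_here
      if (w > 1)
        dU_rev[[w - 1L]][[rep_i]] <- .cpp_energy_frames(systems[[w - 1L]], fr) - u_here
      x0 <- fr[, , dim(fr)[3]]
    }
  }
  structure(list(lambda = lam,
                 dU_fwd = lapply(dU_fwd, function(v) unlist(v)),
                 dU_rev = lapply(dU_rev, function(v) unlist(v)),
                 fwd_rep = lapply(dU_fwd, function(v)
                   rep(seq_along(v), lengths(v))),
                 rev_rep = lapply(dU_rev, function(v)
                   rep(seq_along(v), lengths(v))),
                 n_replicas = n_replicas, kT = kT,
                 from = from_species, to = to_species),
            class = "alchemical_path")
}

# Bennett acceptance ratio for one window pair; solves the self-consistent
# equation with equal-weight Fermi functions via uniroot
bar_pair <- function(dUf, dUr, kT) {
  M <- log(length(dUf) / length(dUr))
  fermi <- function(x) 1 / (1 + exp(pmin(x, 500)))
  g <- function(dG) {
    lf <- sum(fermi((dUf - dG) / kT + M))
    lr <- sum(fermi((dUr + dG) / kT - M))
    lf - lr
  }
  lo <- min(c(dUf, -dUr)) - 10 * kT
  hi <- max(c(dUf, -dUr)) + 10 * kT
  if (g(lo) * g(hi) > 0)
    stop("BAR failed: forward and reverse work distributions do not overlap; use more windows")
  stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
}

exp_pair <- function(dUf, kT) {
  m0 <- min(dUf)
  -kT * (log(mean(exp(-(dUf - m0) / kT))) - m0 / kT)
}

#' Free-energy estimate from an alchemical path
#'
#' Sums per-window free energies from either exponential averaging of the
#' forward work (EXP) or the Bennett acceptance ratio (BAR, the default).
#' The estimate pools all replicate chains. The standard error combines, in
#' quadrature, (a) a window-wise moving-block bootstrap over the pooled
#' samples and (b) the spread of per-replica estimates divided by
#' sqrt(n_replicas). The replicate term exposes slow coordination-basin
#' modes a single chain cannot resolve; since the two components partially
#' overlap (the replicate spread also contains the fast-mode noise), the
#' combined SE is deliberately conservative.
#'
#' @param path an \code{alchemical_path} from [transform_species()].
#' @param method "BAR" or "EXP".
#' @param n_boot bootstrap replicates for the SE (default 100).
#' @param block bootstrap block length in samples (default 10).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{dG} (kcal/mol), \code{se}, \code{per_window},
#'   \code{method}.
#' @export
fep_estimate <- function(path, method = c("BAR", "EXP"), n_boot = 100,
                         block = 10, seed = 1) {
  method <- match.arg(method)
  kT <- path$kT
  if (any(vapply(path$dU_fwd, length, 0L) < 10))
    stop("need at least 10 samples per window for SE estimation")
  one <- function(fwd, rev) {
    vapply(seq_along(fwd), function(i)
      if (method == "BAR") bar_pair(fwd[[i]], rev[[i]], kT)
      else exp_pair(fwd[[i]], kT), 0)
  }
  per <- one(path$dU_fwd, path$dU_rev)
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    tot <- vapply(seq_len(n_boot), function(b) {
      f <- lapply(path$dU_fwd, function(v)
        v[moving_block_indices(length(v), block)])
      r <- lapply(path$dU_rev, function(v)
        v[moving_block_indices(length(v), block)])
      sum(one(f, r))
    }, 0)
    se <- stats::sd(tot)
  }
  R <- path$n_replicas
  if (!is.null(R) && R > 1) {
    per_rep <- vapply(seq_len(R), function(r) {
      f <- lapply(seq_along(path$dU_fwd), function(i)
        path$dU_fwd[[i]][path$fwd_rep[[i]] == r])
      rv <- lapply(seq_along(path$dU_rev), function(i)
        path$dU_rev[[i]][path$rev_rep[[i]] == r])
      sum(one(f, rv))
    }, 0)
    se_rep <- stats::sd(per_rep) / sqrt(R)
    se <- if (is.na(se)) se_rep else sqrt(se^2 + se_rep^2)
  }
  list(dG = sum(per), se = se, per_window = per, method = method)
}

#' Exact quadrature free-energy difference for a site species swap
#'
#' Direct numerical integration of both single-ion partition functions on a
#' 3D grid (beads frozen); the independent oracle for [fep_estimate()] on
#' sites with one mobile particle.
#'
#' @param m the parent \code{channel_model}.
#' @param site a [fep_site()] with \code{frozen = TRUE}.
#' @param from_species,to_species species labels.
#' @param temperature temperature (K).
#' @param spacing grid spacing (A), default 0.15.
#' @return dG in kcal/mol.
#' @export
site_dG_quadrature <- function(m, site, from_species, to_species,
                               temperature = 323.15, spacing = 0.15) {
  if (!site$frozen)
    stop("quadrature oracle requires frozen site beads (one mobile particle)")
  # constant bead-bead energy cancels between the two integrals only if the
  # same shift is used; recompute without per-call shifts
  sm <- site_model(m, site)
  kT <- kBT(temperature)
  extent <- site$radius + 3 * sqrt(kT / site$k) + 1
  g <- seq(-extent, extent, by = spacing)
  pts <- as.matrix(expand.grid(x = g + site$center[1],
                               y = g + site$center[2],
                               z = g + site$center[3]))
  frames <- site_frames(site, pts)
  zof <- function(species) {
    p <- ion_pars(m, species)
    sys <- site_system(sm, site, rad = p["rad"], amp = p["amp"])
    U <- .cpp_energy_frames(sys, frames)
    sum(exp(-(U - min(U)) / kT)) * spacing^3 * exp(-min(U) / kT)
  }
  -kT * log(zof(to_species) / zof(from_species))
}

#' Restraint release correction by quadrature
#'
#' Free energy of releasing the site restraint into a declared standard
#' volume (a sphere of \code{standard_radius} around the site center):
#' \eqn{\Delta G = -k_B T \ln(Z_{free}/Z_{restr})}, both integrals over the
#' standard volume. If the site potential itself confines the ion so the
#' restraint wall is never engaged, the correction is ~0.
#'
#' @param m the parent \code{channel_model}.
#' @param site a [fep_site()] with frozen beads.
#' @param species ion species.
#' @param standard_radius radius (A) of the declared release volume;
#'   required (an unbounded release volume is an error).
#' @param temperature temperature (K).
#' @param spacing quadrature grid spacing (A).
#' @return dG_corr in kcal/mol (SE 0: deterministic quadrature).
#' @export
restraint_correction <- function(m, site, species, standard_radius = NULL,
                                 temperature = 323.15, spacing = 0.15) {
  if (is.null(standard_radius))
    stop("release volume is unbounded: declare a standard_radius")
  if (!site$frozen)
    stop("quadrature correction requires frozen site beads")
  sm <- site_model(m, site)
  p <- ion_pars(m, species)
  kT <- kBT(temperature)
  g <- seq(-standard_radius, standard_radius, by = spacing)
  pts <- as.matrix(expand.grid(x = g + site$center[1],
                               y = g + site$center[2],
                               z = g + site$center[3]))
  keep <- sqrt(rowSums(sweep(pts, 2, site$center)^2)) <= standard_radius
  pts <- pts[keep, , drop = FALSE]
  frames <- site_frames(site, pts)
  sys_r <- site_system(sm, site, rad = p["rad"], amp = p["amp"])
  sys_f <- sys_r; sys_f$restr_idx <- 0L
  Ur <- .cpp_energy_frames(sys_r, frames)
  Uf <- .cpp_energy_frames(sys_f, frames)
  u0 <- min(Uf)
  Zr <- sum(exp(-(Ur - u0) / kT))
  Zf <- sum(exp(-(Uf - u0) / kT))
  -kT * log(Zf / Zr)
}

#' Thermodynamic-cycle bookkeeping for relative binding free energies
#'
#' Combines a site transformation leg and a bulk reference leg into the
#' relative binding free energy \eqn{\Delta\Delta G = \Delta G_{site} -
#' \Delta G_{bulk}}, applies a restraint correction, and propagates standard
#' errors in quadrature. Inputs are (value, se) pairs, so the function also
#' serves for arithmetic on published per-leg tables.
#'
#' @param dG_site,dG_bulk,correction length-2 numeric c(value, se); bulk and
#'   correction default to 0 +- 0.
#' @return object of class \code{fep_result}: raw ddG, correction, corrected
#'   ddG, each with SE.
#' @export
fep_cycle <- function(dG_site, dG_bulk = c(0, 0), correction = c(0, 0)) {
  v <- function(x) if (length(x) == 1) c(x, 0) else x
  s <- v(dG_site); b <- v(dG_bulk); cc <- v(correction)
  raw <- s[1] - b[1]
  raw_se <- sqrt(s[2]^2 + b[2]^2)
  structure(list(raw = raw, raw_se = raw_se,
                 correction = cc[1], correction_se = cc[2],
                 corrected = raw + cc[1],
                 corrected_se = sqrt(raw_se^2 + cc[2]^2)),
            class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat(sprintf("ddG raw %.3f +- %.3f; correction %.3f +- %.3f; corrected %.3f +- %.3f kcal/mol\n",
              x$raw, x$raw_se, x$correction, x$correction_se,
              x$corrected, x$corrected_se))
  invisible(x)
}
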