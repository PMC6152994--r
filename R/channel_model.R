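#' Build a toy channel model
#'
#' Constructs the coarse-grained Hamiltonian of a sodium-channel selectivity
#' filter: an inner ("DEKA-like") and an outer ("EEDD-like") ring of
#' harmonically tethered carboxylate beads, a positively charged lysine bead
#' with an axial double-well (up/down rotamer states), mobile cations of one
#' or more species, screened-Coulomb electrostatics, a soft-core inverse
#' power contact repulsion, and a radial pore-confinement profile with bulk
#' reservoirs at either end.
#'
#' Energy terms (kcal/mol, distances in Angstrom, charges in e):
#' \itemize{
#'   \item screened Coulomb \eqn{k_C q_i q_j / (\epsilon r)} over all charged
#'     pairs, with \eqn{k_C = 332.0636};
#'   \item soft-core repulsion \eqn{A_{ij} (\sigma_{ij}/r)^{12}} with
#'     \eqn{\sigma_{ij} = R_i + R_j} (contact radii) and
#'     \eqn{A_{ij} = \sqrt{A_i A_j}}; an ion's contact radius is defined as
#'     its species' ion-carboxylate contact distance \code{sigma} minus the
#'     carboxylate bead radius, so ion-carboxylate contact occurs exactly at
#'     \code{sigma};
#'   \item isotropic harmonic tethers holding carboxylate beads at their ring
#'     anchors;
#'   \item the lysine bead: lateral harmonic restraint about the pore axis
#'     plus an axial quartic double-well with minima at \code{z_up} and
#'     \code{z_down} separated by \code{barrier};
#'   \item half-harmonic radial confinement beyond the pore radius profile
#'     \code{radial_profile} (applied to ions and the lysine bead);
#'   \item optionally, an external axial field acting on ions: a quartic
#'     double-well or a piecewise-constant profile (used for sampler
#'     validation experiments).
#' }
#'
#' Pairs closer than \code{r_cap} are evaluated at \code{r_cap}, keeping the
#' energy finite for coincident particles.
#'
#' @param pore_axis_range length-2 numeric, the channel region in z (A).
#' @param radial_profile data.frame with columns \code{z}, \code{r}: maximum
#'   accessible radius vs z, linearly interpolated between nodes.
#' @param carb_sites data.frame of carboxylate bead anchors with columns
#'   \code{ring} ("inner"/"outer"), \code{domain}, \code{x}, \code{y},
#'   \code{z}, \code{k} (tether stiffness, kcal/mol/A^2), \code{charge} (e).
#' @param lys_site list with \code{x}, \code{y} (lateral anchor), \code{k_lat},
#'   \code{z_up}, \code{z_down}, \code{barrier}, \code{charge}; or NULL for a
#'   channel without the lysine bead.
#' @param ion_species named list; each entry a list with \code{charge} (e),
#'   \code{sigma} (ion-carboxylate contact distance, A) and \code{amplitude}
#'   (soft-core repulsion amplitude, kcal/mol).
#' @param dielectric uniform relative permittivity for screened Coulomb.
#' @param box length-3 numeric, box edge lengths (A); walls at +-L/2.
#' @param carb_radius,lys_radius contact radii of the fixed-role beads (A).
#' @param k_wall confinement wall stiffness (kcal/mol/A^2).
#' @param external_field NULL, or \code{list(type = "double_well",
#'   z_minima = c(za, zb), barrier = h)}, or \code{list(type = "profile",
#'   edges = ..., values = ...)} (piecewise-constant, metropolis only).
#' @param r_cap evaluation floor for pair distances (A).
#' @param coulomb_k Coulomb constant (kcal*A/mol/e^2).
#' @return an object of class \code{channel_model}.
#' @examples
#' m <- build_model()
#' nrow(m$carb_sites)    # 8 beads in two rings
#' @export
build_model <- function(pore_axis_range = c(-15, 15),
                        radial_profile = NULL,
                        carb_sites = NULL,
                        lys_site = list(x = 0, y = 0, k_lat = 2,
                                        z_up = 2, z_down = -2,
                                        barrier = 2, charge = 1),
                        ion_species = list(
                          Na = list(charge = 1, sigma = 2.3, amplitude = 1),
                          K  = list(charge = 1, sigma = 2.9, amplitude = 1)),
                        dielectric = 20,
                        box = c(24, 24, 50),
                        carb_radius = 1.4,
                        lys_radius = 1.6,
                        k_wall = 10,
                        external_field = NULL,
                        r_cap = 0.1,
                        coulomb_k = .kC_default) {
  if (is.null(radial_profile))
    radial_profile <- data.frame(z = c(-25, -16, -13, 13, 16, 25),
                                 r = c(8, 8, 4, 4, 8, 8))
  if (is.null(carb_sites)) carb_sites <- default_carb_sites()
  m <- structure(list(
    pore_axis_range = as.numeric(pore_axis_range),
    radial_profile = radial_profile,
    carb_sites = carb_sites,
    lys_site = lys_site,
    ion_species = ion_species,
    dielectric = dielectric,
    box = as.numeric(box),
    carb_radius = carb_radius,
    lys_radius = lys_radius,
    k_wall = k_wall,
    external_field = external_field,
    r_cap = r_cap,
    coulomb_k = coulomb_k), class = "channel_model")
  validate_channel_model(m)
  m
}

# two rings of four beads each: inner ring low and narrow, outer vestibular
# ring higher and wider, staggered by 45 degrees. Tethers are deliberately
# soft (RMS displacement ~1.5 A at the default temperature) so carboxylates
# can reach toward ions and jointly coordinate ion pairs, the motif behind
# tight multi-ion complex formation.
default_carb_sites <- function() {
  ang_i <- (0:3) * pi / 2
  ang_o <- (0:3) * pi / 2 + pi / 4
  rbind(
    data.frame(ring = "inner", domain = c("I", "II", "III", "IV"),
               x = 2.5 * cos(ang_i), y = 2.5 * sin(ang_i), z = 5,
               k = 0.3, charge = -1),
    data.frame(ring = "outer", domain = c("I", "II", "III", "IV"),
               x = 3.0 * cos(ang_o), y = 3.0 * sin(ang_o), z = 10,
               k = 0.3, charge = -1))
}

#' Validate a channel model
#'
#' Checks the structural invariants of a \code{channel_model}; errors name
#' the offending field.
#'
#' @param m a \code{channel_model}.
#' @return the model, invisibly.
#' @export
validate_channel_model <- function(m) {
  stopifnot(inherits(m, "channel_model"))
  if (length(m$pore_axis_range) != 2 || diff(m$pore_axis_range) <= 0)
    stop("pore_axis_range: must be an increasing length-2 interval")
  if (!all(c("z", "r") %in% names(m$radial_profile)) ||
      is.unsorted(m$radial_profile$z, strictly = TRUE) ||
      any(m$radial_profile$r <= 0))
    stop("radial_profile: needs strictly increasing z and positive r")
  cs <- m$carb_sites
  if (nrow(cs) > 0 && any(cs$k <= 0))
    stop("carb_sites: tether stiffness k must be > 0")
  if (!is.null(m$lys_site)) {
    ls <- m$lys_site
    if (ls$z_down >= ls$z_up)
      stop("lys_site: z_down must be < z_up")
    if (ls$k_lat <= 0) stop("lys_site: k_lat must be > 0")
    if (ls$barrier < 0) stop("lys_site: barrier must be >= 0")
  }
  for (sp in names(m$ion_species)) {
    s <- m$ion_species[[sp]]
    if (s$sigma <= 0) stop(sprintf("ion_species$%s: sigma must be > 0", sp))
    if (s$amplitude < 0) stop(sprintf("ion_species$%s: amplitude must be >= 0", sp))
  }
  qs <- c(cs$charge, if (!is.null(m$lys_site)) m$lys_site$charge,
          vapply(m$ion_species, function(s) s$charge, 0))
  if (any(!is.finite(qs))) stop("charge: all declared charges must be finite")
  if (m$dielectric <= 0) stop("dielectric: must be > 0")
  if (length(m$box) != 3 || any(m$box <= 0)) stop("box: three positive edges")
  if (!is.null(m$external_field)) {
    ef <- m$external_field
    if (!ef$type %in% c("double_well", "profile"))
      stop("external_field: type must be 'double_well' or 'profile'")
    if (ef$type == "double_well" && ef$z_minima[1] >= ef$z_minima[2])
      stop("external_field: z_minima must be increasing")
    if (ef$type == "profile" &&
        length(ef$edges) != length(ef$values) + 1L)
      stop("external_field: edges must be one longer than values")
  }
  invisible(m)
}

#' @export
print.channel_model <- function(x, ...) {
  cat("<channel_model>\n")
  cat(sprintf("  channel region: %g..%g A, dielectric %g\n",
              x$pore_axis_range[1], x$pore_axis_range[2], x$dielectric))
  cat(sprintf("  carboxylate beads: %d (%s)\n", nrow(x$carb_sites),
              paste(names(table(x$carb_sites$ring)), table(x$carb_sites$ring),
                    sep = ":", collapse = ", ")))
  if (!is.null(x$lys_site))
    cat(sprintf("  lysine bead: z_up %g, z_down %g, barrier %g kcal/mol\n",
                x$lys_site$z_up, x$lys_site$z_down, x$lys_site$barrier))
  cat(sprintf("  ion species: %s\n", paste(sprintf("%s(sigma=%g)",
              names(x$ion_species),
              vapply(x$ion_species, function(s) s$sigma, 0)), collapse = ", ")))
  invisible(x)
}

#' Serialize a channel model to JSON
#'
#' @param m a \code{channel_model}.
#' @param path file path; if NULL the JSON string is returned.
#' @return path (invisibly) or a JSON string.
#' @export
model_to_json <- function(m, path = NULL) {
  validate_channel_model(m)
  txt <- jsonlite::toJSON(unclass(m), auto_unbox = TRUE, digits = NA,
                          dataframe = "columns", null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a channel model from JSON
#'
#' @param path file path or JSON string produced by [model_to_json()].
#' @return a \code{channel_model}.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  x$radial_profile <- as.data.frame(x$radial_profile)
  x$carb_sites <- as.data.frame(x$carb_sites)
  x$pore_axis_range <- as.numeric(x$pore_axis_range)
  x$box <- as.numeric(x$box)
  if (!is.null(x$external_field)) {
    x$external_field <- lapply(x$external_field, function(v)
      if (is.list(v)) unlist(v) else v)
    x$external_field$type <- as.character(x$external_field$type)
    if (!is.null(x$external_field$z_minima))
      x$external_field$z_minima <- as.numeric(x$external_field$z_minima)
  }
  m <- structure(x, class = "channel_model")
  validate_channel_model(m)
  m
}

#' Particle roster for a simulation
#'
#' Expands a model plus per-species ion counts into the full particle table
#' used by the energy evaluator and samplers: ions first (in species order),
#' then carboxylate beads, then the lysine bead.
#'
#' @param m a \code{channel_model}.
#' @param n_ions named integer vector, ions per species, e.g. \code{c(Na = 2)}.
#' @return data.frame with columns \code{role}, \code{type}, \code{species},
#'   \code{charge}, \code{radius}, \code{amplitude}.
#' @export
particle_roster <- function(m, n_ions) {
  validate_channel_model(m)
  if (is.null(names(n_ions)) || !all(names(n_ions) %in% names(m$ion_species)))
    stop("n_ions must be named after species declared in the model")
  rows <- list()
  for (sp in names(n_ions)) {
    k <- n_ions[[sp]]
    if (k > 0) {
      s <- m$ion_species[[sp]]
      rows[[length(rows) + 1L]] <- data.frame(
        role = sprintf("ion:%s:%d", sp, seq_len(k)),
        type = "ion", species = sp, charge = s$charge,
        radius = s$sigma - m$carb_radius, amplitude = s$amplitude)
    }
  }
  cs <- m$carb_sites
  if (nrow(cs) > 0)
    rows[[length(rows) + 1L]] <- data.frame(
      role = sprintf("carb:%s:%s", cs$ring, cs$domain),
      type = "carb", species = NA_character_, charge = cs$charge,
      radius = m$carb_radius, amplitude = 1)
  if (!is.null(m$lys_site))
    rows[[length(rows) + 1L]] <- data.frame(
      role = "lys", type = "lys", species = NA_character_,
      charge = m$lys_site$charge, radius = m$lys_radius, amplitude = 1)
  # non-interacting reference bead pinned at the origin: defines z_ref for
  # the analysis chain (the scaffold-COM convention of imported systems)
  rows[[length(rows) + 1L]] <- data.frame(
    role = "reference", type = "reference", species = NA_character_,
    charge = 0, radius = 0, amplitude = 0)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$role)) stop("role labels must be unique")
  out
}

# flatten model + roster into the plain list consumed by the C++ kernels;
# `mobile` masks particles the samplers may move, `restraint` is an optional
# list(index, center, radius, k) spherical flat-bottom restraint
flatten_system <- function(m, roster, mobile = NULL, restraint = NULL) {
  n <- nrow(roster)
  anchors <- matrix(0, n, 3)
  tk <- numeric(n)
  ic <- which(roster$type == "carb")
  if (length(ic)) {
    anchors[ic, ] <- as.matrix(m$carb_sites[, c("x", "y", "z")])
    tk[ic] <- m$carb_sites$k
  }
  tk[roster$type == "reference"] <- 50   # pinned at the origin
  lys_idx <- which(roster$type == "lys")
  lp <- if (length(lys_idx)) with(m$lys_site,
          c(x, y, k_lat, z_up, z_down, barrier)) else c(0, 0, 0, 1, -1, 0)
  ef <- m$external_field
  well_type <- 0L
  well_par <- c(0, 0, 0); pe <- 0; pv <- 0
  if (!is.null(ef)) {
    if (ef$type == "double_well") {
      well_type <- 1L
      well_par <- c(ef$z_minima[1], ef$z_minima[2], ef$barrier)
    } else {
      well_type <- 2L
      pe <- as.numeric(ef$edges); pv <- as.numeric(ef$values)
    }
  }
  list(q = roster$charge, rad = roster$radius, amp = roster$amplitude,
       tether_k = tk, tether_anchor = anchors,
       conf_mask = as.integer(roster$type %in% c("ion", "lys")),
       well_mask = as.integer(roster$type == "ion"),
       lys_idx = if (length(lys_idx)) as.integer(lys_idx[1]) else 0L,
       lys_par = lp,
       well_type = well_type, well_par = well_par,
       profile_edges = pe, profile_values = pv,
       conf_z = m$radial_profile$z, conf_R = m$radial_profile$r,
       k_wall = m$k_wall, dielectric = m$dielectric,
       coulomb_k = m$coulomb_k, r_cap = m$r_cap, box = m$box,
       mobile = if (is.null(mobile)) rep(1L, n) else as.integer(mobile),
       restr_idx = if (is.null(restraint)) 0L else as.integer(restraint$index),
       restr_par = if (is.null(restraint)) rep(0, 5) else
         c(restraint$center, restraint$radius, restraint$k))
}

#' Total potential energy of a configuration
#'
#' Sum of screened Coulomb, soft-core repulsion, tether, lysine double-well,
#' radial confinement and external-field terms; finite for any configuration
#' (close contacts are evaluated at the cap radius, with a warning).
#'
#' @param m a \code{channel_model}.
#' @param coords n x 3 coordinate matrix (A) matching \code{roster}.
#' @param roster particle table from [particle_roster()].
#' @return energy in kcal/mol.
#' @examples
#' m <- build_model(carb_sites = data.frame(ring = character(0),
#'   domain = character(0), x = numeric(0), y = numeric(0), z = numeric(0),
#'   k = numeric(0), charge = numeric(0)), lys_site = NULL)
#' r <- particle_roster(m, c(Na = 2))
#' # two +1e ions 10 A apart, eps = 40: 332.0636/400 kcal/mol (plus tiny core term)
#' potential_energy(m, rbind(c(0, 0, 0), c(0, 0, 10)), r)
#' @export
potential_energy <- function(m, coords, roster) {
  .cpp_energy(flatten_system(m, roster), as.matrix(coords))
}

#' Per-term energy breakdown
#'
#' @inheritParams potential_energy
#' @return named numeric vector: coulomb, repulsion, tether, lysine, wall,
#'   external (kcal/mol).
#' @export
energy_terms <- function(m, coords, roster) {
  .cpp_energy_terms(flatten_system(m, roster), as.matrix(coords))
}
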