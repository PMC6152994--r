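# Shared fixtures and independent oracles, all generated in code.

# a model with no scaffold: one uncharged, non-interacting ion in a box,
# optionally under an external axial field
bare_ion_model <- function(external_field = NULL, charge = 0, r = 6,
                           box = c(16, 16, 36)) {
  build_model(
    carb_sites = data.frame(ring = character(0), domain = character(0),
                            x = numeric(0), y = numeric(0), z = numeric(0),
                            k = numeric(0), charge = numeric(0)),
    lys_site = NULL,
    ion_species = list(Na = list(charge = charge, sigma = 2.3, amplitude = 0)),
    external_field = external_field,
    radial_profile = data.frame(z = c(-25, 25), r = c(r, r)),
    box = box)
}

# minimal CHARMM-format DCD writer (independent of the bio3d reader used by
# load_trajectory); coords is natom x 3 x nframes
write_dcd_fixture <- function(path, coords) {
  natom <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wi(84); writeChar("CORD", con, 4, eos = NULL)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1; icntrl[3] <- 1; icntrl[4] <- nf
  icntrl[20] <- 24
  wi(icntrl); wi(84)
  wi(4 + 80); wi(1)
  writeChar(sprintf("%-80s", "synthetic test fixture"), con, 80, eos = NULL)
  wi(4 + 80)
  wi(4); wi(natom); wi(4)
  for (t in seq_len(nf)) for (k in 1:3) {
    wi(4 * natom)
    writeBin(as.numeric(coords[, k, t]), con, size = 4, endian = "little")
    wi(4 * natom)
  }
  invisible(path)
}

# PDB + DCD pair emulating a small filter: 2 Na ions, 2 Asp + 2 Glu side
# chains (central carboxylate C), 1 Lys NZ, 2 backbone CA atoms
make_pdb_dcd_fixture <- function(dir, nf = 10, seed = 99) {
  set.seed(seed)
  resid <- c("SOD", "SOD", "ASP", "ASP", "GLU", "GLU", "LYS", "GLY", "GLY")
  elety <- c("SOD", "SOD", "CG", "CG", "CD", "CD", "NZ", "CA", "CA")
  natom <- length(resid)
  base <- matrix(c(0, 0, 8,   0, 0, 12,
                   2.5, 0, 5, -2.5, 0, 5,
                   0, 2.5, 10, 0, -2.5, 10,
                   0, 0, 2,   1, 1, 0,  -1, -1, 0),
                 ncol = 3, byrow = TRUE)
  coords <- array(NA_real_, c(natom, 3, nf))
  for (t in seq_len(nf))
    coords[, , t] <- base + matrix(rnorm(natom * 3, sd = 0.3), natom, 3)
  pdb_path <- file.path(dir, "fixture.pdb")
  dcd_path <- file.path(dir, "fixture.dcd")
  bio3d::write.pdb(file = pdb_path, xyz = as.vector(t(coords[, , 1])),
                   resno = seq_len(natom), resid = resid, elety = elety)
  write_dcd_fixture(dcd_path, coords)
  list(pdb = pdb_path, dcd = dcd_path, coords = coords,
       resid = resid, elety = elety)
}

default_fixture_spec <- function() {
  role_spec(
    Na = list(resid = "SOD"),
    carb = list(list(resid = "ASP", elety = "CG"),
                list(resid = "GLU", elety = "CD")),
    lys = list(resid = "LYS", elety = "NZ"),
    reference = list(elety = "CA"))
}

# independent brute-force complex classifier: plain loops, written directly
# from the state definitions, sharing no code with classify_frames()
brute_classify <- function(traj, cutoffs, channel_range = c(-15, 15)) {
  roles <- traj$roles
  ion_idx <- grep("^ion:", roles)
  carb_idx <- grep("^carb", roles)
  lys_idx <- which(roles == "lys" | startsWith(roles, "lys:"))
  ref_idx <- which(roles == "reference" | startsWith(roles, "reference:"))
  if (!length(ref_idx)) ref_idx <- c(carb_idx, lys_idx)
  sp <- sub("^ion:([^:]+):.*$", "\\1", roles[ion_idx])
  nf <- dim(traj$coords)[3]
  out <- character(nf)
  dist3 <- function(a, b) sqrt(sum((a - b)^2))
  for (t in seq_len(nf)) {
    X <- traj$coords[, , t]
    zr <- mean(X[ref_idx, 3])
    inch <- c()
    for (i in seq_along(ion_idx)) {
      z <- X[ion_idx[i], 3] - zr
      if (z > channel_range[1] && z < channel_range[2]) inch <- c(inch, i)
    }
    if (!length(inch)) { out[t] <- "unbound"; next }
    nb <- integer(length(inch))
    bound <- matrix(FALSE, length(inch), length(carb_idx))
    for (a in seq_along(inch)) {
      cc <- cutoffs[[sp[inch[a]]]]["ion_carb"]
      for (cix in seq_along(carb_idx))
        bound[a, cix] <- dist3(X[ion_idx[inch[a]], ], X[carb_idx[cix], ]) < cc
      nb[a] <- sum(bound[a, ])
    }
    tight <- FALSE
    if (length(inch) >= 2) {
      for (a in seq_along(inch)) for (b in seq_along(inch)) {
        if (b <= a) next
        iic <- (cutoffs[[sp[inch[a]]]]["ion_ion"] +
                cutoffs[[sp[inch[b]]]]["ion_ion"]) / 2
        if (dist3(X[ion_idx[inch[a]], ], X[ion_idx[inch[b]], ]) < iic &&
            sum(bound[a, ] & bound[b, ]) >= 2) tight <- TRUE
      }
    }
    ionlys <- FALSE
    if (length(lys_idx) == 1) {
      for (a in seq_along(inch)) {
        cc <- cutoffs[[sp[inch[a]]]]["ion_carb"]
        shared <- 0
        for (cix in seq_along(carb_idx))
          if (bound[a, cix] &&
              dist3(X[lys_idx, ], X[carb_idx[cix], ]) < cc)
            shared <- shared + 1
        if (shared >= 2) ionlys <- TRUE
      }
    }
    out[t] <- if (tight) "tight-multi" else if (ionlys) "ion+Lys" else
      if (max(nb) >= 2) "multi" else if (max(nb) == 1) "single" else "unbound"
  }
  out
}

# random labeled frames spanning the state space, mixed species
random_classification_traj <- function(n_frames, seed = 5) {
  set.seed(seed)
  m <- build_model()
  roster <- particle_roster(m, c(Na = 2, K = 1))
  n <- nrow(roster)
  coords <- array(NA_real_, c(n, 3, n_frames))
  ii <- which(roster$type == "ion")
  ic <- which(roster$type == "carb")
  il <- which(roster$type == "lys")
  ir <- which(roster$type == "reference")
  anchors <- as.matrix(m$carb_sites[, c("x", "y", "z")])
  for (t in seq_len(n_frames)) {
    coords[ii, 1, t] <- runif(length(ii), -5, 5)
    coords[ii, 2, t] <- runif(length(ii), -5, 5)
    coords[ii, 3, t] <- runif(length(ii), -20, 20)
    coords[ic, , t] <- anchors + matrix(rnorm(length(ic) * 3, sd = 1.5),
                                        length(ic), 3)
    coords[il, , t] <- c(rnorm(2, sd = 1), runif(1, -4, 4))
    coords[ir, , t] <- rnorm(3, sd = 0.1)
  }
  trajectory(coords, roster$role, seq_len(n_frames), m$box)
}

# independent bottleneck oracle: smallest threshold t such that the start
# and end regions are connected through bins with W <= t (BFS flood fill);
# equals the minimax path height
brute_bottleneck <- function(W, start_bins, end_bins, dims) {
  nb <- length(W)
  neigh <- function(i) {
    if (length(dims) == 1) {
      out <- c(i - 1L, i + 1L)
      return(out[out >= 1L & out <= nb])
    }
    r <- ((i - 1L) %% dims[1]) + 1L
    cc <- ((i - 1L) %/% dims[1]) + 1L
    dr <- rep(-1:1, 3); dc <- rep(-1:1, each = 3)
    rr <- r + dr; cn <- cc + dc
    ok <- (dr != 0 | dc != 0) & rr >= 1 & rr <= dims[1] &
          cn >= 1 & cn <= dims[2]
    (cn[ok] - 1L) * dims[1] + rr[ok]
  }
  connected_at <- function(t) {
    open <- !is.na(W) & W <= t
    if (!any(open[start_bins])) return(FALSE)
    seen <- rep(FALSE, nb)
    queue <- start_bins[open[start_bins]]
    seen[queue] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in neigh(i)) if (open[j] && !seen[j]) {
        seen[j] <- TRUE; queue <- c(queue, j)
      }
    }
    any(seen[end_bins])
  }
  for (t in sort(unique(W[!is.na(W)]))) if (connected_at(t)) return(t)
  NA_real_
}
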