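#' Construct a trajectory object
#'
#' The shared container for synthetic and imported trajectories: an ordered
#' stack of labeled 3D coordinate frames. Coordinates are in Angstrom; the z
#' axis is the pore axis with positive z extracellular.
#'
#' @param coords numeric array, particles x 3 x frames.
#' @param roles character vector of per-particle role labels
#'   (\code{ion:<species>:<id>}, \code{carb:<ring>:<domain>}, \code{lys},
#'   \code{reference}, or other labels treated as unassigned scaffold).
#' @param times numeric, strictly increasing frame times (ps).
#' @param box length-3 box edge lengths (A).
#' @return an object of class \code{ion_trajectory}.
#' @export
trajectory <- function(coords, roles, times, box) {
  if (length(dim(coords)) == 2) dim(coords) <- c(dim(coords), 1L)
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == 3)
  n <- dim(coords)[1]; nf <- dim(coords)[3]
  if (length(roles) != n) stop("roles must have one label per particle")
  if (anyDuplicated(roles)) stop("role labels must be unique per particle")
  if (length(times) != nf) stop("times must have one entry per frame")
  if (nf > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(coords = coords, roles = as.character(roles),
                 times = as.numeric(times), box = as.numeric(box)),
            class = "ion_trajectory")
}

#' @export
print.ion_trajectory <- function(x, ...) {
  cat(sprintf("<ion_trajectory> %d particles, %d frames\n",
              dim(x$coords)[1], dim(x$coords)[3]))
  cat("  roles:", paste(utils::head(x$roles, 8), collapse = " "),
      if (length(x$roles) > 8) "..." else "", "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an \code{ion_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

role_type <- function(roles) sub(":.*$", "", roles)

role_species <- function(roles) {
  out <- rep(NA_character_, length(roles))
  i <- grepl("^ion:", roles)
  out[i] <- sub("^ion:([^:]+):.*$", "\\1", roles[i])
  out
}

#' Write a trajectory in the native labeled-XYZ format
#'
#' Extended XYZ: per frame a particle-count line, a comment line carrying
#' \code{frame=},\code{time=} and \code{box=} metadata, then one line per
#' particle with columns element, x, y, z, role. Coordinates are written with
#' 0.001 A precision. An optional JSON sidecar stores times and box exactly.
#'
#' @param traj an \code{ion_trajectory}.
#' @param path output file path.
#' @param sidecar write \code{<path>.json} metadata (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "ion_trajectory"))
  n <- dim(traj$coords)[1]; nf <- dim(traj$coords)[3]
  elem <- ifelse(role_type(traj$roles) == "ion",
                 ifelse(is.na(role_species(traj$roles)), "X",
                        role_species(traj$roles)),
                 c(ion = "X", carb = "C", lys = "N",
                   reference = "X")[role_type(traj$roles)])
  elem[is.na(elem)] <- "X"
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(nf)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("frame=%d time=%.6f box=%s", t, traj$times[t],
                       paste(format(traj$box, trim = TRUE), collapse = ",")),
               con)
    writeLines(sprintf("%s %.3f %.3f %.3f %s", elem,
                       traj$coords[, 1, t], traj$coords[, 2, t],
                       traj$coords[, 3, t], traj$roles), con)
  }
  if (nf == 0) {               # header-only file for a degenerate trajectory
    writeLines(as.character(n), con)
    writeLines(sprintf("frame=0 time=0 box=%s",
                       paste(format(traj$box, trim = TRUE), collapse = ",")),
               con)
  }
  if (sidecar)
    jsonlite::write_json(list(n_particles = n, n_frames = nf,
                              roles = traj$roles, times = traj$times,
                              box = traj$box),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_trajectory_xyz <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty labeled-XYZ file")
  n <- as.integer(lines[1])
  block <- n + 2L
  nf <- length(lines) %/% block
  first <- strsplit(lines[2], " ")[[1]]
  box <- as.numeric(strsplit(sub("box=", "", first[grep("^box=", first)]),
                             ",")[[1]])
  if (n == 0 || nf == 0 || grepl("frame=0", lines[2])) {
    # header-only file: roles live in the sidecar when present
    side <- paste0(path, ".json")
    roles <- if (file.exists(side))
      as.character(jsonlite::fromJSON(side)$roles)
    else sprintf("unassigned:%d", seq_len(n))
    return(trajectory(array(0, c(n, 3, 0)), roles, numeric(0), box))
  }
  coords <- array(NA_real_, c(n, 3, nf))
  times <- numeric(nf)
  roles <- NULL
  for (t in seq_len(nf)) {
    off <- (t - 1L) * block
    meta <- strsplit(lines[off + 2L], " ")[[1]]
    times[t] <- as.numeric(sub("time=", "", meta[grep("^time=", meta)]))
    rows <- strsplit(lines[off + 2L + seq_len(n)], "[[:space:]]+")
    coords[, , t] <- t(vapply(rows, function(r) as.numeric(r[2:4]),
                              numeric(3)))
    if (t == 1L) roles <- vapply(rows, function(r) r[5], "")
  }
  trajectory(coords, roles, times, box)
}

#' Role-assignment specification for imported trajectories
#'
#' Maps role labels onto atom selections over (residue name, residue number,
#' atom name, chain). Each role gets a list of selection blocks; an atom
#' matches a block if it satisfies every field given in the block, and a role
#' if it matches any of its blocks. A typical spec selects ions by residue
#' name, carboxylates by the central carboxylate carbon of Asp/Glu side
#' chains (CG for Asp, CD for Glu) and the lysine by its terminal amine
#' nitrogen (NZ).
#'
#' @param ... named arguments: role label = list of selection blocks (each a
#'   list with any of \code{resid}, \code{elety}, \code{resno}, \code{chain});
#'   a single block may be given directly.
#' @return an object of class \code{role_spec}.
#' @examples
#' spec <- role_spec(
#'   Na   = list(resid = c("SOD", "NA")),
#'   carb = list(list(resid = "ASP", elety = "CG"),
#'               list(resid = "GLU", elety = "CD")),
#'   lys  = list(resid = "LYS", elety = "NZ"))
#' @export
role_spec <- function(...) {
  spec <- list(...)
  if (is.null(names(spec)) || any(names(spec) == ""))
    stop("every selection must be named with its role label")
  spec <- lapply(spec, function(s) {
    if (!is.null(names(s)) && any(names(s) %in% c("resid", "elety", "resno", "chain")))
      list(s) else s
  })
  structure(spec, class = "role_spec")
}

apply_role_spec <- function(atoms, spec) {
  # atoms: data.frame with resid, elety, resno, chain
  n <- nrow(atoms)
  assigned <- rep(NA_character_, n)
  for (role in names(spec)) {
    hit <- rep(FALSE, n)
    for (blk in spec[[role]]) {
      m <- rep(TRUE, n)
      for (f in names(blk)) {
        if (!f %in% names(atoms)) stop("unknown selection field: ", f)
        m <- m & (atoms[[f]] %in% blk[[f]])
      }
      hit <- hit | m
    }
    if (!any(hit))
      warning(sprintf("role '%s': selection matched no atoms", role))
    clash <- hit & !is.na(assigned)
    if (any(clash))
      stop(sprintf("role '%s' collides with role '%s' on %d atom(s)",
                   role, assigned[which(clash)[1]], sum(clash)))
    assigned[hit] <- role
  }
  assigned
}

# expand role labels to unique per-particle labels (ion roles get ids)
uniquify_roles <- function(assigned, ion_roles) {
  out <- assigned
  for (r in unique(assigned[!is.na(assigned)])) {
    idx <- which(assigned == r)
    if (r %in% ion_roles) {
      out[idx] <- sprintf("ion:%s:%d", r, seq_along(idx))
    } else if (r %in% c("lys", "reference")) {
      out[idx] <- if (length(idx) == 1) r else sprintf("%s:%d", r, seq_along(idx))
    } else {
      out[idx] <- sprintf("%s:%d", r, seq_along(idx))
    }
  }
  out[is.na(out)] <- sprintf("unassigned:%d", seq_len(sum(is.na(out))))
  out
}

#' Load a trajectory from standard MD formats or labeled XYZ
#'
#' For PDB + DCD input, topology parsing and DCD decoding are delegated to
#' \pkg{bio3d}; roles are then assigned from a [role_spec()]. Entries of the
#' spec named after ion species become \code{ion:<species>:<id>} roles;
#' entries named \code{carb} become \code{carb:<i>}; \code{lys} and
#' \code{reference} pass through. For the native labeled-XYZ format the role
#' column is read directly and \code{spec} is ignored.
#'
#' @param coords path to a DCD or labeled-XYZ coordinate file.
#' @param topology path to a PDB topology (required for DCD input).
#' @param spec a [role_spec()] (required for DCD input).
#' @param ion_roles which spec names denote ion species (default: any name
#'   that is not \code{carb}, \code{lys} or \code{reference}).
#' @return an \code{ion_trajectory}.
#' @export
load_trajectory <- function(coords, topology = NULL, spec = NULL,
                            ion_roles = NULL) {
  ext <- tolower(tools::file_ext(coords))
  if (ext %in% c("xyz", "exyz")) return(read_trajectory_xyz(coords))
  if (ext == "xtc")
    stop("XTC input is not supported; convert to DCD or labeled XYZ")
  if (ext != "dcd") stop("unsupported coordinate format: ", ext)
  if (is.null(topology) || is.null(spec))
    stop("DCD input needs a PDB topology and a role_spec")
  pdb <- bio3d::read.pdb(topology)
  xyz <- bio3d::read.dcd(coords, verbose = FALSE)
  if (ncol(xyz) != 3 * nrow(pdb$atom))
    stop(sprintf("atom-count mismatch: PDB has %d atoms, DCD has %d",
                 nrow(pdb$atom), ncol(xyz) / 3))
  atoms <- data.frame(resid = pdb$atom$resid, elety = pdb$atom$elety,
                      resno = pdb$atom$resno, chain = pdb$atom$chain,
                      stringsAsFactors = FALSE)
  assigned <- apply_role_spec(atoms, spec)
  if (is.null(ion_roles))
    ion_roles <- setdiff(names(spec), c("carb", "lys", "reference"))
  roles <- uniquify_roles(assigned, ion_roles)
  n <- nrow(atoms); nf <- nrow(xyz)
  coords_arr <- array(NA_real_, c(n, 3, nf))
  for (t in seq_len(nf))
    coords_arr[, , t] <- matrix(xyz[t, ], ncol = 3, byrow = TRUE)
  box <- rep(2 * max(abs(coords_arr), na.rm = TRUE), 3)
  trajectory(coords_arr, roles, seq_len(nf), box)
}

#' Write a trajectory
#'
#' @param traj an \code{ion_trajectory}.
#' @param path output path.
#' @param format only \code{"xyz"} (native labeled XYZ) is supported.
#' @param ... passed to the format writer.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path, format = "xyz", ...) {
  if (format != "xyz") stop("unsupported trajectory format: ", format)
  write_trajectory_xyz(traj, path, ...)
}

#' Role partition summary
#'
#' Counts particles per role type plus unassigned; the counts always sum to
#' the total particle number.
#'
#' @param traj an \code{ion_trajectory}.
#' @return named integer vector.
#' @export
role_partition <- function(traj) {
  ty <- role_type(traj$roles)
  ty[!ty %in% c("ion", "carb", "lys", "reference")] <- "unassigned"
  table(factor(ty, levels = c("ion", "carb", "lys", "reference", "unassigned")))
}
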