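# Kabsch superposition of mobile onto ref (both n x 3, n >= 3): returns the
# rotated+translated mobile coordinates
kabsch_fit <- function(mobile, ref) {
  cm <- colMeans(mobile); cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm); B <- sweep(ref, 2, cr)
  H <- t(A) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(A %*% t(R), 2, cr, "+")
}

#' RMSD and RMSF with global or per-subunit superposition
#'
#' Each frame is least-squares superposed (orthogonal Procrustes) onto the
#' reference frame before deviations are computed. In per-subunit mode each
#' declared subunit is fitted independently, so rigid-body motions of
#' individual subunits do not inflate the fluctuations of their atoms.
#'
#' @param traj an \code{ion_trajectory}.
#' @param selection particle indices (default: all non-ion particles).
#' @param ref_frame reference frame index (default 1).
#' @param mode "global" or "per-subunit".
#' @param subunits list of index vectors (within \code{selection}) declaring
#'   the subunits; required for per-subunit mode.
#' @return object of class \code{superposition_result}: per-frame \code{rmsd}
#'   (A), per-particle \code{rmsf} (A), the mode, and the selection used.
#' @export
rmsd_rmsf <- function(traj, selection = NULL, ref_frame = 1,
                      mode = c("global", "per-subunit"), subunits = NULL) {
  mode <- match.arg(mode)
  if (is.null(selection))
    selection <- which(role_type(traj$roles) != "ion")
  if (length(selection) < 3) stop("need at least 3 atoms in the selection")
  nf <- n_frames(traj)
  if (ref_frame < 1 || ref_frame > nf) stop("ref_frame out of range")
  if (mode == "per-subunit") {
    if (is.null(subunits)) stop("per-subunit mode needs a subunits list")
    groups <- subunits
  } else groups <- list(seq_along(selection))
  ref <- matrix(traj$coords[selection, , ref_frame], ncol = 3)
  # degenerate-geometry guard: Procrustes needs non-collinear references
  if (qr(sweep(ref, 2, colMeans(ref)))$rank < 2)
    stop("reference selection is collinear; superposition is ill-defined")
  fitted <- array(NA_real_, c(length(selection), 3, nf))
  for (t in seq_len(nf)) {
    X <- matrix(traj$coords[selection, , t], ncol = 3)
    for (g in groups) {
      if (length(g) < 3) stop("each subunit needs at least 3 atoms")
      fitted[g, , t] <- kabsch_fit(X[g, , drop = FALSE],
                                   ref[g, , drop = FALSE])
    }
  }
  dev2 <- (fitted - array(ref, dim(fitted)))^2
  rmsd <- sqrt(colMeans(apply(dev2, c(1, 3), sum)))
  mean_str <- apply(fitted, c(1, 2), mean)
  fl2 <- (fitted - array(mean_str, dim(fitted)))^2
  rmsf <- sqrt(rowMeans(apply(fl2, c(1, 3), sum)))
  structure(list(rmsd = rmsd, rmsf = rmsf, mode = mode,
                 selection = selection),
            class = "superposition_result")
}

#' Ion (or any role) occupancy density map
#'
#' Counts per voxel divided by (frames x voxel volume); the integral over
#' the mapped region equals the mean particle count in that region.
#'
#' @param traj an \code{ion_trajectory}.
#' @param role role pattern to map (default "ion").
#' @param spacing voxel edge (A), > 0.
#' @param limits optional list of c(lo, hi) per axis; default spans the data.
#' @return list with \code{density} (3D array, A^-3), \code{edges} (per-axis
#'   bin edges), \code{spacing}, \code{n_frames}.
#' @export
density_map <- function(traj, role = "ion", spacing = 1, limits = NULL) {
  if (spacing <= 0) stop("spacing must be > 0")
  ii <- match_roles(traj$roles, role)
  if (!length(ii)) stop("no particles match role: ", role)
  nf <- n_frames(traj)
  P <- matrix(aperm(traj$coords[ii, , , drop = FALSE], c(1, 3, 2)), ncol = 3)
  edges <- lapply(1:3, function(k) {
    lim <- if (!is.null(limits)) limits[[k]] else
      c(floor(min(P[, k]) / spacing) * spacing,
        ceiling(max(P[, k]) / spacing) * spacing + spacing / 2)
    seq(lim[1], lim[2] + spacing / 2, by = spacing)
  })
  nb <- vapply(edges, function(e) length(e) - 1L, 0L)
  b <- vapply(1:3, function(k) {
    v <- findInterval(P[, k], edges[[k]], rightmost.closed = TRUE)
    v[v < 1 | v > nb[k]] <- NA_integer_
    v
  }, integer(nrow(P)))
  b <- matrix(b, ncol = 3)
  ok <- stats::complete.cases(b)
  idx <- (b[ok, 3] - 1L) * nb[1] * nb[2] + (b[ok, 2] - 1L) * nb[1] + b[ok, 1]
  counts <- array(tabulate(idx, nbins = prod(nb)), dim = nb)
  list(density = counts / (nf * spacing^3), edges = edges,
       spacing = spacing, n_frames = nf)
}

#' Time-averaged screened-Coulomb potential map
#'
#' For each frame the potential of all declared point charges is evaluated
#' on a grid (by default a 2D x-z slice through the pore axis at y = 0) and
#' averaged over frames. Distances below 1 A from any charge are evaluated
#' at 1 A, capping the singularity. This is a qualitative electrostatic
#' analog: a uniform dielectric stands in for solvent screening.
#'
#' @param traj an \code{ion_trajectory}.
#' @param charges named numeric: charge (e) per role type (e.g.
#'   \code{c(ion = 1, carb = -1, lys = 1)}); every mapped role must appear.
#' @param grid list with \code{x}, \code{z} (and optionally \code{y})
#'   coordinate vectors; default a 1 A x-z grid spanning the box.
#' @param dielectric uniform relative permittivity (default 2).
#' @param include role pattern of charge-carrying particles to include
#'   (default all with a declared charge).
#' @return list with \code{phi} (matrix x-by-z or 3D array, kcal/mol/e),
#'   \code{grid}, \code{dielectric}.
#' @export
electrostatic_map <- function(traj, charges, grid = NULL, dielectric = 2,
                              include = NULL) {
  ty <- role_type(traj$roles)
  ii <- which(ty %in% names(charges))
  if (!is.null(include)) ii <- intersect(ii, match_roles(traj$roles, include))
  missing_q <- setdiff(unique(ty[ty %in% c("ion", "carb", "lys")]),
                       names(charges))
  if (length(missing_q))
    stop("no charge declared for role(s): ", paste(missing_q, collapse = ", "))
  if (!length(ii)) stop("no charged particles selected")
  q <- charges[ty[ii]]
  if (is.null(grid)) {
    hx <- traj$box[1] / 2; hz <- traj$box[3] / 2
    grid <- list(x = seq(-hx, hx, by = 1), y = 0, z = seq(-hz, hz, by = 1))
  }
  if (is.null(grid$y)) grid$y <- 0
  pts <- as.matrix(expand.grid(x = grid$x, y = grid$y, z = grid$z))
  nf <- n_frames(traj)
  phi <- numeric(nrow(pts))
  kC <- .kC_default
  for (t in seq_len(nf)) {
    X <- matrix(traj$coords[ii, , t], ncol = 3)
    for (p in seq_along(q)) {
      r <- sqrt((pts[, 1] - X[p, 1])^2 + (pts[, 2] - X[p, 2])^2 +
                (pts[, 3] - X[p, 3])^2)
      phi <- phi + kC * q[p] / (dielectric * pmax(r, 1))
    }
  }
  phi <- phi / nf
  dims <- c(length(grid$x), length(grid$y), length(grid$z))
  phi <- array(phi, dims)
  if (dims[2] == 1) phi <- phi[, 1, ]
  list(phi = phi, grid = grid, dielectric = dielectric)
}
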