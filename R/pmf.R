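#' Occupancy-conditioned axial reaction coordinates
#'
#' For each retained frame, takes the z positions of all ions strictly inside
#' the channel region, measured relative to the scaffold reference
#' (\code{z_ref}, the per-frame center of mass of particles with role
#' \code{reference}, or of all carboxylate/lysine beads when no explicit
#' reference role exists), rank-sorts them ascending (z1 = lower-most ion)
#' and forms the pair centroids z12 = (z1+z2)/2 and z23 = (z2+z3)/2, plus
#' the lysine bead position zLys. Ion identity is deliberately not tracked:
#' the coordinates are order statistics, so permuting ion ids leaves them
#' unchanged.
#'
#' @param traj an \code{ion_trajectory}.
#' @param channel_range length-2 interval in z (A); ions outside the open
#'   interval are excluded from the ranks.
#' @param equil_discard fraction of initial frames discarded as equilibration
#'   (0 <= f < 1).
#' @param species restrict to one ion species (default: all ions).
#' @return data.frame of class \code{axial_states} with columns \code{frame},
#'   \code{time}, \code{n} (occupancy), \code{z1}, \code{z2}, \code{z3},
#'   \code{z12}, \code{z23}, \code{zLys}; unoccupied ranks are NA.
#' @export
axial_states <- function(traj, channel_range = c(-15, 15),
                         equil_discard = 0, species = NULL) {
  stopifnot(inherits(traj, "ion_trajectory"))
  if (equil_discard < 0 || equil_discard >= 1)
    stop("equil_discard must be in [0, 1)")
  ty <- role_type(traj$roles)
  iref <- which(ty == "reference")
  if (!length(iref)) iref <- which(ty %in% c("carb", "lys"))
  if (!length(iref))
    stop("no reference role (and no scaffold beads) to define z_ref")
  ii <- which(ty == "ion")
  if (!is.null(species))
    ii <- ii[role_species(traj$roles)[ii] %in% species]
  if (!length(ii)) stop("no ion roles present")
  ilys <- which(ty == "lys")
  nf <- n_frames(traj)
  keep <- seq_len(nf)
  if (equil_discard > 0) keep <- keep[keep > floor(nf * equil_discard)]
  zref <- if (length(iref) == 1) traj$coords[iref, 3, ] else
    colMeans(matrix(traj$coords[iref, 3, ], nrow = length(iref)))
  out <- data.frame(frame = keep, time = traj$times[keep], n = 0L,
                    z1 = NA_real_, z2 = NA_real_, z3 = NA_real_,
                    z12 = NA_real_, z23 = NA_real_, zLys = NA_real_)
  zion <- matrix(traj$coords[ii, 3, ], nrow = length(ii))
  for (r in seq_along(keep)) {
    t <- keep[r]
    z <- zion[, t] - zref[t]
    z <- sort(z[z > channel_range[1] & z < channel_range[2]])
    out$n[r] <- length(z)
    if (length(z) >= 1) out$z1[r] <- z[1]
    if (length(z) >= 2) { out$z2[r] <- z[2]; out$z12[r] <- (z[1] + z[2]) / 2 }
    if (length(z) >= 3) { out$z3[r] <- z[3]; out$z23[r] <- (z[2] + z[3]) / 2 }
    if (length(ilys)) out$zLys[r] <- traj$coords[ilys[1], 3, t] - zref[t]
  }
  class(out) <- c("axial_states", "data.frame")
  out
}

moving_block_indices <- function(N, block) {
  block <- max(1L, min(block, N))
  nb <- ceiling(N / block)
  starts <- sample.int(max(N - block + 1L, 1L), nb, replace = TRUE)
  idx <- as.vector(outer(0:(block - 1L), starts, `+`))
  idx[seq_len(N)]
}

#' Boltzmann-inverted free-energy grid
#'
#' Histograms one or two axial coordinates over frames at a given occupancy
#' and inverts the normalized density to a free energy,
#' \eqn{W = -k_B T \ln\rho + C}, with the constant chosen so the sampled
#' minimum is zero. Per-bin standard errors come from a moving-block
#' bootstrap over frames (blocks of consecutive saved frames, so serial
#' correlation is respected).
#'
#' @param states an \code{axial_states} data.frame.
#' @param coords one or two of \code{"z1"}, \code{"z2"}, \code{"z3"},
#'   \code{"z12"}, \code{"z23"}, \code{"zLys"}.
#' @param occupancy condition on this pore ion occupancy (NULL: all frames
#'   with the requested coordinates defined).
#' @param bin_width bin width in A (default 0.5).
#' @param kT thermal energy kB*T in kcal/mol.
#' @param n_boot bootstrap replicates (default 200).
#' @param block bootstrap block length in saved frames (default 200).
#' @param seed RNG seed for the bootstrap.
#' @param range optional list of per-axis c(lo, hi) histogram limits.
#' @return object of class \code{pmf_grid}: axes (name, edges, centers),
#'   counts, density, W (kcal/mol, NA on unsampled bins), se, kT.
#' @export
pmf <- function(states, coords, occupancy = NULL, bin_width = 0.5,
                kT = kBT(), n_boot = 200, block = 200, seed = 1,
                range = NULL) {
  if (!all(coords %in% c("z1", "z2", "z3", "z12", "z23", "zLys")))
    stop("coords must name axial coordinates (z1, z2, z3, z12, z23, zLys)")
  if (length(coords) > 2) stop("1D and 2D grids only")
  if (bin_width <= 0) stop("bin_width must be > 0")
  df <- states
  if (!is.null(occupancy)) df <- df[df$n == occupancy, , drop = FALSE]
  X <- as.matrix(df[, coords, drop = FALSE])
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  if (!nrow(X))
    stop(sprintf("no frames at occupancy %s", as.character(occupancy)))
  axes <- lapply(seq_along(coords), function(k) {
    lim <- if (!is.null(range)) range[[k]] else
      c(floor(min(X[, k]) / bin_width) * bin_width,
        ceiling(max(X[, k]) / bin_width) * bin_width)
    if (diff(lim) <= 0) lim <- lim + c(-bin_width, bin_width) / 2
    edges <- seq(lim[1], lim[2], by = bin_width)
    if (utils::tail(edges, 1) < lim[2]) edges <- c(edges, utils::tail(edges, 1) + bin_width)
    list(name = coords[k], edges = edges,
         centers = edges[-length(edges)] + bin_width / 2)
  })
  binof <- function(v, ax) {
    b <- findInterval(v, ax$edges, rightmost.closed = TRUE)
    b[b < 1 | b > length(ax$centers)] <- NA
    b
  }
  count_grid <- function(Xs) {
    b1 <- binof(Xs[, 1], axes[[1]])
    if (length(axes) == 1) {
      tabulate(b1[!is.na(b1)], nbins = length(axes[[1]]$centers))
    } else {
      b2 <- binof(Xs[, 2], axes[[2]])
      ok2 <- !is.na(b1) & !is.na(b2)
      n1 <- length(axes[[1]]$centers); n2 <- length(axes[[2]]$centers)
      matrix(tabulate((b2[ok2] - 1L) * n1 + b1[ok2], nbins = n1 * n2), n1, n2)
    }
  }
  binvol <- bin_width ^ length(axes)
  w_of <- function(cnt) {
    rho <- cnt / (sum(cnt) * binvol)
    W <- -kT * log(rho)
    W[!is.finite(W)] <- NA
    W - min(W, na.rm = TRUE)
  }
  counts <- count_grid(X)
  W <- w_of(counts)
  se <- counts * NA_real_
  if (n_boot > 0 && nrow(X) > 1) {
    set.seed(seed)
    reps <- array(NA_real_, c(length(counts), n_boot))
    for (b in seq_len(n_boot)) {
      idx <- moving_block_indices(nrow(X), block)
      reps[, b] <- as.vector(w_of(count_grid(X[idx, , drop = FALSE])))
    }
    se[] <- apply(reps, 1, stats::sd, na.rm = TRUE)
    se[is.na(W)] <- NA
  }
  structure(list(axes = axes, counts = counts,
                 density = counts / (sum(counts) * binvol),
                 W = W, se = se, kT = kT, bin_width = bin_width,
                 n_frames = nrow(X)),
            class = "pmf_grid")
}

#' @export
print.pmf_grid <- function(x, ...) {
  cat(sprintf("<pmf_grid> %s; %s bins; %d frames; kT = %.4g kcal/mol\n",
              paste(vapply(x$axes, `[[`, "", "name"), collapse = " x "),
              paste(vapply(x$axes, function(a) length(a$centers), 0L),
                    collapse = " x "),
              x$n_frames, x$kT))
  invisible(x)
}

#' Write a PMF grid as TSV
#'
#' Long format: one row per sampled bin with bin centers, counts, W and SE.
#'
#' @param grid a \code{pmf_grid}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pmf_tsv <- function(grid, path) {
  if (length(grid$axes) == 1) {
    df <- data.frame(x = grid$axes[[1]]$centers, counts = grid$counts,
                     W = grid$W, se = grid$se)
    names(df)[1] <- grid$axes[[1]]$name
  } else {
    g <- expand.grid(x = grid$axes[[1]]$centers, y = grid$axes[[2]]$centers)
    df <- data.frame(g$x, g$y, counts = as.vector(grid$counts),
                     W = as.vector(grid$W), se = as.vector(grid$se))
    names(df)[1:2] <- vapply(grid$axes, `[[`, "", "name")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

region_bins <- function(grid, region) {
  # region: c(lo, hi) in 1D, or list(c(lo,hi), c(lo,hi)) in 2D
  if (length(grid$axes) == 1) {
    ctr <- grid$axes[[1]]$centers
    which(ctr >= region[1] & ctr <= region[2])
  } else {
    if (!is.list(region)) stop("2D region must be a list of two intervals")
    c1 <- grid$axes[[1]]$centers; c2 <- grid$axes[[2]]$centers
    i1 <- c1 >= region[[1]][1] & c1 <= region[[1]][2]
    i2 <- c2 >= region[[2]][1] & c2 <= region[[2]][2]
    which(outer(i1, i2, `&`))
  }
}

#' Minimum-free-energy (minimax bottleneck) path and barrier
#'
#' Finds, among all paths across sampled bins from the start region to the
#' end region, the one minimizing the highest free energy encountered
#' (the bottleneck path). Connectivity is adjacency in 1D and 8-neighbor in
#' 2D; unsampled (masked) bins are impassable. The barrier is the maximum W
#' on the path minus the minimum W inside the start region.
#'
#' @param grid a \code{pmf_grid}.
#' @param start,end regions: c(lo, hi) on the axis (1D) or a list of two
#'   intervals (2D).
#' @return list with \code{path} (matrix of bin indices, one row per step),
#'   \code{barrier} (kcal/mol), \code{path_max} and \code{start_min}.
#' @export
mfep_barrier <- function(grid, start, end) {
  W <- as.vector(grid$W)
  nd <- length(grid$axes)
  dims <- vapply(grid$axes, function(a) length(a$centers), 0L)
  sbin <- intersect(region_bins(grid, start), which(!is.na(W)))
  ebin <- intersect(region_bins(grid, end), which(!is.na(W)))
  if (!length(sbin)) stop("start region contains no sampled bins")
  if (!length(ebin)) stop("end region contains no sampled bins")
  nb <- length(W)
  neighbors <- function(i) {
    if (nd == 1) {
      out <- c(i - 1L, i + 1L)
      out[out >= 1L & out <= nb]
    } else {
      r <- ((i - 1L) %% dims[1]) + 1L
      cc <- ((i - 1L) %/% dims[1]) + 1L
      dr <- rep(-1:1, 3); dc <- rep(-1:1, each = 3)
      rr <- r + dr; cn <- cc + dc
      ok <- (dr != 0 | dc != 0) & rr >= 1 & rr <= dims[1] &
            cn >= 1 & cn <= dims[2]
      (cn[ok] - 1L) * dims[1] + rr[ok]
    }
  }
  v <- rep(Inf, nb); v[sbin] <- W[sbin]
  pred <- rep(NA_integer_, nb)
  done <- rep(FALSE, nb); done[is.na(W)] <- TRUE
  repeat {
    u <- which.min(ifelse(done, Inf, v))
    if (!length(u) || !is.finite(v[u])) break
    done[u] <- TRUE
    if (u %in% ebin && all(done[ebin] | !is.finite(v[ebin]))) break
    for (w in neighbors(u)) {
      if (done[w] || is.na(W[w])) next
      cand <- max(v[u], W[w])
      if (cand < v[w]) { v[w] <- cand; pred[w] <- u }
    }
    if (all(done | !is.finite(v))) break
  }
  besti <- ebin[which.min(v[ebin])]
  if (!is.finite(v[besti])) stop("disconnected landscape")
  path <- besti
  while (!is.na(pred[path[1]])) path <- c(pred[path[1]], path)
  idx <- if (nd == 1) matrix(path, ncol = 1) else
    cbind(((path - 1L) %% dims[1]) + 1L, ((path - 1L) %/% dims[1]) + 1L)
  start_min <- min(W[sbin])
  list(path = idx, barrier = v[besti] - start_min,
       path_max = v[besti], start_min = start_min)
}

#' Pore occupancy distribution
#'
#' @param states an \code{axial_states} data.frame.
#' @param n_boot,block,seed moving-block bootstrap settings for the SE of the
#'   mean occupancy.
#' @return list with \code{prob} (named probabilities per occupancy),
#'   \code{mean}, \code{se}.
#' @export
occupancy_distribution <- function(states, n_boot = 200, block = 200,
                                   seed = 1) {
  if (!nrow(states)) stop("empty states")
  tab <- table(states$n)
  prob <- as.numeric(tab) / nrow(states)
  names(prob) <- names(tab)
  mu <- mean(states$n)
  se <- NA_real_
  if (n_boot > 0 && nrow(states) > 1) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b)
      mean(states$n[moving_block_indices(nrow(states), block)]), 0)
    se <- stats::sd(reps)
  }
  list(prob = prob, mean = mu, se = se)
}
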