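# role pattern matching: "ion" matches every ion, "ion:Na" all Na ions,
# "carb:inner" the inner ring, an exact role string matches itself
match_roles <- function(roles, pattern) {
  which(roles == pattern | startsWith(roles, paste0(pattern, ":")))
}

#' Radial distribution function between two roles
#'
#' Shell-normalized pair histogram averaged over frames, with minimum-image
#' distances (the conventional periodic normalization, so a uniform fixture
#' gives g(r) ~ 1). For the confined toy channel the first-shell region is
#' far from the box edges, where the image convention is immaterial.
#'
#' @param traj an \code{ion_trajectory}.
#' @param pair character of length 2, role patterns (e.g.
#'   \code{c("ion:Na", "carb")}).
#' @param r_max maximum distance (A); must not exceed half the smallest box
#'   edge.
#' @param bin bin width (A), default 0.05.
#' @param periodic apply the minimum-image convention (default TRUE).
#' @return object of class \code{rdf_profile}: data.frame with \code{r}
#'   (bin centers) and \code{g}, plus attributes.
#' @export
rdf <- function(traj, pair, r_max = 10, bin = 0.05, periodic = TRUE) {
  iA <- match_roles(traj$roles, pair[1])
  iB <- match_roles(traj$roles, pair[2])
  if (!length(iA) || !length(iB)) stop("empty selection for rdf pair")
  if (r_max > min(traj$box) / 2)
    stop("r_max must not exceed half the smallest box edge")
  same <- identical(sort(iA), sort(iB))
  edges <- seq(0, r_max, by = bin)
  nbin <- length(edges) - 1L
  counts <- numeric(nbin)
  nf <- n_frames(traj)
  for (t in seq_len(nf)) {
    A <- traj$coords[iA, , t, drop = FALSE][, , 1, drop = TRUE]
    B <- traj$coords[iB, , t, drop = FALSE][, , 1, drop = TRUE]
    if (is.null(dim(A))) A <- matrix(A, ncol = 3)
    if (is.null(dim(B))) B <- matrix(B, ncol = 3)
    D2 <- 0
    for (k in 1:3) {
      dk <- outer(A[, k], B[, k], "-")
      if (periodic) dk <- dk - traj$box[k] * round(dk / traj$box[k])
      D2 <- D2 + dk^2
    }
    D <- sqrt(D2)
    d <- if (same) D[upper.tri(D)] else as.vector(D)
    d <- d[d < r_max]
    if (length(d))
      counts <- counts + tabulate(findInterval(d, edges,
                                               rightmost.closed = TRUE),
                                  nbins = nbin)
  }
  V <- prod(traj$box)
  npair <- if (same) length(iA) * (length(iA) - 1) / 2 else
    length(iA) * length(iB)
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (nf * npair * shell / V)
  out <- data.frame(r = edges[-length(edges)] + bin / 2, g = g)
  structure(out, class = c("rdf_profile", "data.frame"),
            pair = pair, bin = bin, n_frames = nf, counts = counts)
}

#' First minimum of a radial distribution function
#'
#' Smooths g(r) with a centered moving average (default 5 bins), locates the
#' first local maximum and returns the r of the first local minimum after
#' it -- the conventional data-driven binding cutoff.
#'
#' @param profile an \code{rdf_profile} (or data.frame with \code{r},
#'   \code{g}).
#' @param smooth_window moving-average window in bins (odd, default 5).
#' @return cutoff radius in A.
#' @export
first_minimum <- function(profile, smooth_window = 5) {
  g <- profile$g; r <- profile$r
  k <- max(1L, smooth_window %/% 2L)
  gs <- stats::filter(g, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  gs <- as.numeric(gs)
  ok <- which(!is.na(gs))
  gs <- gs[ok]; rs <- r[ok]
  n <- length(gs)
  d <- diff(gs)
  imax <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  # ignore noise ripples: a shell peak must be a substantial maximum
  imax <- imax[gs[imax] > 0.2 * max(gs)]
  if (!length(imax)) stop("no shell structure in g(r)")
  i0 <- imax[1]
  d2 <- diff(gs[i0:n])
  imin <- which(d2[-length(d2)] < 0 & d2[-1] >= 0) + i0
  if (!length(imin)) stop("no shell structure in g(r)")
  rs[imin[1]]
}

#' Species-specific complex cutoffs
#'
#' Defaults follow the convention of defining multi-ion clusters and
#' carboxylate binding from the first minima of the respective radial
#' distribution functions: ion-ion 4.7 A and ion-carboxylate 3.8 A for the
#' Na-like species, 5.5 A and 4.2 A for the K-like species.
#'
#' @param ... per-species overrides: \code{Na = c(ion_ion = , ion_carb = )}.
#' @return object of class \code{complex_cutoffs}.
#' @export
complex_cutoffs <- function(...) {
  cut <- list(Na = c(ion_ion = 4.7, ion_carb = 3.8),
              K  = c(ion_ion = 5.5, ion_carb = 4.2))
  over <- list(...)
  for (sp in names(over)) cut[[sp]] <- over[[sp]]
  for (sp in names(cut)) {
    v <- cut[[sp]]
    if (any(v <= 0)) stop("cutoffs must be > 0")
    if (v["ion_ion"] <= v["ion_carb"])
      warning(sprintf("%s: ion_ion cutoff not larger than ion_carb", sp))
  }
  structure(cut, class = "complex_cutoffs")
}

frame_geometry <- function(traj) {
  ty <- role_type(traj$roles)
  list(ion = which(ty == "ion"),
       sp = role_species(traj$roles),
       carb = which(ty == "carb"),
       lys = which(ty == "lys"),
       ref = { r <- which(ty == "reference")
               if (length(r)) r else which(ty %in% c("carb", "lys")) })
}

#' Classify frames into ion/carboxylate complex states
#'
#' Per frame, ions strictly inside the channel region are tested against the
#' species cutoffs and the frame is assigned exactly one state with the
#' precedence \code{tight-multi > ion+Lys > multi > single > unbound}:
#' \itemize{
#'   \item \code{tight-multi}: two channel ions within the ion-ion cutoff
#'     jointly coordinated by at least two carboxylate beads, each within
#'     the ion-carboxylate cutoff of both members of the pair (bridging
#'     carboxylates, the signature of a collectively bound cluster);
#'   \item \code{ion+Lys}: the lysine bead and one ion each within the
#'     ion-carboxylate cutoff of at least two shared carboxylates;
#'   \item \code{multi}: some ion bound to two or more carboxylates;
#'   \item \code{single}: some ion bound to exactly one carboxylate;
#'   \item \code{unbound}: no ion-carboxylate contact.
#' }
#' For an ion pair of different species the ion-ion cutoff is the mean of
#' the two species cutoffs.
#'
#' @param traj an \code{ion_trajectory}.
#' @param cutoffs a [complex_cutoffs()] object.
#' @param channel_range channel region in z relative to the reference (A).
#' @return object of class \code{frame_classification}: data.frame with
#'   \code{frame}, \code{n} (occupancy), \code{state}; attribute
#'   \code{participation} is a frames x carboxylates logical matrix of
#'   binding involvement, \code{carb_roles} its column labels.
#' @export
classify_frames <- function(traj, cutoffs = complex_cutoffs(),
                            channel_range = c(-15, 15)) {
  geo <- frame_geometry(traj)
  if (!length(geo$ion) || !length(geo$carb))
    stop("classification needs ion and carb roles")
  sp_ion <- geo$sp[geo$ion]
  for (sp in unique(sp_ion))
    if (is.null(cutoffs[[sp]]))
      stop("missing cutoffs for species present in trajectory: ", sp)
  nf <- n_frames(traj)
  states <- character(nf)
  occ <- integer(nf)
  part <- matrix(FALSE, nf, length(geo$carb))
  lysb <- logical(nf)
  for (t in seq_len(nf)) {
    X <- traj$coords[, , t]
    zref <- mean(X[geo$ref, 3])
    zi <- X[geo$ion, 3] - zref
    inch <- which(zi > channel_range[1] & zi < channel_range[2])
    occ[t] <- length(inch)
    ions <- geo$ion[inch]
    if (!length(ions)) { states[t] <- "unbound"; next }
    cc <- cutoffs
    icut <- vapply(sp_ion[inch], function(s) cc[[s]]["ion_carb"], 0)
    # ion-carb contact matrix
    dC <- sqrt(outer(X[ions, 1], X[geo$carb, 1], "-")^2 +
               outer(X[ions, 2], X[geo$carb, 2], "-")^2 +
               outer(X[ions, 3], X[geo$carb, 3], "-")^2)
    bound <- sweep(dC, 1, icut, "<")
    if (is.null(dim(bound))) bound <- matrix(bound, nrow = length(ions))
    nb <- rowSums(bound)
    part[t, ] <- colSums(bound) > 0
    state <- if (any(nb >= 2)) "multi" else if (any(nb == 1)) "single" else
      "unbound"
    # ion+Lys: shared carboxylates binding both the lysine bead and an ion
    if (length(geo$lys)) {
      dL <- sqrt(colSums((t(X[geo$carb, , drop = FALSE]) -
                          X[geo$lys[1], ])^2))
      for (k in seq_along(ions)) {
        shared <- bound[k, ] & (dL < icut[k])
        if (sum(shared) >= 2) { lysb[t] <- TRUE; break }
      }
      if (lysb[t]) state <- "ion+Lys"
    }
    if (length(ions) >= 2) {
      dI <- sqrt(outer(X[ions, 1], X[ions, 1], "-")^2 +
                 outer(X[ions, 2], X[ions, 2], "-")^2 +
                 outer(X[ions, 3], X[ions, 3], "-")^2)
      tight <- FALSE
      for (a in seq_along(ions)) {
        for (b in seq_along(ions)) {
          if (b <= a) next
          ii_cut <- mean(c(cc[[sp_ion[inch[a]]]]["ion_ion"],
                           cc[[sp_ion[inch[b]]]]["ion_ion"]))
          if (dI[a, b] < ii_cut && sum(bound[a, ] & bound[b, ]) >= 2) {
            tight <- TRUE; break
          }
        }
        if (tight) break
      }
      if (tight) state <- "tight-multi"
    }
    states[t] <- state
  }
  out <- data.frame(frame = seq_len(nf), n = occ, state = states)
  structure(out, class = c("frame_classification", "data.frame"),
            participation = part, ion_lys = lysb,
            carb_roles = traj$roles[geo$carb])
}

#' Summary tables for a frame classification
#'
#' @param cls a \code{frame_classification}.
#' @return list with \code{state_fraction} (state x occupancy-class table of
#'   time fractions), \code{carb_involvement} (per-carboxylate binding
#'   fraction, normalized both over all frames and over bound frames),
#'   \code{ring_involvement} (inner / outer / both, same two normalizations)
#'   and \code{ion_lys_fraction}.
#' @export
complex_summary <- function(cls) {
  part <- attr(cls, "participation")
  carbs <- attr(cls, "carb_roles")
  occ_class <- ifelse(cls$n <= 1, "1-ion", "multi-ion")
  tab <- table(state = cls$state, occupancy = occ_class)
  frac <- sweep(tab, 2, colSums(tab), "/")
  bound <- cls$state != "unbound" & cls$n > 0
  inner <- grepl("^carb:inner", carbs)
  involve_all <- colMeans(part)
  involve_bound <- if (any(bound)) colMeans(part[bound, , drop = FALSE]) else
    rep(NA_real_, ncol(part))
  names(involve_all) <- names(involve_bound) <- carbs
  ring <- function(rows) {
    any_in <- rowSums(part[rows, inner, drop = FALSE]) > 0
    any_out <- rowSums(part[rows, !inner, drop = FALSE]) > 0
    c(inner = mean(any_in), outer = mean(any_out),
      both = mean(any_in & any_out))
  }
  list(state_fraction = frac,
       carb_involvement = rbind(all_frames = involve_all,
                                bound_frames = involve_bound),
       ring_involvement = rbind(all_frames = ring(seq_len(nrow(cls))),
                                bound_frames = if (any(bound)) ring(which(bound))
                                               else c(inner = NA, outer = NA,
                                                      both = NA)),
       ion_lys_fraction = mean(attr(cls, "ion_lys")))
}

#' Mean ion-ion distance at double occupancy
#'
#' Over frames with exactly two ions of the species inside the channel
#' region, the mean pairwise distance with a moving-block bootstrap SE.
#'
#' @param traj an \code{ion_trajectory}.
#' @param species ion species label.
#' @param channel_range channel region (A).
#' @param n_boot,block,seed bootstrap settings.
#' @return list with \code{mean}, \code{se}, \code{n_frames}.
#' @export
ion_ion_distance_stats <- function(traj, species, channel_range = c(-15, 15),
                                   n_boot = 200, block = 200, seed = 1) {
  geo <- frame_geometry(traj)
  ii <- geo$ion[geo$sp[geo$ion] == species]
  if (length(ii) < 2) stop("need at least two ions of species ", species)
  nf <- n_frames(traj)
  d <- rep(NA_real_, nf)
  for (t in seq_len(nf)) {
    X <- traj$coords[, , t]
    zref <- mean(X[geo$ref, 3])
    z <- X[ii, 3] - zref
    inch <- which(z > channel_range[1] & z < channel_range[2])
    if (length(inch) == 2)
      d[t] <- sqrt(sum((X[ii[inch[1]], ] - X[ii[inch[2]], ])^2))
  }
  d <- d[!is.na(d)]
  if (!length(d)) stop("no frames with two channel ions of species ", species)
  se <- 0
  if (n_boot > 0 && length(d) > 1) {
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b)
      mean(d[moving_block_indices(length(d), block)]), 0)
    se <- stats::sd(reps)
  }
  list(mean = mean(d), se = se, n_frames = length(d))
}

#' Coordination number
#'
#' Mean count of partner-role particles within a cutoff of each center-role
#' particle, optionally resolved along z.
#'
#' @param traj an \code{ion_trajectory}.
#' @param center_role,partner_role role patterns.
#' @param cutoff coordination cutoff (A), > 0.
#' @param z_edges optional z bin edges for a coordination-vs-z profile
#'   (center z relative to the scaffold reference).
#' @return list with \code{mean}, \code{se} (over per-frame means) and, with
#'   \code{z_edges}, a data.frame \code{profile} (z, n, count).
#' @export
coordination_number <- function(traj, center_role, partner_role, cutoff,
                                z_edges = NULL) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  ic <- match_roles(traj$roles, center_role)
  ip <- match_roles(traj$roles, partner_role)
  if (!length(ic) || !length(ip)) stop("empty selection")
  geo <- frame_geometry(traj)
  nf <- n_frames(traj)
  per_frame <- numeric(nf)
  if (!is.null(z_edges)) {
    zsum <- numeric(length(z_edges) - 1L)
    zcnt <- numeric(length(z_edges) - 1L)
  }
  for (t in seq_len(nf)) {
    X <- traj$coords[, , t]
    D <- sqrt(outer(X[ic, 1], X[ip, 1], "-")^2 +
              outer(X[ic, 2], X[ip, 2], "-")^2 +
              outer(X[ic, 3], X[ip, 3], "-")^2)
    D <- matrix(D, nrow = length(ic))
    self <- outer(ic, ip, "==")
    cnt <- rowSums(D < cutoff & !self)
    per_frame[t] <- mean(cnt)
    if (!is.null(z_edges)) {
      zref <- mean(X[geo$ref, 3])
      b <- findInterval(X[ic, 3] - zref, z_edges, rightmost.closed = TRUE)
      ok <- b >= 1 & b <= length(zsum)
      for (k in which(ok)) {
        zsum[b[k]] <- zsum[b[k]] + cnt[k]
        zcnt[b[k]] <- zcnt[b[k]] + 1
      }
    }
  }
  out <- list(mean = mean(per_frame),
              se = stats::sd(per_frame) / sqrt(max(nf, 1)))
  if (!is.null(z_edges))
    out$profile <- data.frame(z = z_edges[-length(z_edges)] + diff(z_edges) / 2,
                              n = ifelse(zcnt > 0, zsum / zcnt, NA),
                              count = zcnt)
  out
}

#' Coordination relative to a bulk value
#'
#' @param value coordination number(s) (scalar or profile data.frame from
#'   [coordination_number()]).
#' @param bulk_value bulk-solution coordination number.
#' @return ratio(s) n / n_bulk.
#' @export
relative_to_bulk <- function(value, bulk_value) {
  if (is.data.frame(value)) {
    value$ratio <- value$n / bulk_value
    value
  } else value / bulk_value
}
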