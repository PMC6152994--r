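#' Detect complete permeation events
#'
#' Two-plane hysteresis counting: an inward event is recorded when an ion
#' moves from above the upper plane to below the lower plane (and outward
#' for the reverse), so recrossings of a single plane are never counted. A
#' stride that jumps both planes between saved frames counts once. Events
#' are non-overlapping per ion.
#'
#' @param z either a frames x ions matrix of axial positions (columns named
#'   by ion id) or an \code{ion_trajectory} (ion z relative to the scaffold
#'   reference is extracted).
#' @param upper_plane,lower_plane crossing planes in z (A); upper > lower.
#' @param species with trajectory input, restrict to one species.
#' @return data.frame of class \code{permeation_events} with columns
#'   \code{ion}, \code{species}, \code{direction} ("inward"/"outward"),
#'   \code{entry_frame} (last frame on the originating side),
#'   \code{exit_frame} (first frame past the far plane); attribute
#'   \code{planes} records the plane definition.
#' @examples
#' z <- matrix(c(10, 5, 0, -5, -10), ncol = 1,
#'             dimnames = list(NULL, "ion:Na:1"))
#' detect_events(z, upper_plane = 2, lower_plane = -2)
#' @export
detect_events <- function(z, upper_plane, lower_plane, species = NULL) {
  if (upper_plane <= lower_plane)
    stop("upper_plane must be greater than lower_plane")
  if (inherits(z, "ion_trajectory")) {
    geo <- frame_geometry(z)
    ii <- geo$ion
    if (!is.null(species)) ii <- ii[geo$sp[ii] %in% species]
    zref <- vapply(seq_len(n_frames(z)),
                   function(t) mean(z$coords[geo$ref, 3, t]), 0)
    zm <- t(matrix(z$coords[ii, 3, ], nrow = length(ii))) - zref
    zm <- matrix(zm, ncol = length(ii))
    colnames(zm) <- z$roles[ii]
    z <- zm
  }
  if (is.null(colnames(z)))
    colnames(z) <- sprintf("ion:%d", seq_len(ncol(z)))
  ev <- list()
  for (j in seq_len(ncol(z))) {
    s <- z[, j]
    region <- ifelse(s > upper_plane, 1L, ifelse(s < lower_plane, -1L, 0L))
    side <- 0L          # last extreme region fully visited
    last_ext <- NA_integer_
    for (t in seq_along(s)) {
      r <- region[t]
      if (r == 0L) next
      if (side == 0L) { side <- r; last_ext <- t; next }
      if (r == side) { last_ext <- t; next }
      # completed transit side -> r
      ion_id <- colnames(z)[j]
      ev[[length(ev) + 1L]] <- data.frame(
        ion = ion_id,
        species = if (grepl("^ion:[^:]+:", ion_id))
          sub("^ion:([^:]+):.*$", "\\1", ion_id) else NA_character_,
        direction = if (side == 1L) "inward" else "outward",
        entry_frame = last_ext, exit_frame = t)
      side <- r
      last_ext <- t
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(ion = character(0), species = character(0),
               direction = character(0), entry_frame = integer(0),
               exit_frame = integer(0))
  out <- out[order(out$exit_frame), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("permeation_events", "data.frame"),
            planes = c(upper = upper_plane, lower = lower_plane))
}

#' Summarize permeation events
#'
#' @param events a \code{permeation_events} data.frame.
#' @param total_time_us trajectory length in microseconds (optional, for the
#'   event rate).
#' @return list with totals by direction and species, distinct-ion count,
#'   net flux (inward - outward) and, if \code{total_time_us} is given,
#'   events per microsecond.
#' @export
summarize_events <- function(events, total_time_us = NULL) {
  out <- list(
    total = nrow(events),
    inward = sum(events$direction == "inward"),
    outward = sum(events$direction == "outward"),
    by_species = if (nrow(events)) table(events$species) else table(character(0)),
    distinct_ions = length(unique(events$ion)),
    net_flux = sum(events$direction == "inward") -
               sum(events$direction == "outward"))
  if (!is.null(total_time_us))
    out$events_per_us <- out$total / total_time_us
  out
}

#' Default crossing planes around the lysine bead
#'
#' Crossing "past the lysine" is operationalized as planes a fixed offset
#' above and below the mean lysine bead position; for a channel without the
#' lysine (or for whole-filter counting) the channel boundaries are used.
#'
#' @param traj an \code{ion_trajectory}.
#' @param offset half-gap around the mean lysine z (A), default 4.
#' @param channel_range fallback planes when no lysine bead exists.
#' @return named numeric c(upper, lower).
#' @export
default_event_planes <- function(traj, offset = 4,
                                 channel_range = c(-15, 15)) {
  geo <- frame_geometry(traj)
  if (length(geo$lys)) {
    zref <- vapply(seq_len(n_frames(traj)),
                   function(t) mean(traj$coords[geo$ref, 3, t]), 0)
    zl <- mean(traj$coords[geo$lys[1], 3, ] - zref)
    c(upper = zl + offset, lower = zl - offset)
  } else c(upper = channel_range[2], lower = channel_range[1])
}
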