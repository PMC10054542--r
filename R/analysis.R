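#' @title Insertion analytics
#' @name analysis
#' @description
#' Observables of an inserted system: signed depth of the centroid,
#' tilt of a declared insertion vector against the local membrane
#' normal, roll about that vector, per-residue depth profiles, and
#' rigid energy scans along an axis.
NULL

.unit <- function(v) v / sqrt(sum(v^2))

#' Depth, tilt and roll of an inserted particle system
#'
#' Depth is the signed depth of the centroid; tilt is the angle between
#' the insertion vector (particle a to particle b) and the local
#' membrane normal, folded into [0, 90] degrees; roll is the signed
#' rotation about the insertion vector of a body-fixed marker (the
#' component of the centroid-to-a offset perpendicular to the insertion
#' vector) relative to the declared reference axis, in (-180, 180].
#'
#' @param ps a \code{particle_system}
#' @param membrane a \code{membrane} object
#' @param vector_pair particle ids (a, b) defining the insertion vector
#' @param reference_axis lab-frame axis whose projection defines zero
#'   roll (default +x)
#' @return list with \code{depth} (A), \code{tilt} (deg), \code{roll}
#'   (deg)
#' @export
insertion_metrics <- function(ps, membrane, vector_pair,
                              reference_axis = c(1, 0, 0)) {
  a <- ps_coords(ps)[match(vector_pair[1], ps$id), ]
  b <- ps_coords(ps)[match(vector_pair[2], ps$id), ]
  if (anyNA(a) || anyNA(b)) stop("vector_pair particle id not found")
  v <- b - a
  if (sqrt(sum(v^2)) < 1e-9)
    stop("degenerate insertion vector (coincident particles)")
  v <- .unit(v)
  com <- ps_center(ps)
  d <- membrane_depth(membrane, matrix(com, 1, 3))
  nrm <- d$normal[1, ]
  cosang <- abs(sum(v * nrm))
  tilt <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # roll: angle from the reference-axis projection to the body marker
  # projection, about v (right-hand rule)
  ref_p <- reference_axis - v * sum(reference_axis * v)
  marker <- (a - com) - v * sum((a - com) * v)
  roll <- NA_real_
  if (sqrt(sum(ref_p^2)) > 1e-9 && sqrt(sum(marker^2)) > 1e-9) {
    ref_p <- .unit(ref_p); marker_u <- .unit(marker)
    s_ <- sum(v * c(ref_p[2] * marker_u[3] - ref_p[3] * marker_u[2],
                    ref_p[3] * marker_u[1] - ref_p[1] * marker_u[3],
                    ref_p[1] * marker_u[2] - ref_p[2] * marker_u[1]))
    c_ <- sum(ref_p * marker_u)
    roll <- atan2(s_, c_) * 180 / pi
    if (roll <= -180) roll <- roll + 360
  }
  list(depth = d$z, tilt = tilt, roll = roll)
}

#' Per-residue depth profile
#'
#' For a static system, the per-residue mean signed depth of its
#' particles; for a list of systems (trajectory frames), the
#' per-residue mean over frames.  An optional reference profile (named
#' by residue number) adds per-residue deviations.
#'
#' @param ps a \code{particle_system} or a list of them (frames)
#' @param membrane a \code{membrane} object
#' @param selection residue numbers to include (default: all)
#' @param reference optional numeric vector of reference depths named
#'   by residue number
#' @return data frame (resno, depth, and with a reference: reference,
#'   deviation)
#' @export
depth_profile <- function(ps, membrane, selection = NULL,
                          reference = NULL) {
  frames <- if (inherits(ps, "particle_system")) list(ps) else ps
  if (length(frames) == 0L) stop("empty frame window")
  resnos <- sort(unique(frames[[1]]$resno))
  if (!is.null(selection)) resnos <- intersect(resnos, selection)
  if (length(resnos) == 0L) stop("empty residue selection")
  acc <- stats::setNames(numeric(length(resnos)), resnos)
  for (fr in frames) {
    d <- membrane_depth(membrane, ps_coords(fr))$z
    md <- tapply(d, fr$resno, mean)
    acc <- acc + md[as.character(resnos)]
  }
  out <- data.frame(resno = resnos, depth = unname(acc) / length(frames))
  if (!is.null(reference)) {
    out$reference <- unname(reference[as.character(resnos)])
    out$deviation <- out$depth - out$reference
  }
  out
}

#' Rigid energy scan along an axis
#'
#' Translates the system rigidly so its centroid visits each coordinate
#' along the axis and tabulates the energy breakdown.
#'
#' @param ps a \code{particle_system}
#' @param membrane a \code{membrane} object
#' @param axis length-3 direction (default +z, the planar membrane
#'   normal)
#' @param range scan range for the centroid coordinate along the axis
#'   (A)
#' @param step scan step (A)
#' @return data frame (coordinate, e_int, e_lip, e_imp)
#' @export
energy_scan <- function(ps, membrane, axis = c(0, 0, 1),
                        range = c(-40, 40), step = 1) {
  stopifnot(length(range) == 2L, range[2] > range[1], step > 0)
  axis <- .unit(axis)
  coords <- seq(range[1], range[2], by = step)
  com0 <- ps_center(ps)
  proj0 <- sum(com0 * axis)
  out <- data.frame(coordinate = coords, e_int = NA_real_,
                    e_lip = NA_real_, e_imp = NA_real_)
  for (k in seq_along(coords)) {
    shifted <- ps_translate(ps, axis * (coords[k] - proj0))
    e <- total_energy(shifted, membrane)
    out$e_int[k] <- e$e_int; out$e_lip[k] <- e$e_lip
    out$e_imp[k] <- e$e_imp
  }
  out
}
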