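#' @title Particle systems
#' @name particle-system
#' @description
#' A particle system is the package's container for a structure at any
#' representation scale: all-atom, coarse-grained beads, or one bead per
#' residue.  It is a data frame with one row per particle and columns
#' \code{id}, \code{chain}, \code{resname}, \code{resno}, \code{name},
#' \code{x}, \code{y}, \code{z}, \code{radius}, \code{sasa},
#' \code{type}, \code{etr} (transfer energy per area, kcal mol^-1 A^-2)
#' and \code{sidechain}; the representation label is kept as an
#' attribute.
NULL

#' Construct a particle system
#'
#' @param df data frame with at least \code{resname}, \code{resno},
#'   \code{name}, \code{x}, \code{y}, \code{z}; missing annotation
#'   columns are filled with defaults
#' @param representation one of \code{"all-atom"}, \code{"cg-bead"},
#'   \code{"one-bead"}
#' @return an object of class \code{particle_system}
#' @export
particle_system <- function(df, representation = c("all-atom", "cg-bead",
                                                   "one-bead")) {
  representation <- match.arg(representation)
  stopifnot(is.data.frame(df))
  need <- c("resname", "resno", "name", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing particle columns: ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  if (is.null(df$chain)) df$chain <- "A"
  if (is.null(df$radius)) df$radius <- NA_real_
  if (is.null(df$sasa)) df$sasa <- NA_real_
  if (is.null(df$type)) df$type <- NA_character_
  if (is.null(df$etr)) df$etr <- NA_real_
  if (is.null(df$sidechain)) df$sidechain <- TRUE
  df$id <- seq_len(n)
  if (any(!is.na(df$radius) & df$radius <= 0))
    stop("particle radii must be positive")
  if (any(!is.na(df$sasa) & df$sasa < 0))
    stop("particle SASA must be non-negative")
  df <- df[c("id", "chain", "resname", "resno", "name", "x", "y", "z",
             "radius", "sasa", "type", "etr", "sidechain")]
  structure(df, class = c("particle_system", "data.frame"),
            representation = representation)
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("Particle system: %d particles, %d residues [%s]\n",
              nrow(x), length(unique(paste(x$chain, x$resno))),
              attr(x, "representation")))
  invisible(x)
}

#' Representation scale of a particle system
#' @param ps a \code{particle_system}
#' @return \code{"all-atom"}, \code{"cg-bead"} or \code{"one-bead"}
#' @export
representation <- function(ps) attr(ps, "representation")

#' Particle coordinates as an n x 3 matrix
#' @param ps a \code{particle_system}
#' @return numeric matrix with columns x, y, z
#' @export
ps_coords <- function(ps) {
  cbind(x = ps$x, y = ps$y, z = ps$z)
}

#' Replace particle coordinates
#' @param ps a \code{particle_system}
#' @param xyz n x 3 coordinate matrix
#' @return the updated system
#' @export
ps_set_coords <- function(ps, xyz) {
  stopifnot(nrow(xyz) == nrow(ps), ncol(xyz) == 3L)
  ps$x <- xyz[, 1]; ps$y <- xyz[, 2]; ps$z <- xyz[, 3]
  ps
}

#' Centre of mass (unweighted centroid) of a particle system
#' @param ps a \code{particle_system}
#' @return length-3 numeric vector
#' @export
ps_center <- function(ps) colMeans(ps_coords(ps))

#' Rigidly translate a particle system
#' @param ps a \code{particle_system}
#' @param shift length-3 translation vector (Angstrom)
#' @return the translated system
#' @export
ps_translate <- function(ps, shift) {
  stopifnot(length(shift) == 3L)
  ps$x <- ps$x + shift[1]; ps$y <- ps$y + shift[2]; ps$z <- ps$z + shift[3]
  ps
}

#' Rigidly rotate a particle system about a pivot
#' @param ps a \code{particle_system}
#' @param R 3 x 3 rotation matrix
#' @param pivot rotation centre (default: centroid)
#' @return the rotated system
#' @export
ps_rotate <- function(ps, R, pivot = ps_center(ps)) {
  xyz <- sweep(ps_coords(ps), 2, pivot)
  xyz <- xyz %*% t(R)
  ps_set_coords(ps, sweep(xyz, 2, pivot, `+`))
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis vector (need not be unit)
#' @param angle_deg rotation angle in degrees
#' @return 3 x 3 rotation matrix
#' @export
rotation_matrix <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  c_ <- cos(th); s_ <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * (u %o% u)
}
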