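#' @title Insertion energy model
#' @name energy
#' @description
#' The membrane is a continuum field C(z) of the signed depth z,
#' interpolating between +0.5 in bulk water and -0.5 in the hydrocarbon
#' core across the headgroup region:
#' \deqn{C(z) = 0.5 - (1 + \exp(\alpha(|z| - z_0)))^{-1}}
#' The insertion energy of a structure is
#' \deqn{E_{imp} = E_{int} + E_{lip}}
#' with the interaction term \eqn{E_{int} = -\sum_i S_i E_{tr,i} C(z_i)}
#' (per-area transfer energies weighted by exposed surface) and the
#' lipid perturbation term \eqn{E_{lip} = a_{lip} \sum_i S_i C(z_i)}.
#' How a particle's signed depth z_i is obtained is pluggable: analytic
#' planar frame, analytic double membrane, or signed distance to a
#' triangulated mesh.
NULL

#' Sigmoidal membrane profile C(z)
#'
#' Even in z, bounded in (-0.5, 0.5); C(z0) = 0 exactly; approaches
#' -0.5 in the core (z = 0) and +0.5 in bulk water.  Exponent overflow
#' saturates to the asymptotes.
#'
#' @param z signed depth(s), Angstrom
#' @param geom a \code{membrane_geometry}
#' @return profile value(s) in (-0.5, 0.5)
#' @export
#' @examples
#' membrane_profile(c(0, 15.75, 40), membrane_geometry())
membrane_profile <- function(z, geom) {
  stopifnot(inherits(geom, "membrane_geometry"))
  ex <- geom$alpha * (abs(z) - geom$z0)
  ex <- pmin(ex, 700)  # exp overflow guard; sigmoid saturated anyway
  0.5 - 1 / (1 + exp(ex))
}

#' Derivative dC/dz of the membrane profile
#'
#' \code{sign(0)} is taken as 0, so the force vanishes exactly at the
#' midplane kink.
#'
#' @inheritParams membrane_profile
#' @return derivative value(s) (per Angstrom)
#' @export
membrane_profile_deriv <- function(z, geom) {
  stopifnot(inherits(geom, "membrane_geometry"))
  ex <- geom$alpha * (abs(z) - geom$z0)
  ex <- pmin(ex, 350)
  e <- exp(ex)
  sign(z) * geom$alpha * e / (1 + e)^2
}

# ---------------------------------------------------------------------
# Membrane objects: pluggable depth + profile providers
# ---------------------------------------------------------------------

#' Planar implicit membrane
#'
#' Midplane at z = 0; a particle's signed depth is its z coordinate and
#' the local normal is +z everywhere.
#'
#' @param geom a \code{membrane_geometry}
#' @return an object of classes \code{planar_membrane}, \code{membrane}
#' @export
planar_membrane <- function(geom = membrane_geometry()) {
  stopifnot(inherits(geom, "membrane_geometry"))
  structure(list(geom = geom), class = c("planar_membrane", "membrane"))
}

#' Signed depth and local normal of points in a membrane frame
#'
#' @param membrane a \code{membrane} object
#' @param xyz n x 3 coordinate matrix (a length-3 vector is accepted)
#' @return list with \code{z} (signed depths, Angstrom) and
#'   \code{normal} (n x 3 unit normals)
#' @export
membrane_depth <- function(membrane, xyz) UseMethod("membrane_depth")

#' @export
membrane_depth.planar_membrane <- function(membrane, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  list(z = xyz[, 3],
       normal = matrix(rep(c(0, 0, 1), each = n), n, 3))
}

#' Membrane profile value at given signed depth(s)
#' @param membrane a \code{membrane} object
#' @param z signed depth(s), Angstrom
#' @return profile value(s)
#' @export
profile_at <- function(membrane, z) UseMethod("profile_at")

#' @export
profile_at.membrane <- function(membrane, z) {
  membrane_profile(z, membrane$geom)
}

#' Derivative of the membrane profile at given signed depth(s)
#' @inheritParams profile_at
#' @return derivative value(s)
#' @export
profile_deriv_at <- function(membrane, z) UseMethod("profile_deriv_at")

#' @export
profile_deriv_at.membrane <- function(membrane, z) {
  membrane_profile_deriv(z, membrane$geom)
}

#' Geometry carried by a membrane object
#' @param membrane a \code{membrane} object
#' @return the \code{membrane_geometry}
#' @export
membrane_geom <- function(membrane) membrane$geom

# profile values for each particle; checks annotations
.particle_profile <- function(ps, membrane, need_etr = TRUE) {
  if (anyNA(ps$sasa)) {
    i <- which(is.na(ps$sasa))[1]
    stop(sprintf("particle %d (%s %s %s) has no SASA; run compute_sasa() or set areas",
                 ps$id[i], ps$resname[i], ps$resno[i], ps$name[i]))
  }
  if (need_etr && anyNA(ps$etr)) {
    i <- which(is.na(ps$etr))[1]
    stop(sprintf("particle %d (%s %s %s) has no transfer energy; run assign_atom_types()",
                 ps$id[i], ps$resname[i], ps$resno[i], ps$name[i]))
  }
  d <- membrane_depth(membrane, ps_coords(ps))
  list(C = profile_at(membrane, d$z), depth = d)
}

#' Interaction (transfer) energy of a particle system
#'
#' \eqn{E_{int} = -\sum_i S_i E_{tr,i} C(z_i)} in kcal/mol.
#'
#' @param ps a \code{particle_system} with \code{sasa} and \code{etr}
#' @param membrane a \code{membrane} object
#' @return energy in kcal/mol
#' @export
interaction_energy <- function(ps, membrane) {
  if (nrow(ps) == 0L) return(0)
  pp <- .particle_profile(ps, membrane)
  -sum(ps$sasa * ps$etr * pp$C)
}

#' Lipid perturbation energy of a particle system
#'
#' \eqn{E_{lip} = a_{lip} \sum_i S_i C(z_i)} in kcal/mol.
#'
#' @inheritParams interaction_energy
#' @return energy in kcal/mol
#' @export
lipid_perturbation_energy <- function(ps, membrane) {
  if (nrow(ps) == 0L) return(0)
  pp <- .particle_profile(ps, membrane, need_etr = FALSE)
  membrane_geom(membrane)$a_lip * sum(ps$sasa * pp$C)
}

#' Total insertion energy breakdown
#'
#' @inheritParams interaction_energy
#' @return an \code{energy_breakdown}: list with \code{e_int},
#'   \code{e_lip} and \code{e_imp = e_int + e_lip} (kcal/mol)
#' @export
total_energy <- function(ps, membrane) {
  if (nrow(ps) == 0L) {
    return(structure(list(e_int = 0, e_lip = 0, e_imp = 0),
                     class = "energy_breakdown"))
  }
  pp <- .particle_profile(ps, membrane)
  e_int <- -sum(ps$sasa * ps$etr * pp$C)
  e_lip <- membrane_geom(membrane)$a_lip * sum(ps$sasa * pp$C)
  structure(list(e_int = e_int, e_lip = e_lip, e_imp = e_int + e_lip),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("E_int = %.4f  E_lip = %.4f  E_imp = %.4f kcal/mol\n",
              x$e_int, x$e_lip, x$e_imp))
  invisible(x)
}

#' Per-particle membrane forces
#'
#' The force on particle i is \eqn{-dE_{imp}/dz_i} directed along the
#' local membrane normal, with
#' \eqn{dE_{imp}/dz_i = (a_{lip} - E_{tr,i}) S_i \, dC/dz|_{z_i}}.
#'
#' @inheritParams interaction_energy
#' @return n x 3 matrix of force vectors (kcal mol^-1 A^-1)
#' @export
energy_gradient <- function(ps, membrane) {
  pp <- .particle_profile(ps, membrane)
  dC <- profile_deriv_at(membrane, pp$depth$z)
  dEdz <- (membrane_geom(membrane)$a_lip - ps$etr) * ps$sasa * dC
  -dEdz * pp$depth$normal
}

#' Predicted transfer energy of a residue conformation
#'
#' Centres the side-chain centroid at the bilayer midplane (z = 0) and
#' evaluates the insertion energy over the side-chain particles only.
#' This is the quantity calibrated against a reference hydrophobicity
#' scale.  For one-bead systems the single bead is the side chain.
#'
#' @param ps a \code{particle_system} for a single residue, typed and
#'   with SASA
#' @param geom a \code{membrane_geometry}
#' @param center if TRUE (default), translate so the side-chain centroid
#'   sits at z = 0
#' @return predicted transfer energy (kcal/mol); 0 with a warning when
#'   the residue has no side-chain particles
#' @export
predict_transfer_energy <- function(ps, geom = membrane_geometry(),
                                    center = TRUE) {
  sc <- ps[ps$sidechain, , drop = FALSE]
  if (nrow(sc) == 0L) {
    warning("residue has no side-chain particles; transfer energy is 0")
    return(0)
  }
  if (center) {
    ctr <- colMeans(ps_coords(sc))
    sc <- ps_translate(sc, -ctr)
  }
  if (sum(sc$sasa, na.rm = TRUE) == 0) return(0)
  total_energy(sc, planar_membrane(geom))$e_imp
}
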