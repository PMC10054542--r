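#' @title Elastic network model
#' @name enm
#' @description
#' Harmonic springs between every unique particle pair within a
#' distance cutoff (default 9 Angstrom), rest lengths set to the build
#' geometry, energy \eqn{\sum \frac{1}{2} k (d - d_0)^2}, analytic
#' forces.  No non-bonded terms.
NULL

#' Build an elastic network over a particle system
#'
#' @param ps a \code{particle_system}
#' @param cutoff spring cutoff distance (Angstrom, default 9)
#' @param stiffness spring constant k (kcal mol^-1 A^-2, default 1)
#' @return an object of class \code{elastic_network}: data frame of
#'   springs (i, j, rest, k) with the cutoff as an attribute
#' @export
build_enm <- function(ps, cutoff = 9, stiffness = 1) {
  xyz <- ps_coords(ps)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  springs <- data.frame(i = idx[, 1], j = idx[, 2],
                        rest = d[idx], k = stiffness)
  structure(springs, class = c("elastic_network", "data.frame"),
            cutoff = cutoff)
}

#' Elastic network energy at given coordinates
#' @param enm an \code{elastic_network}
#' @param xyz n x 3 coordinate matrix
#' @return energy in kcal/mol
#' @export
enm_energy <- function(enm, xyz) {
  if (nrow(enm) == 0L) return(0)
  dv <- xyz[enm$i, , drop = FALSE] - xyz[enm$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  sum(0.5 * enm$k * (d - enm$rest)^2)
}

#' Elastic network forces at given coordinates
#' @inheritParams enm_energy
#' @return n x 3 matrix of forces (kcal mol^-1 A^-1)
#' @export
enm_forces <- function(enm, xyz) {
  f <- matrix(0, nrow(xyz), 3)
  if (nrow(enm) == 0L) return(f)
  dv <- xyz[enm$i, , drop = FALSE] - xyz[enm$j, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  d[d < 1e-12] <- 1e-12
  # force on i along -(d - rest) * unit(i - j)
  fij <- -enm$k * (d - enm$rest) / d * dv
  for (c_ in 1:3) {
    f[, c_] <- f[, c_] + tabulate_weighted(enm$i, fij[, c_], nrow(xyz)) -
      tabulate_weighted(enm$j, fij[, c_], nrow(xyz))
  }
  f
}
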