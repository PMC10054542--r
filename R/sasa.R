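#' @title Solvent-accessible surface area
#' @name sasa
#' @description
#' Numerical per-particle SASA in the Shrake-Rupley style: a fixed
#' deterministic point set (golden-spiral distribution) is placed on
#' each particle's solvent-expanded sphere and points occluded by any
#' neighbouring expanded sphere are discarded.  The deterministic point
#' set makes calibration reproducible bit-for-bit.
NULL

# golden-spiral (Fibonacci) unit sphere points; deterministic
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Compute per-particle SASA
#'
#' @param ps a \code{particle_system} with radii set
#' @param probe_radius probe sphere radius (Angstrom, default 1.4)
#' @param n_points test points per particle (default 960)
#' @return the system with the \code{sasa} column filled (Angstrom^2)
#' @export
#' @examples
#' one <- particle_system(data.frame(resname = "X", resno = 1, name = "C",
#'                                   x = 0, y = 0, z = 0, radius = 1.7))
#' compute_sasa(one)$sasa  # ~ 4*pi*(1.7+1.4)^2
compute_sasa <- function(ps, probe_radius = 1.4, n_points = 960) {
  n <- nrow(ps)
  if (n == 0L) stop("cannot compute SASA of an empty system")
  if (anyNA(ps$radius)) stop("all particles need radii before SASA")
  pts <- .sphere_points(n_points)
  xyz <- ps_coords(ps)
  rr <- ps$radius + probe_radius
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded spheres can occlude points on sphere i
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    test <- pts * rr[i]
    test <- sweep(test, 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- (test[exposed, 1] - xyz[j, 1])^2 +
        (test[exposed, 2] - xyz[j, 2])^2 +
        (test[exposed, 3] - xyz[j, 3])^2
      exposed[exposed] <- dj2 >= rr[j]^2
    }
    sasa[i] <- 4 * pi * rr[i]^2 * sum(exposed) / n_points
  }
  ps$sasa <- sasa
  ps
}
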