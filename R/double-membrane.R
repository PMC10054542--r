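#' @title Analytic double membranes
#' @name double-membrane
#' @description
#' Two parallel implicit bilayers at tunable separation m are described
#' analytically by
#' \deqn{C_{double}(z) = C_{main}(z) + C_{side}(z) C_{side}(-z)}
#' where \eqn{C_{main}(z) = 0.5 - (1+\exp(\alpha(|z| - (m + z_0))))^{-1}}
#' widens the single-membrane profile by m and
#' \eqn{C_{side}(z) = 1 - (1+\exp(\alpha((z + m) - z_0)))^{-1}}
#' carves the aqueous gap between the two bilayers.  At m = 0 the
#' profile reduces to the single membrane; as m grows the two bilayers
#' first merge and then separate with a bulk-water plateau between
#' them.
NULL

.clamp_exp <- function(x) exp(pmin(x, 700))

#' Construct a double-membrane profile provider
#'
#' The midplane of the double system is z = 0; each bilayer midplane
#' sits near +/- m.  The object exposes the same depth/profile contract
#' as \code{\link{planar_membrane}}, so all energy, force and sampling
#' machinery applies unchanged.
#'
#' @param geom a \code{membrane_geometry}
#' @param m separation parameter (Angstrom, >= 0)
#' @return an object of classes \code{double_membrane}, \code{membrane}
#' @export
double_membrane <- function(geom = membrane_geometry(), m = 0) {
  stopifnot(inherits(geom, "membrane_geometry"))
  if (!(is.numeric(m) && length(m) == 1L && m >= 0))
    stop("separation m must be a single non-negative number")
  structure(list(geom = geom, m = m),
            class = c("double_membrane", "membrane"))
}

#' Double-membrane profile C_double(z)
#'
#' @param z signed depth(s), Angstrom
#' @param dm a \code{double_membrane} (or a \code{membrane_geometry}
#'   together with \code{m})
#' @param m separation, used when \code{dm} is a geometry
#' @return profile value(s); even in z, within [-0.5, 0.5] up to
#'   exponentially small excess
#' @export
#' @examples
#' dm <- double_membrane(membrane_geometry(), m = 18)
#' double_profile(0, dm)   # aqueous gap forming between the bilayers
double_profile <- function(z, dm, m = NULL) {
  if (inherits(dm, "membrane_geometry")) dm <- double_membrane(dm, m)
  stopifnot(inherits(dm, "double_membrane"))
  g <- dm$geom; m <- dm$m
  c_main <- 0.5 - 1 / (1 + .clamp_exp(g$alpha * (abs(z) - (m + g$z0))))
  c_side <- function(zz) 1 - 1 / (1 + .clamp_exp(g$alpha * ((zz + m) - g$z0)))
  c_main + c_side(z) * c_side(-z)
}

#' Derivative of the double-membrane profile
#' @inheritParams double_profile
#' @return dC_double/dz
#' @export
double_profile_deriv <- function(z, dm, m = NULL) {
  if (inherits(dm, "membrane_geometry")) dm <- double_membrane(dm, m)
  g <- dm$geom; m <- dm$m
  e_main <- .clamp_exp(g$alpha * (abs(z) - (m + g$z0)))
  d_main <- sign(z) * g$alpha * e_main / (1 + e_main)^2
  cs <- function(zz) 1 - 1 / (1 + .clamp_exp(g$alpha * ((zz + m) - g$z0)))
  dcs <- function(zz) {
    e <- .clamp_exp(g$alpha * ((zz + m) - g$z0))
    g$alpha * e / (1 + e)^2
  }
  d_main + dcs(z) * cs(-z) - cs(z) * dcs(-z)
}

#' @export
membrane_depth.double_membrane <- function(membrane, xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  list(z = xyz[, 3],
       normal = matrix(rep(c(0, 0, 1), each = n), n, 3))
}

#' @export
profile_at.double_membrane <- function(membrane, z) {
  double_profile(z, membrane)
}

#' @export
profile_deriv_at.double_membrane <- function(membrane, z) {
  double_profile_deriv(z, membrane)
}

#' Classify the regime of a double membrane at separation m
#'
#' The two bilayers are \code{"fused"} into one for
#' m <= z0 - beta/2, \code{"merging"} for
#' z0 - beta/2 < m <= z0 + beta/2, and \code{"separated"} (aqueous gap
#' formed) for m > z0 + beta/2.  With the default geometry the two
#' thresholds are 13.5 and 18 Angstrom.
#'
#' @param m separation (Angstrom, >= 0)
#' @param geom a \code{membrane_geometry}
#' @return one of \code{"fused"}, \code{"merging"}, \code{"separated"}
#' @export
classify_regime <- function(m, geom = membrane_geometry()) {
  stopifnot(m >= 0)
  lo <- geom$z0 - geom$beta / 2
  hi <- geom$z0 + geom$beta / 2
  if (m <= lo) "fused" else if (m <= hi) "merging" else "separated"
}

#' Regime thresholds of a geometry
#' @param geom a \code{membrane_geometry}
#' @return named numeric vector with \code{fused_to_merging} and
#'   \code{merging_to_separated} separations (Angstrom)
#' @export
regime_thresholds <- function(geom = membrane_geometry()) {
  c(fused_to_merging = geom$z0 - geom$beta / 2,
    merging_to_separated = geom$z0 + geom$beta / 2)
}

#' Update the separation of a double membrane
#'
#' Stateless: the returned object's profile reflects the new separation
#' immediately, supporting programmatic sweeps of m.
#'
#' @param dm a \code{double_membrane}
#' @param m_new new separation (Angstrom, >= 0)
#' @return the updated \code{double_membrane}
#' @export
set_separation <- function(dm, m_new) {
  stopifnot(inherits(dm, "double_membrane"))
  double_membrane(dm$geom, m_new)
}
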