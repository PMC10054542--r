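#' @title Lipid bilayer structural parameterization
#' @name membrane-params
#' @description
#' An implicit bilayer is described by four numbers: the steepness
#' \code{alpha} of the water/core interface, the distance \code{z0} from
#' the midplane to the centre of the headgroup region, the width
#' \code{beta} of that region, and the per-area lipid perturbation
#' coefficient \code{a_lip}. The geometric triple (alpha, z0, beta) can
#' be derived from two experimentally measurable thicknesses of a lipid
#' bilayer: the hydrocarbon thickness 2D_C (acyl core) and the steric
#' thickness D_B' (full bilayer width).
NULL

# alpha * beta is pinned so the sigmoid spans its transition over one
# headgroup width: exp(alpha * beta / 2) = SIGMOID_SPAN.  The default
# geometry (alpha = 1.99, beta = 4.5) encodes exactly this pairing.
SIGMOID_SPAN <- 88.0145

# kcal <-> kJ
CAL_TO_JOULE <- 4.184

#' Construct an implicit membrane geometry
#'
#' @param alpha interface steepness (dimensionless as used; controls the
#'   sigmoid slope per Angstrom of depth)
#' @param z0 distance from the bilayer midplane to the centre of the
#'   headgroup region (Angstrom)
#' @param beta width of the headgroup region (Angstrom)
#' @param a_lip lipid perturbation coefficient (kcal mol^-1 A^-2)
#' @param label free-text label (typically the lipid name)
#' @return an object of class \code{membrane_geometry}
#' @export
#' @examples
#' membrane_geometry()  # the default (DOPC-like) geometry
membrane_geometry <- function(alpha = 1.99, z0 = 15.75, beta = 4.5,
                              a_lip = -0.018, label = "default") {
  stopifnot(is.numeric(alpha), is.numeric(z0), is.numeric(beta),
            length(alpha) == 1L, length(z0) == 1L, length(beta) == 1L)
  if (!(alpha > 0)) stop("alpha must be > 0")
  if (!(z0 > 0)) stop("z0 must be > 0")
  if (!(beta > 0)) stop("beta must be > 0")
  structure(list(alpha = alpha, z0 = z0, beta = beta,
                 a_lip = a_lip, label = label),
            class = "membrane_geometry")
}

#' @export
print.membrane_geometry <- function(x, ...) {
  cat(sprintf("Implicit membrane geometry [%s]\n", x$label))
  cat(sprintf("  alpha = %.4f   z0 = %.2f A   beta = %.2f A   a_lip = %.4f kcal/mol/A^2\n",
              x$alpha, x$z0, x$beta, x$a_lip))
  invisible(x)
}

#' Lipid structural thickness parameters
#'
#' @param hydrocarbon_thickness acyl-core thickness 2D_C (Angstrom)
#' @param steric_thickness full steric bilayer thickness D_B' (Angstrom)
#' @param temperature temperature in degrees C (metadata only)
#' @return an object of class \code{lipid_params}
#' @export
lipid_params <- function(hydrocarbon_thickness, steric_thickness,
                         temperature = NA_real_) {
  if (!(hydrocarbon_thickness > 0))
    stop("hydrocarbon thickness must be positive")
  if (!(steric_thickness > hydrocarbon_thickness))
    stop("steric thickness must exceed the hydrocarbon thickness ",
         "(the headgroup region would have non-positive width)")
  structure(list(hydrocarbon_thickness = hydrocarbon_thickness,
                 steric_thickness = steric_thickness,
                 temperature = temperature),
            class = "lipid_params")
}

#' Derive an implicit membrane geometry from bilayer thicknesses
#'
#' Computes the headgroup width \code{beta = (DB' - 2DC)/2}, the
#' headgroup centre \code{z0 = (DB' - beta)/2} and the steepness
#' \code{alpha = 2 ln(88.0145)/beta}.  All downstream values use the
#' unrounded \code{beta}.
#'
#' @param lipid a \code{lipid_params} object, or the hydrocarbon
#'   thickness 2D_C in Angstrom (with \code{steric_thickness} given)
#' @param steric_thickness steric thickness D_B' (Angstrom), when
#'   \code{lipid} is given numerically
#' @param a_lip lipid perturbation coefficient carried into the geometry
#' @param label label carried into the geometry
#' @return a \code{membrane_geometry}
#' @export
#' @examples
#' derive_geometry(27.1, 35.9, label = "DOPC")   # beta 4.4, z0 15.75
derive_geometry <- function(lipid, steric_thickness = NULL,
                            a_lip = -0.018, label = "derived") {
  if (is.numeric(lipid)) {
    lipid <- lipid_params(lipid, steric_thickness)
  }
  stopifnot(inherits(lipid, "lipid_params"))
  beta <- (lipid$steric_thickness - lipid$hydrocarbon_thickness) / 2
  if (!(beta > 0)) stop("invalid lipid: derived headgroup width is non-positive")
  z0 <- (lipid$steric_thickness - beta) / 2
  alpha <- 2 * log(SIGMOID_SPAN) / beta
  membrane_geometry(alpha = alpha, z0 = z0, beta = beta,
                    a_lip = a_lip, label = label)
}

# Printed structural thicknesses (Angstrom) for common phospholipids.
# Temperature in degrees C.
.lipid_presets <- list(
  DLPG = list(twoDC = 20.7, DBp = 35.3, temp = 20),
  DOPC = list(twoDC = 27.1, DBp = 35.9, temp = 30),
  DMPC = list(twoDC = 26.2, DBp = 36.9, temp = 30),
  DLPE = list(twoDC = 30.0, DBp = 42.1, temp = 20),
  DOPG = list(twoDC = 27.9, DBp = 42.8, temp = 20),
  POPG = list(twoDC = 28.3, DBp = 44.0, temp = 20),
  DPPC = list(twoDC = 34.4, DBp = 47.8, temp = 20)
)

#' Preset membrane geometries for common lipids
#'
#' \code{"default"} returns the canonical geometry (alpha 1.99,
#' z0 15.75 A, beta 4.5 A, a_lip -0.018) corresponding to a theoretical
#' 36 A bilayer with a 27 A acyl core; the lipid names return geometries
#' derived from published hydrocarbon/steric thicknesses.
#'
#' @param name one of \code{"default"}, \code{"DLPG"}, \code{"DOPC"},
#'   \code{"DMPC"}, \code{"DLPE"}, \code{"DOPG"}, \code{"POPG"},
#'   \code{"DPPC"} (case-insensitive)
#' @param a_lip perturbation coefficient carried into the geometry
#' @return a \code{membrane_geometry}
#' @export
#' @examples
#' get_preset("DPPC")$z0    # 20.55
get_preset <- function(name, a_lip = -0.018) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- toupper(name)
  if (key == "DEFAULT") {
    return(membrane_geometry(a_lip = a_lip, label = "default"))
  }
  if (!key %in% names(.lipid_presets)) {
    stop(sprintf("unknown lipid preset '%s'; available: %s",
                 name, paste(c(names(.lipid_presets), "default"),
                             collapse = ", ")))
  }
  p <- .lipid_presets[[key]]
  derive_geometry(lipid_params(p$twoDC, p$DBp, p$temp),
                  a_lip = a_lip, label = key)
}

#' Names of the available lipid presets
#' @return character vector of preset names
#' @export
list_presets <- function() c(names(.lipid_presets), "default")

#' Convert energies between kcal/mol and kJ/mol
#'
#' Also accepts the per-area variants (\code{"kcal/mol/A^2"},
#' \code{"kJ/mol/A^2"}); the per-area dimension must match on both
#' sides.
#'
#' @param value numeric energy value(s)
#' @param from,to unit strings
#' @return converted numeric value(s)
#' @export
convert_energy <- function(value, from, to) {
  norm <- function(u) {
    u <- gsub("\\s", "", tolower(u))
    u <- sub("mol-1", "/mol", u, fixed = TRUE)
    per_area <- grepl("a\\^?-?2|ang", u)
    base <- if (grepl("^kcal", u)) "kcal" else if (grepl("^kj", u)) "kj" else
      stop(sprintf("unrecognised energy unit '%s'", u))
    list(base = base, per_area = per_area)
  }
  uf <- norm(from); ut <- norm(to)
  if (uf$per_area != ut$per_area)
    stop("unit dimension mismatch: cannot convert between molar and per-area energies")
  if (uf$base == ut$base) return(value)
  if (uf$base == "kcal") value * CAL_TO_JOULE else value / CAL_TO_JOULE
}
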