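#' @title Hydrophobicity scales
#' @name scales
#' @description
#' A hydrophobicity scale maps each residue to a water-to-membrane
#' transfer free energy.  The sign convention throughout the package is
#' negative = hydrophobic (membrane-favouring), positive = hydrophilic.
NULL

.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

#' The 20 standard residue names
#' @return character vector of three-letter residue codes
#' @export
standard_residues <- function() .aa3

#' Construct a hydrophobicity scale
#'
#' @param values named numeric vector, names are residue identifiers
#'   (three-letter codes for protein scales)
#' @param name text label for the scale
#' @param units \code{"kcal/mol"} or \code{"kJ/mol"}
#' @return an object of class \code{hydrophobicity_scale}
#' @export
hydrophobicity_scale <- function(values, name = "user",
                                 units = c("kcal/mol", "kJ/mol")) {
  units <- match.arg(units)
  stopifnot(is.numeric(values), !is.null(names(values)))
  if (anyDuplicated(names(values)))
    stop("duplicate residue identifiers in scale")
  if (any(!is.finite(values)))
    stop("scale values must be finite")
  structure(list(name = name, units = units, values = values),
            class = "hydrophobicity_scale")
}

#' @export
print.hydrophobicity_scale <- function(x, ...) {
  cat(sprintf("Hydrophobicity scale '%s' (%s), %d residues\n",
              x$name, x$units, length(x$values)))
  invisible(x)
}

#' Check a scale covers the 20 standard residues
#' @param scale a \code{hydrophobicity_scale}
#' @return logical
#' @export
is_complete_scale <- function(scale) {
  all(.aa3 %in% names(scale$values))
}

#' Read a hydrophobicity scale from a delimited text file
#'
#' Format: optional comment/header lines starting with \code{#} (a line
#' \code{# units: kcal/mol} sets the units), then two whitespace- or
#' tab-delimited columns: residue identifier, energy.
#'
#' @param path file path
#' @param name label for the scale (default: file name)
#' @return a \code{hydrophobicity_scale}
#' @export
read_scale <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty scale file: ", path)
  units <- "kcal/mol"
  hdr <- grep("^\\s*#", lines, value = TRUE)
  um <- regmatches(hdr, regexpr("units:\\s*\\S+", hdr))
  if (length(um)) units <- sub("units:\\s*", "", um[[1]])
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  parts <- strsplit(trimws(body), "[\t ]+")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("malformed scale line(s): ",
                     paste(body[bad], collapse = "; "))
  vals <- vapply(parts, function(p) as.numeric(p[[2]]), 1.0)
  names(vals) <- toupper(vapply(parts, `[[`, "", 1L))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  hydrophobicity_scale(vals, name = name,
                       units = match.arg(units, c("kcal/mol", "kJ/mol")))
}

#' Write a hydrophobicity scale to a delimited text file
#' @param scale a \code{hydrophobicity_scale}
#' @param path output path
#' @return invisibly, the path
#' @export
write_scale <- function(scale, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# scale: %s", scale$name), con)
  writeLines(sprintf("# units: %s", scale$units), con)
  writeLines(sprintf("%s\t%.6g", names(scale$values), scale$values), con)
  invisible(path)
}

# Octanol-partition side-chain transfer energies (kcal/mol), expressed in
# the water->membrane convention (negative = hydrophobic).  This is the
# classic octanol/water partition scale used to calibrate the default
# atom typing.
.fp_scale <- c(
  ALA = -0.31, ARG = 1.01, ASN = 0.60, ASP = 0.77, CYS = -1.54,
  GLN = 0.22, GLU = 0.64, GLY = 0.00, HIS = -0.13, ILE = -1.80,
  LEU = -1.70, LYS = 0.99, MET = -1.23, PHE = -1.79, PRO = -0.72,
  SER = 0.04, THR = -0.26, TRP = -2.25, TYR = -0.96, VAL = -1.22
)

#' Built-in hydrophobicity scales
#'
#' \code{"octanol"} is the classic octanol/water side-chain partition
#' scale in the water-to-membrane sign convention (negative =
#' hydrophobic).
#'
#' @param name scale name; currently \code{"octanol"}
#' @return a \code{hydrophobicity_scale}
#' @export
builtin_scale <- function(name = "octanol") {
  switch(tolower(name),
    octanol = hydrophobicity_scale(.fp_scale, name = "octanol",
                                   units = "kcal/mol"),
    stop(sprintf("unknown built-in scale '%s' (available: octanol)", name))
  )
}
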