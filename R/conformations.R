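#' @title Residue conformation templates
#' @name conformations
#' @description
#' Calibration evaluates each residue's transfer energy on standard
#' conformations.  The package ships one extended-conformation template
#' per residue, built from ideal internal coordinates (standard bond
#' lengths, tetrahedral/planar angles, extended dihedrals) with heavy
#' atoms only; glycine carries its two alpha hydrogens so that it has a
#' calibratable side chain.  Users may instead supply a directory of
#' PDB files, one per residue.
NULL

# place atom D given A, B, C with bond r = |C-D|, angle B-C-D (deg),
# dihedral A-B-C-D (deg): natural extension reference frame
.nerf <- function(A, B, C, r, angle, dihedral) {
  th <- angle * pi / 180; phi <- dihedral * pi / 180
  b1 <- B - A; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- C - B; b2 <- b2 / sqrt(sum(b2^2))
  n <- c(b1[2] * b2[3] - b1[3] * b2[2],
         b1[3] * b2[1] - b1[1] * b2[3],
         b1[1] * b2[2] - b1[2] * b2[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * b2[3] - n[3] * b2[2],
         n[3] * b2[1] - n[1] * b2[3],
         n[1] * b2[2] - n[2] * b2[1])
  d2 <- r * c(-cos(th), sin(th) * cos(phi), sin(th) * sin(phi))
  C + d2[1] * b2 + d2[2] * m + d2[3] * n
}

# side-chain internal coordinate tables.  Each row: atom, then the
# three reference atoms (A, B, C: new atom bonds to C), bond length,
# angle, dihedral.  Bond lengths: C-C 1.53, C-N 1.47, C-O 1.43,
# C-S 1.81, aromatic 1.39, carboxyl/amide C-O 1.23-1.25.
.sidechain_zmat <- list(
  GLY = list(c("HA2", "C", "N", "CA", 1.09, 109.5, -122),
             c("HA3", "C", "N", "CA", 1.09, 109.5, 118)),
  ALA = list(),
  SER = list(c("OG", "N", "CA", "CB", 1.43, 110.5, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.81, 113.8, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.43, 109.5, 180),
             c("CG2", "N", "CA", "CB", 1.53, 110.5, -60)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.53, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.53, 110.5, -60)),
  LEU = list(c("CG", "N", "CA", "CB", 1.53, 116.3, 180),
             c("CD1", "CA", "CB", "CG", 1.53, 110.5, 180),
             c("CD2", "CA", "CB", "CG", 1.53, 110.5, -60)),
  ILE = list(c("CG1", "N", "CA", "CB", 1.53, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.53, 110.5, -60),
             c("CD1", "CA", "CB", "CG1", 1.53, 113.9, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.53, 114.1, 180),
             c("SD", "CA", "CB", "CG", 1.81, 112.7, 180),
             c("CE", "CB", "CG", "SD", 1.79, 100.2, 180)),
  PRO = list(c("CG", "N", "CA", "CB", 1.50, 104.5, 30),
             c("CD", "CA", "CB", "CG", 1.51, 105.0, -35)),
  ASP = list(c("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.25, 118.4, 0),
             c("OD2", "CA", "CB", "CG", 1.25, 118.4, 180)),
  ASN = list(c("CG", "N", "CA", "CB", 1.52, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.23, 120.8, 0),
             c("ND2", "CA", "CB", "CG", 1.33, 116.4, 180)),
  GLU = list(c("CG", "N", "CA", "CB", 1.53, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.25, 118.4, 0),
             c("OE2", "CB", "CG", "CD", 1.25, 118.4, 180)),
  GLN = list(c("CG", "N", "CA", "CB", 1.53, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.52, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.23, 120.8, 0),
             c("NE2", "CB", "CG", "CD", 1.33, 116.4, 180)),
  LYS = list(c("CG", "N", "CA", "CB", 1.53, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.53, 111.3, 180),
             c("CE", "CB", "CG", "CD", 1.53, 111.3, 180),
             c("NZ", "CG", "CD", "CE", 1.49, 111.9, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.53, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.53, 111.3, 180),
             c("NE", "CB", "CG", "CD", 1.46, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.33, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180)),
  HIS = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.38, 122.7, 90),
             c("CD2", "CA", "CB", "CG", 1.36, 131.0, -90),
             c("CE1", "CB", "CG", "ND1", 1.33, 109.3, 180),
             c("NE2", "CG", "ND1", "CE1", 1.33, 111.0, 0)),
  PHE = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.39, 120.0, 90),
             c("CD2", "CA", "CB", "CG", 1.39, 120.0, -90),
             c("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0)),
  TYR = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.39, 120.0, 90),
             c("CD2", "CA", "CB", "CG", 1.39, 120.0, -90),
             c("CE1", "CB", "CG", "CD1", 1.39, 120.0, 180),
             c("CE2", "CB", "CG", "CD2", 1.39, 120.0, 180),
             c("CZ", "CG", "CD1", "CE1", 1.39, 120.0, 0),
             c("OH", "CD1", "CE1", "CZ", 1.38, 120.0, 180)),
  TRP = list(c("CG", "N", "CA", "CB", 1.50, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.37, 127.0, 90),
             c("CD2", "CA", "CB", "CG", 1.43, 126.6, -90),
             c("NE1", "CB", "CG", "CD1", 1.38, 110.1, 180),
             c("CE2", "CG", "CD1", "NE1", 1.37, 109.0, 0),
             c("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0),
             c("CZ2", "CD1", "NE1", "CE2", 1.40, 130.4, 180),
             c("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, 180),
             c("CH2", "NE1", "CE2", "CZ2", 1.40, 117.5, 180))
)

#' Build the ideal-geometry template for one residue
#'
#' Backbone N, CA, C, O plus CB (except glycine) and the side chain
#' from the internal-coordinate table.
#'
#' @param resname three-letter residue code
#' @return an all-atom \code{particle_system} for the single residue
#' @export
residue_template <- function(resname) {
  resname <- toupper(resname)
  if (!resname %in% names(.sidechain_zmat))
    stop("no template for residue ", resname)
  pos <- list(
    N = c(-0.527, 1.360, 0.0),
    CA = c(0, 0, 0),
    C = c(1.525, 0, 0)
  )
  pos$O <- .nerf(pos$N, pos$CA, pos$C, 1.23, 121.0, 0)
  atoms <- c("N", "CA", "C", "O")
  if (resname != "GLY") {
    pos$CB <- .nerf(pos$C, pos$N, pos$CA, 1.53, 110.5, -122)
    atoms <- c(atoms, "CB")
  }
  for (row in .sidechain_zmat[[resname]]) {
    nm <- row[1]
    pos[[nm]] <- .nerf(pos[[row[2]]], pos[[row[3]]], pos[[row[4]]],
                       as.numeric(row[5]), as.numeric(row[6]),
                       as.numeric(row[7]))
    atoms <- c(atoms, nm)
  }
  xyz <- do.call(rbind, pos[atoms])
  el <- .guess_element(atoms)
  df <- data.frame(resname = resname, resno = 1L, name = atoms,
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   radius = unname(.element_radii[el]),
                   stringsAsFactors = FALSE)
  ps <- particle_system(df, representation = "all-atom")
  ps$sidechain <- !(ps$name %in% c("N", "CA", "C", "O"))
  ps
}

#' Build the conformation database for calibration
#'
#' One typed, SASA-annotated template per residue.  The result is
#' cached per (params identity is not part of the cache: typing labels
#' do not depend on energies, and \code{etr} is refreshed on use).
#'
#' @param residues residue codes (default: the 20 standard residues)
#' @param params an \code{atom_type_params} used to seed \code{etr}
#' @param n_points SASA point count
#' @param pdb_dir optional directory of per-residue PDB files
#'   (\code{<RES>.pdb}) used instead of the ideal templates
#' @return a named list of single-residue \code{particle_system}s,
#'   class \code{conformation_db}
#' @export
build_conformation_db <- function(residues = standard_residues(),
                                  params = default_atom_params(),
                                  n_points = 960, pdb_dir = NULL) {
  db <- lapply(residues, function(rn) {
    ps <- if (is.null(pdb_dir)) residue_template(rn)
    else {
      f <- file.path(pdb_dir, paste0(rn, ".pdb"))
      if (!file.exists(f)) stop("no conformation file for ", rn)
      load_pdb(f)
    }
    ps <- assign_atom_types(ps, params)
    compute_sasa(ps, n_points = n_points)
  })
  names(db) <- toupper(residues)
  structure(db, class = "conformation_db")
}

#' @export
print.conformation_db <- function(x, ...) {
  cat(sprintf("Conformation database: %d residues (%s...)\n",
              length(x), paste(utils::head(names(x), 5), collapse = ", ")))
  invisible(x)
}

# package-level cache of the default conformation DB
.implimem_cache <- new.env(parent = emptyenv())

#' Default conformation database (cached)
#' @return a \code{conformation_db} over the 20 standard residues
#' @export
default_conformation_db <- function() {
  if (is.null(.implimem_cache$confdb)) {
    .implimem_cache$confdb <- build_conformation_db()
  }
  .implimem_cache$confdb
}
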