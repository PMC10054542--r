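#' @title Structure ingestion and atom typing
#' @name structures
#' @description
#' Structures enter as PDB files (all-atom or coarse-grained bead
#' coordinates) and become \code{\link{particle_system}} objects.
#' All-atom particles are classified into 7 atom types: Csp3 (single
#' bonded carbons), Csp2 (double bonded and aromatic carbons), Hnc
#' (hydrogen bonded to carbon), Hc (hydrogen bonded to N/O/S), O, N and
#' S.  Each (residue, type) pair maps to a transfer energy per area
#' through an \code{\link{atom_type_params}} table.
NULL

# element-based van der Waals radii (Angstrom)
.element_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, H = 1.2,
                    P = 1.8)

.guess_element <- function(name) {
  el <- sub("^[0-9']*", "", trimws(name))
  el <- toupper(substr(el, 1, 1))
  ifelse(el %in% names(.element_radii), el, "C")
}

#' Load a PDB file into a particle system
#'
#' Uses the first model only; alternate locations are resolved to the
#' highest occupancy; water and hetero records are skipped by default.
#' Radii are assigned from the element.  A file whose residues each
#' contain a single particle is flagged as a one-bead system.
#'
#' @param path PDB file path
#' @param keep_hetero keep HETATM records (default FALSE)
#' @param representation force a representation label; guessed when NULL
#' @return a \code{particle_system}
#' @export
load_pdb <- function(path, keep_hetero = FALSE, representation = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  if (!is.null(at$type) && !keep_hetero) at <- at[at$type == "ATOM", ]
  at <- at[!(at$resid %in% c("HOH", "WAT")), ]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  # resolve altloc: keep highest occupancy per (chain, resno, atom name)
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any((nzchar(alt) & alt != "A") |
          duplicated(paste(at$chain, at$resno, at$elety)))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- if (is.null(at$o)) rep(1, nrow(at)) else at$o
    ord <- order(key, -occ)
    at <- at[ord, ][!duplicated(key[ord]), ]
    at <- at[order(at$eleno), ]
  }
  el <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
    toupper(trimws(at$elesy)) else .guess_element(at$elety)
  el[!el %in% names(.element_radii)] <- .guess_element(at$elety[!el %in% names(.element_radii)])
  df <- data.frame(chain = ifelse(is.na(at$chain), "A", at$chain),
                   resname = toupper(trimws(at$resid)),
                   resno = at$resno,
                   name = trimws(at$elety),
                   x = at$x, y = at$y, z = at$z,
                   radius = unname(.element_radii[el]),
                   stringsAsFactors = FALSE)
  if (is.null(representation)) {
    per_res <- table(paste(df$chain, df$resno))
    representation <- if (all(per_res == 1L)) "one-bead" else "all-atom"
  }
  ps <- particle_system(df, representation = representation)
  ps$sidechain <- !(ps$name %in% .backbone_names)
  ps
}

#' Write a particle system as a PDB file
#' @param ps a \code{particle_system}
#' @param path output path
#' @return invisibly, the path
#' @export
write_pdb <- function(ps, path) {
  bio3d::write.pdb(file = path, xyz = as.vector(t(ps_coords(ps))),
                   resno = ps$resno, resid = ps$resname,
                   eleno = ps$id, elety = ps$name, chain = ps$chain)
  invisible(path)
}

# backbone atom names (heavy + amide/alpha hydrogens)
.backbone_names <- c("N", "CA", "C", "O", "OXT", "H", "HN", "HA",
                     "H1", "H2", "H3", "HA2", "HA3")

# sp2 carbons by residue (carbonyl, guanidinium, aromatic); the
# backbone carbonyl C is sp2 in every residue
.sp2_carbons <- list(
  ASP = c("CG"), ASN = c("CG"), GLU = c("CD"), GLN = c("CD"),
  ARG = c("CZ"),
  HIS = c("CG", "CD2", "CE1"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# hydrogens bonded to N/O/S, per residue (classified Hc); all other
# hydrogens are bonded to carbon (Hnc)
.polar_hydrogens <- list(
  SER = "HG", THR = "HG1", CYS = "HG", TYR = "HH",
  TRP = "HE1", HIS = c("HD1", "HE2"),
  ASN = c("HD21", "HD22"), GLN = c("HE21", "HE22"),
  LYS = c("HZ1", "HZ2", "HZ3"),
  ARG = c("HE", "HH11", "HH12", "HH21", "HH22")
)

#' Classify one atom into the 7-type scheme
#' @param resname residue name (three-letter code)
#' @param atom atom name (PDB convention)
#' @return one of \code{"Csp3"}, \code{"Csp2"}, \code{"Hnc"},
#'   \code{"Hc"}, \code{"O"}, \code{"N"}, \code{"S"}
#' @export
atom_type_of <- function(resname, atom) {
  el <- .guess_element(atom)
  switch(el,
    O = "O", N = "N", S = "S",
    H = {
      polar <- c(.polar_hydrogens[[resname]], "H", "HN", "H1", "H2", "H3")
      if (atom %in% polar) "Hc" else "Hnc"
    },
    C = {
      sp2 <- c(.sp2_carbons[[resname]], "C")
      if (atom %in% sp2) "Csp2" else "Csp3"
    },
    stop(sprintf("cannot type atom '%s' in residue %s", atom, resname))
  )
}

#' Construct an atom-type parameter table
#'
#' Rows map (residue, type) to a transfer energy per area in
#' kcal mol^-1 A^-2.  A residue value of \code{"*"} is a wildcard
#' matched when no residue-specific row exists; per-residue calibration
#' inserts residue-specific rows.
#'
#' @param df data frame with columns \code{residue}, \code{type},
#'   \code{etr}
#' @return an object of class \code{atom_type_params}
#' @export
atom_type_params <- function(df) {
  stopifnot(all(c("residue", "type", "etr") %in% names(df)))
  key <- paste(df$residue, df$type)
  if (anyDuplicated(key)) stop("duplicate (residue, type) entries")
  structure(df[c("residue", "type", "etr")], class = c("atom_type_params",
                                                       "data.frame"))
}

#' Look up the per-area transfer energy for (residue, type) pairs
#' @param params an \code{atom_type_params}
#' @param residue,type character vectors (recycled)
#' @return numeric vector of energies (kcal mol^-1 A^-2)
#' @export
lookup_etr <- function(params, residue, type) {
  n <- max(length(residue), length(type))
  residue <- rep_len(residue, n); type <- rep_len(type, n)
  exact <- match(paste(residue, type), paste(params$residue, params$type))
  wild <- match(paste("*", type), paste(params$residue, params$type))
  out <- ifelse(is.na(exact), params$etr[wild], params$etr[exact])
  if (anyNA(out)) {
    i <- which(is.na(out))[1]
    stop(sprintf("no transfer energy for residue %s type %s",
                 residue[i], type[i]))
  }
  out
}

#' Read an atom-type parameter table from delimited text
#'
#' Columns: \code{residue type etr} (whitespace/tab separated, \code{#}
#' comments allowed).
#' @param path file path
#' @return an \code{atom_type_params}
#' @export
read_atom_params <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  atom_type_params(df)
}

#' Write an atom-type parameter table
#' @param params an \code{atom_type_params}
#' @param path output path
#' @return invisibly, the path
#' @export
write_atom_params <- function(params, path) {
  utils::write.table(as.data.frame(params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic default atom-type parameters
#'
#' A plausible starting parameterization of the 7 atom types (apolar
#' types membrane-favouring, polar types water-favouring), used as the
#' initial point for calibration when no user table is supplied.  The
#' values are synthetic defaults, not a published set.
#'
#' @return an \code{atom_type_params} with wildcard-residue rows
#' @export
default_atom_params <- function() {
  atom_type_params(data.frame(
    residue = "*",
    type = c("Csp3", "Csp2", "Hnc", "Hc", "O", "N", "S"),
    etr = c(-0.012, -0.010, -0.008, 0.012, 0.022, 0.018, -0.010),
    stringsAsFactors = FALSE))
}

#' Assign atom types and transfer energies to an all-atom system
#'
#' @param ps an all-atom \code{particle_system}
#' @param params an \code{atom_type_params}
#' @return the system with \code{type} and \code{etr} filled
#' @export
assign_atom_types <- function(ps, params = default_atom_params()) {
  ps$type <- mapply(atom_type_of, ps$resname, ps$name, USE.NAMES = FALSE)
  ps$etr <- lookup_etr(params, ps$resname, ps$type)
  ps
}
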