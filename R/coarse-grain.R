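#' @title Coarse-grained mapping and correspondence tables
#' @name coarse-grain
#' @description
#' A correspondence table links coarse-grained bead types to the atoms
#' they subsume, their surface areas, and their transfer free energies.
#' Beads are placed at the centre of geometry of their constituent
#' atoms.  The one-bead-per-residue representation is the limiting
#' case: one side-chain-centroid bead per residue whose transfer energy
#' is the hydrophobicity-scale value itself.
NULL

#' Construct a correspondence table
#'
#' @param df data frame with columns \code{residue} (3-letter code),
#'   \code{particle} (bead name), \code{atoms}
#'   (comma-separated member atom names), \code{type} (bead type
#'   label), \code{area} (bead surface area in A^2, or NA to compute
#'   from the bead sphere), \code{energy} (bead transfer free energy),
#'   \code{units} (\code{kcal/mol} or \code{kJ/mol}), and optionally
#'   \code{radius} (bead radius, A)
#' @return an object of class \code{correspondence_table}
#' @export
correspondence_table <- function(df) {
  need <- c("residue", "particle", "atoms", "type", "area", "energy",
            "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing correspondence columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(paste(df$residue, df$particle)))
    stop("duplicate (residue, particle) correspondence rows")
  if (is.null(df$radius)) df$radius <- 2.3
  structure(df, class = c("correspondence_table", "data.frame"))
}

#' Read a correspondence table from delimited text
#'
#' Header \code{residue particle atoms type area energy units}
#' (whitespace/tab separated; \code{#} comments allowed; \code{area}
#' may be \code{computed}).
#' @param path file path
#' @return a \code{correspondence_table}
#' @export
read_correspondence <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!is.null(df$area)) {
    df$area <- suppressWarnings(as.numeric(ifelse(df$area == "computed",
                                                  NA, df$area)))
  }
  correspondence_table(df)
}

#' Convert a partition free energy to a per-area bead energy
#'
#' @param dG partition free energy (any molar unit)
#' @param bead_area bead surface area (A^2, > 0)
#' @return energy per area in the same molar unit per A^2
#' @export
partition_to_per_area <- function(dG, bead_area) {
  if (any(!(bead_area > 0))) stop("bead area must be positive")
  dG / bead_area
}

#' Map an all-atom system to a coarse-grained bead system
#'
#' Each bead is placed at the centre of geometry of its member atoms;
#' its surface area is taken from the table (or the bare bead sphere
#' area when the table says computed); its per-area transfer energy is
#' the table's bead transfer free energy divided by the bead area,
#' converted to kcal if tabulated in kJ.
#'
#' @param ps an all-atom \code{particle_system}
#' @param table a \code{correspondence_table} covering every residue
#'   present
#' @return a \code{particle_system} with representation
#'   \code{"cg-bead"}
#' @export
map_coarse_grained <- function(ps, table) {
  stopifnot(inherits(table, "correspondence_table"))
  res_keys <- unique(ps[c("chain", "resno", "resname")])
  uncovered <- setdiff(unique(res_keys$resname), unique(table$residue))
  if (length(uncovered))
    stop("correspondence table does not cover residue(s): ",
         paste(uncovered, collapse = ", "))
  rows <- list()
  for (r in seq_len(nrow(res_keys))) {
    rk <- res_keys[r, ]
    sub <- ps[ps$chain == rk$chain & ps$resno == rk$resno, ]
    beads <- table[table$residue == rk$resname, ]
    for (b in seq_len(nrow(beads))) {
      members <- trimws(strsplit(beads$atoms[b], ",")[[1]])
      hit <- sub[sub$name %in% members, ]
      if (nrow(hit) == 0L) next
      ctr <- colMeans(ps_coords(hit))
      area <- beads$area[b]
      if (is.na(area)) area <- 4 * pi * beads$radius[b]^2
      e <- beads$energy[b]
      if (grepl("^kj", tolower(beads$units[b]))) e <- e / CAL_TO_JOULE
      rows[[length(rows) + 1L]] <- data.frame(
        chain = rk$chain, resname = rk$resname, resno = rk$resno,
        name = beads$particle[b], x = ctr[1], y = ctr[2], z = ctr[3],
        radius = beads$radius[b], sasa = area,
        type = beads$type[b], etr = e / area,
        sidechain = !identical(beads$particle[b], "BB"),
        stringsAsFactors = FALSE)
    }
  }
  out <- particle_system(do.call(rbind, rows), representation = "cg-bead")
  out
}

#' Map a system to the one-bead-per-residue representation
#'
#' One bead per residue at the side-chain centroid (CA for glycine and
#' any residue without side-chain particles).  The bead's energetics
#' are constructed so that its predicted transfer energy at the bilayer
#' midplane equals the hydrophobicity-scale value exactly: with
#' C(0) = -0.5 the prediction is
#' \eqn{0.5 S E_{tr} - 0.5 a_{lip} S}, so the bead's per-area energy is
#' set to \eqn{2 v / S + a_{lip}} for scale value v and bead area S.
#'
#' @param ps a \code{particle_system} (any representation)
#' @param scale a \code{hydrophobicity_scale} covering the residues
#'   present
#' @param geom a \code{membrane_geometry} (supplies \code{a_lip})
#' @param bead_area bead surface area (A^2)
#' @param bead_radius bead radius (A)
#' @return a \code{particle_system} with representation
#'   \code{"one-bead"}
#' @export
map_one_bead <- function(ps, scale, geom = membrane_geometry(),
                         bead_area = 60, bead_radius = 3.0) {
  vals <- scale$values
  if (identical(scale$units, "kJ/mol")) vals <- vals / CAL_TO_JOULE
  res_keys <- unique(ps[c("chain", "resno", "resname")])
  uncovered <- setdiff(unique(res_keys$resname), names(vals))
  if (length(uncovered))
    stop("scale does not cover residue(s): ",
         paste(uncovered, collapse = ", "))
  rows <- lapply(seq_len(nrow(res_keys)), function(r) {
    rk <- res_keys[r, ]
    sub <- ps[ps$chain == rk$chain & ps$resno == rk$resno, ]
    sc <- sub[sub$sidechain, ]
    if (nrow(sc) == 0L) sc <- sub[sub$name == "CA", ]
    if (nrow(sc) == 0L) sc <- sub
    ctr <- colMeans(ps_coords(sc))
    v <- vals[[rk$resname]]
    data.frame(chain = rk$chain, resname = rk$resname, resno = rk$resno,
               name = rk$resname, x = ctr[1], y = ctr[2], z = ctr[3],
               radius = bead_radius, sasa = bead_area,
               type = rk$resname, etr = 2 * v / bead_area + geom$a_lip,
               sidechain = TRUE, stringsAsFactors = FALSE)
  })
  particle_system(do.call(rbind, rows), representation = "one-bead")
}
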