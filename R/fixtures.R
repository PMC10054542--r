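#' @title Synthetic test fixtures
#' @name fixtures
#' @description
#' Deterministic synthetic particle systems for testing and
#' demonstration without any external structure download: toy residues
#' with known isolated-sphere surface areas, ideal alpha-helices
#' (1.5 A rise, 100 degrees per residue) with assignable per-residue
#' transfer energies, and a hollow barrel-like particle shell with a
#' hydrophobic outer band.
NULL

#' Generate a synthetic fixture
#'
#' Kinds:
#' \describe{
#'   \item{toy_residue}{\code{size} well-separated spheres with exactly
#'     known isolated SASA.}
#'   \item{hydrophobic_helix}{ideal one-bead alpha-helix, all residues
#'     hydrophobic (negative transfer energy).}
#'   \item{amphipathic_helix}{ideal one-bead alpha-helix whose faces
#'     alternate hydrophobic/hydrophilic with the ~3.6-residue helical
#'     period.}
#'   \item{barrel_shell}{hollow cylinder of beads whose outer mid-band
#'     is hydrophobic and whose rims are hydrophilic; \code{size} is
#'     the height in Angstrom.}
#' }
#' All kinds are deterministic for a fixed seed (the seed only jitters
#' toy-residue placement).
#'
#' @param kind fixture kind (see Details)
#' @param size residue/particle count, or barrel height in Angstrom
#' @param seed integer seed
#' @param etr_hydrophobic,etr_hydrophilic per-area transfer energies
#'   (kcal mol^-1 A^-2) assigned to the two classes of beads
#' @param bead_area,bead_radius bead surface parameters
#' @return a \code{particle_system}
#' @export
#' @examples
#' helix <- make_fixture("amphipathic_helix", size = 18)
make_fixture <- function(kind = c("toy_residue", "amphipathic_helix",
                                  "hydrophobic_helix", "barrel_shell"),
                         size = 18, seed = 1,
                         etr_hydrophobic = -0.03,
                         etr_hydrophilic = 0.03,
                         bead_area = 60, bead_radius = 3.0) {
  kind <- match.arg(kind)
  switch(kind,
    toy_residue = .fix_toy_residue(size, seed, etr_hydrophobic,
                                   bead_radius),
    hydrophobic_helix = .fix_helix(size, etr_hydrophobic,
                                   etr_hydrophobic, bead_area,
                                   bead_radius),
    amphipathic_helix = .fix_helix(size, etr_hydrophobic,
                                   etr_hydrophilic, bead_area,
                                   bead_radius),
    barrel_shell = .fix_barrel(size, etr_hydrophobic, etr_hydrophilic,
                               bead_area, bead_radius)
  )
}

.fix_toy_residue <- function(n, seed, etr, radius) {
  stopifnot(n >= 1, n <= 1000)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old))
  set.seed(seed)
  # spheres far enough apart that each keeps its full isolated surface
  sep <- 6 * (radius + 1.4)
  xyz <- cbind(seq_len(n) * sep + stats::runif(n, -0.5, 0.5),
               stats::runif(n, -0.5, 0.5), stats::runif(n, -0.5, 0.5))
  df <- data.frame(resname = "TOY", resno = seq_len(n),
                   name = sprintf("B%d", seq_len(n)),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   radius = radius,
                   sasa = 4 * pi * (radius + 1.4)^2,
                   etr = etr, sidechain = TRUE,
                   stringsAsFactors = FALSE)
  particle_system(df, representation = "one-bead")
}

# ideal alpha-helix along +z: rise 1.5 A and 100 degrees per residue,
# helical radius 2.3 A.  Face assignment: hydrophobic when the bead's
# azimuthal direction has negative x-component after laying the helix
# along the x axis (so the hydrophobic stripe forms one face).
.fix_helix <- function(n_res, etr_phobic, etr_philic, bead_area,
                       bead_radius) {
  stopifnot(n_res >= 4, n_res <= 200)
  i <- seq_len(n_res)
  theta <- (i - 1) * 100 * pi / 180
  helix_r <- 2.3
  xyz <- cbind(helix_r * cos(theta), helix_r * sin(theta),
               (i - 1) * 1.5)
  xyz <- sweep(xyz, 2, colMeans(xyz))
  # lay the helix axis along x so depth scans move it through the
  # membrane sideways; the face normal is then +/- z
  xyz <- xyz[, c(3, 2, 1)]
  phobic <- cos(theta) < 0  # one helical face
  df <- data.frame(resname = ifelse(phobic, "PHO", "PHI"),
                   resno = i, name = "SC",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   radius = bead_radius, sasa = bead_area,
                   etr = ifelse(phobic, etr_phobic, etr_philic),
                   sidechain = TRUE, stringsAsFactors = FALSE)
  particle_system(df, representation = "one-bead")
}

.fix_barrel <- function(height, etr_phobic, etr_philic, bead_area,
                        bead_radius) {
  stopifnot(height >= 10, height <= 100)
  n_ring <- 12
  ring_z <- seq(-height / 2, height / 2, by = 2.5)
  band <- abs(ring_z) <= height / 2 - 7.5  # hydrophobic mid-band
  th <- (seq_len(n_ring) - 1) * 2 * pi / n_ring
  rows <- lapply(seq_along(ring_z), function(k) {
    data.frame(resname = if (band[k]) "PHO" else "PHI",
               resno = (k - 1L) * n_ring + seq_len(n_ring),
               name = "SC",
               x = 8 * cos(th), y = 8 * sin(th), z = ring_z[k],
               radius = bead_radius, sasa = bead_area,
               etr = if (band[k]) etr_phobic else etr_philic,
               sidechain = TRUE, stringsAsFactors = FALSE)
  })
  particle_system(do.call(rbind, rows), representation = "one-bead")
}

# save/restore the global RNG state around seeded fixture generation
.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
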