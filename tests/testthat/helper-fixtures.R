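# shared helpers for the test suite

# decimal rounding with ties away from zero, as printed tables round
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# a random annotated particle system (beads with SASA and transfer
# energies set), deterministic under the given seed
random_system <- function(n = 50, seed = 1, spread = 30) {
  set.seed(seed)
  df <- data.frame(resname = "RND", resno = seq_len(n), name = "B",
                   x = runif(n, -spread, spread),
                   y = runif(n, -spread, spread),
                   z = runif(n, -spread, spread),
                   radius = 2, sasa = runif(n, 5, 80),
                   etr = runif(n, -0.05, 0.05), sidechain = TRUE)
  particle_system(df, representation = "one-bead")
}

# single bead at a given position
single_bead <- function(z = 0, sasa = 10, etr = -0.1, x = 0, y = 0) {
  particle_system(data.frame(resname = "TOY", resno = 1, name = "B",
                             x = x, y = y, z = z, radius = 2,
                             sasa = sasa, etr = etr, sidechain = TRUE),
                  representation = "one-bead")
}

# printed structural table used by the reproduction tests:
# lipid, 2D_C, D_B', beta, z0, alpha
printed_lipid_table <- function() {
  data.frame(
    lipid = c("DLPG", "DOPC", "DMPC", "DLPE", "DOPG", "POPG", "DPPC"),
    twoDC = c(20.7, 27.1, 26.2, 30.0, 27.9, 28.3, 34.4),
    DBp   = c(35.3, 35.9, 36.9, 42.1, 42.8, 44.0, 47.8),
    beta  = c(7.3, 4.4, 5.4, 6.1, 7.5, 7.9, 6.7),
    z0    = c(14.00, 15.75, 15.78, 18.03, 17.68, 18.08, 20.55),
    alpha = c(1.23, 2.04, 1.67, 1.48, 1.20, 1.14, 1.34))
}
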