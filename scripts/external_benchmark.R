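#!/usr/bin/env Rscript
# Membrane-protein insertion benchmark against an externally supplied
# all-atom structure (e.g. the OmpA transmembrane domain, PDB 1QJP /
# 1BXW, protonated).  This script is NOT run by the test suite: it
# needs a structure file the package does not ship.
#
# Preparation:
#   1. Download an OmpA beta-barrel structure from the PDB and strip
#      waters/heteroatoms (the loader skips them anyway).
#   2. Optionally add hydrogens with your favourite tool; the
#      heavy-atom typing table is used when none are present.
#   3. Run:  Rscript scripts/external_benchmark.R ompa.pdb
#
# The expected behaviour for an OmpA-like barrel in the default
# membrane is a converged insertion depth of roughly -6 Angstrom and
# an insertion angle of roughly 60 degrees for the insertion vector
# through the first and last CA of the barrel.

suppressPackageStartupMessages(library(implimem))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: external_benchmark.R <structure.pdb> [steps]")
steps <- if (length(args) > 1) as.integer(args[[2]]) else 50000

ps <- load_pdb(args[[1]])
ps <- assign_atom_types(ps)
ps <- compute_sasa(ps)
mem <- planar_membrane(get_preset("default"))

# start above the membrane and relax, then sample
ps <- ps_translate(ps, c(0, 0, 30) - ps_center(ps))
res <- minimize(ps, mem, tol = 1e-9)
traj <- run_monte_carlo(res$system, mem, steps = steps, seed = 1,
                        record_every = 10L, max_depth = 60)
final <- trajectory_final(traj)

ca <- final$id[final$name == "CA"]
met <- insertion_metrics(final, mem, c(ca[1], ca[length(ca)]))
cat(sprintf("insertion depth: %.2f A\n", met$depth))
cat(sprintf("insertion angle: %.1f deg\n", met$tilt))
cat(sprintf("E_imp: %.2f kcal/mol\n",
            total_energy(final, mem)$e_imp))
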