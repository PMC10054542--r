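# implimem

Implicit lipid bilayer models for protein insertion energetics in R.

## The problem

Predicting how a protein positions itself in a lipid bilayer — how deep
it sits, how it tilts — is central to membrane biology, and direct
experimental determination is often impractical. Explicit-lipid
molecular dynamics is accurate but expensive; implicit membrane models
replace the lipids with a smooth environmental field and score a
protein pose in microseconds, which makes exhaustive scans, Monte Carlo
sampling and interactive exploration practical.

`implimem` is for structural bioinformaticians and modellers who want a
small, fully scriptable implicit-membrane engine: planar bilayers,
analytic double bilayers at a tunable separation (membrane-fusion
geometries), and membranes of arbitrary shape defined by a triangulated
mesh — with per-residue calibration so the model reproduces *any*
reference hydrophobicity scale exactly, at all-atom, coarse-grained, or
one-bead-per-residue resolution.

## The model

The bilayer midplane sits at signed depth z = 0. The membrane is the
sigmoid field

    C(z) = 0.5 − (1 + exp(α(|z| − z₀)))⁻¹

which is −0.5 in the hydrocarbon core, +0.5 in bulk water, and crosses
0 at the centre of the headgroup region (z = z₀, width β). A pose of a
structure with particles i (exposed surface Sᵢ, per-area transfer
energy E_tr(i)) is scored by

    E_int = − Σᵢ Sᵢ · E_tr(i) · C(zᵢ)
    E_lip = a_lip · Σᵢ Sᵢ · C(zᵢ)
    E_imp = E_int + E_lip

with a_lip = −0.018 kcal mol⁻¹ Å⁻². Negative transfer energies are
hydrophobic (membrane-favouring). The geometric parameters derive from
measurable bilayer thicknesses — hydrocarbon thickness 2D_C and steric
thickness D_B′ — via

    β = (D_B′ − 2D_C)/2,   z₀ = (D_B′ − β)/2,   α = 2 ln(88.0145)/β

and presets are included for DLPG, DOPC, DMPC, DLPE, DOPG, POPG and
DPPC. Double membranes are handled analytically
(C_double(z) = C_main(z) + C_side(z)·C_side(−z), separation parameter
m); arbitrary shapes are handled by measuring each particle's signed
depth against the nearest vertex of a midplane mesh along its normal.

Because E_imp is linear in the per-type transfer energies, calibrating
a residue against a target scale value is a single linear constraint.
Four closed-form strategies (minimal-norm, proportional, single-type,
uniform-shift) solve it exactly; per residue the package keeps the one
that changes the starting parameters least, measured by the mean
arctangent absolute percent error (MAAPE).

## Worked example

```r
library(implimem)

get_preset("DOPC")
#> Implicit membrane geometry [DOPC]
#>   alpha = 2.0352   z0 = 15.75 A   beta = 4.40 A   a_lip = -0.0180 kcal/mol/A^2

## an 18-residue amphipathic helix touching the headgroup region
helix <- make_fixture("amphipathic_helix", size = 18)
mem   <- planar_membrane(get_preset("default"))
start <- ps_translate(helix, c(0, 0, 18 - ps_center(helix)[3]))
total_energy(start, mem)
#> E_int = -4.0014  E_lip = -7.2897  E_imp = -11.2911 kcal/mol

res <- minimize(start, mem, tol = 1e-9)
ps_center(res$system)[3]       # relaxed depth: 16.37 A
res$energy
#> E_int = -11.9394  E_lip = -1.8740  E_imp = -13.8134 kcal/mol
```

The helix settles with its centre ~16 Å from the midplane — lying in
the headgroup region, hydrophobic face toward the core — and the
insertion energy drops from −11.3 to −13.8 kcal/mol. A hydrophobic
helix instead buries at |z| < 11 Å in the core (`run_monte_carlo()`
samples both basins; `energy_scan()` tabulates the landscape).

Calibrating the shipped synthetic atom types against the built-in
octanol scale:

```r
cal <- calibrate_scale(builtin_scale("octanol"))
head(cal$report, 3)
#>   residue target initial_prediction calibrated_prediction    strategy    maape
#> 1     ALA  -0.31          0.1890693                 -0.31  least_norm 51.72600
#> 2     ARG   1.01          2.4376254                  1.01 single_type 44.59251
#> 3     ASN   0.60          1.8437186                  0.60 single_type 25.66507
```

Every calibrated prediction matches its target to 1e−6 kcal/mol.

## Command line

A thin CLI wraps the same functions:

```sh
exec/implimem params --lipid DOPC
exec/implimem mesh --size 90 --res 4 --sphere-radius 150 --out curved.obj
exec/implimem mc --fixture hydrophobic_helix --steps 20000 --outdir run/
exec/implimem calibrate --scale inst/extdata/scale_octanol.tsv --out calib.tsv
```

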