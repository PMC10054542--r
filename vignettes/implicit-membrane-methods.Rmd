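---
title: "Implicit membrane insertion: model, calibration and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit membrane insertion: model, calibration and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(implimem)
```

## The model and its assumptions

`implimem` treats the lipid bilayer as a continuum: a structureless
environmental field `C(z)` of the signed distance `z` from the bilayer
midplane,

$$C(z) = 0.5 - \left(1 + e^{\alpha(|z| - z_0)}\right)^{-1},$$

equal to $-0.5$ in the hydrocarbon core, $+0.5$ in bulk water, and $0$
at the centre of the headgroup region. A protein pose is scored by two
additive terms over its particles (atoms or beads): a transfer term
that rewards burying hydrophobic surface in the core,

$$E_{int} = -\sum_i S_i\, E_{tr}(i)\, C(z_i),$$

and a perturbation term that charges for any surface the protein
pushes into the bilayer,

$$E_{lip} = a_{lip} \sum_i S_i\, C(z_i), \qquad E_{imp} = E_{int} + E_{lip}.$$

The assumptions are those of any continuum solvent model: no specific
protein–lipid contacts, no electrostatics, no lateral pressure or
curvature stress, and a membrane that does not deform in response to
the protein. The pay-off is speed — a pose is scored in one vectorised
pass — which makes exhaustive scans, Monte Carlo and interactive use
practical. The model is best read as a tool for *positioning* proteins
and ranking poses, not for absolute binding thermodynamics.

## Parameters, units, defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `alpha` | interface steepness | 1.99 | — (slope per Å of depth) |
| `z0` | midplane → headgroup-centre distance | 15.75 | Å |
| `beta` | headgroup region width | 4.5 | Å |
| `a_lip` | lipid perturbation coefficient | −0.018 | kcal mol⁻¹ Å⁻² |
| `E_tr` | per-area transfer energy of a type | calibrated | kcal mol⁻¹ Å⁻² |

All internal energies are kcal/mol; kJ conversion happens only at I/O
boundaries (`convert_energy()`, scale files). The sign convention is
fixed throughout: negative transfer energy = hydrophobic.

The geometric triple is not free: it derives from two measurable
bilayer thicknesses, the hydrocarbon thickness $2D_C$ and steric
thickness $D_B'$, via $\beta = (D_B' - 2D_C)/2$, $z_0 = (D_B' -
\beta)/2$ and $\alpha = 2\ln(88.0145)/\beta$. The constant 88.0145
pins the sigmoid's span so that the transition occupies one headgroup
width; it equals $e^{\alpha\beta/2}$ for the default pairing
$\alpha = 1.99$, $\beta = 4.5$. `derive_geometry()` always computes
$z_0$ and $\alpha$ from the *unrounded* $\beta$: the shipped preset
table is only reproducible that way (rounding $\beta$ first propagates
visible errors into $z_0$ and $\alpha$). When comparing against
printed tables note that they round ties away from zero, while R's
`round()` follows IEC 60559 — the package's tests carry an explicit
half-up helper for exactly this reason.

## Calibration

The defining feature of the package is that the predicted transfer
energy of every residue — $E_{imp}$ of its side chain centred at
$z = 0$ — can be made to reproduce an arbitrary reference
hydrophobicity scale *exactly*. Because $E_{imp}$ is linear in the
per-type energies $E_t$, the prediction for a residue is

$$E_{pred} = \sum_t A_t E_t + B, \qquad
A_t = -\!\!\sum_{i \in t} S_i C(z_i), \quad
B = a_{lip} \sum_i S_i C(z_i),$$

a single linear constraint per residue. Four closed-form strategies
solve it: minimal-L2-change (`least_norm`), ratio-preserving scaling
(`proportional`), adjusting only the highest-leverage type
(`single_type`), and an equal additive shift (`uniform_shift`). The
`auto` mode runs all four and keeps the one whose parameters moved
least, measured by the mean arctangent absolute percent error

$$\mathrm{MAAPE} = \frac{100}{n}\sum_i \arctan\left|\frac{U_i - I_i}{U_i}\right|$$

(radians; $U$ adjusted, $I$ initial). The closed forms replace
iteration: the constraint being linear, a fixed-point iteration
(provided via `iterate = TRUE` for parity) converges to the same
solutions. Calibration is per residue — the same type label may carry
different energies in different residues — and the constraint is
imposed on the conformation-mean prediction when a residue has several
conformations. `proportional` is undefined when the initial prediction
equals the offset $B$ (nothing to scale); it then falls through to
`least_norm` with a warning. No sign constraint is imposed on adjusted
energies.

The shipped conformation database contains one extended-conformation
heavy-atom template per residue, built from ideal internal coordinates
(standard bond lengths, tetrahedral/planar angles, extended
dihedrals). Glycine keeps its two α-hydrogens so that it owns a
calibratable side chain. Heavy-atom-only input structures are
supported by letting the heavy-atom per-area energies absorb hydrogen
contributions during calibration; structures with explicit hydrogens
use the full 7-type table (Hc for H on N/O/S, Hnc for H on C).
The shipped initial parameter values are synthetic defaults with
plausible signs and magnitudes — they are a starting point for
calibration, not a published set — and users supply their own via
`read_atom_params()`.

The one-bead-per-residue representation is the limiting case: one
side-chain-centroid bead per residue whose per-area energy is
constructed as $2v/S + a_{lip}$ (scale value $v$, bead area $S$), so
its prediction equals $v$ identically — no calibration needed.

## Membranes beyond a single plane

**Double bilayers.** Two parallel membranes at separation $m$ are
analytic: $C_{double}(z) = C_{main}(z) + C_{side}(z)C_{side}(-z)$,
where $C_{main}$ widens the single profile by $m$ and the $C_{side}$
product carves the aqueous gap. The bilayers are fused into one for
$m \le z_0 - \beta/2$, merging for $m \le z_0 + \beta/2$ and separated
beyond; the thresholds are kept in terms of the geometry (13.5 Å and
18 Å for the default) so the feature works with any lipid preset.

**Meshes.** Arbitrary shapes are triangulated meshes of the bilayer
midplane (generated planar grids, spherically curved caps, or ASCII
OBJ/PLY files). A particle's depth is measured against its nearest
mesh vertex (uniform-grid spatial hash with an expanding-shell search
that provably returns the true nearest vertex). Two depth modes exist:
`projection` (offset · vertex normal — exact on planar meshes at any
resolution) and `euclidean` (full distance to the vertex, signed by
side), which carries the grid-resolution-dependent error of a raw
point-cloud distance and exists to study the accuracy-versus-coarseness
trade-off (`benchmark_mesh_resolution()`). Vertex normals are
area-weighted incident-triangle normals, renormalised. Several meshes
act as several membranes: each particle uses the mesh giving the
smallest |depth|. Hash cell size defaults to twice the grid spacing
(generated meshes) or the mean edge length (loaded meshes).

## Sampling and numerics

Rigid-body Metropolis Monte Carlo: per step a uniform translation
within ±1 Å per axis plus a rotation about a random axis through the
centroid by a uniform angle within ±5°, accepted with probability
$\min(1, e^{-\Delta E/k_BT})$ at $k_B = 0.0019872$ kcal mol⁻¹ K⁻¹,
default 300 K. Rotation axes are uniform on the sphere but the move
set is not uniform over SO(3); only relative exploration matters here.
Identical seeds give bitwise-identical trajectories. An optional
`max_depth` hard wall rejects moves whose centroid leaves a finite box
— without it an interface-bound solute has no normalisable equilibrium
in the semi-infinite water phase and will eventually random-walk away,
so equilibration statements are only well-posed in a finite box, just
as in any real simulation setup.

Gradient relaxation (`minimize()`) follows the net membrane force
(rigid translation; per-particle with an elastic network), halving the
step on overshoot. Two numerical degeneracies are worth knowing.
First, the sigmoid saturates: beyond $|z| \approx z_0 + 20$ Å the
profile equals ±0.5 to machine precision, so forces underflow and
"bulk water" is numerically flat — relaxation started deep in water
has no signal to follow. Second, the core is a *plateau*, not a point
minimum: inside $|z| \lesssim 10$ Å the energy is constant to
~1e−13 kcal/mol, so a relaxed hydrophobic particle stops anywhere on
the plateau at the minimum energy rather than at exactly $z = 0$.
The exact-midplane kink of $|z|$ is resolved by defining the force to
vanish at $z = 0$.

The elastic network (`build_enm()`) springs every unique pair within
9 Å with $\tfrac{1}{2}k(d-d_0)^2$ and no non-bonded terms. Insertion
analytics report the centroid's signed depth, the tilt of a declared
insertion vector against the local membrane normal folded to [0°, 90°],
and the roll about that vector relative to the projection of a
declared lab axis (default +x); with fewer than three non-collinear
particles roll is undefined and reported as NA.

Solvent-accessible surface areas are Shrake–Rupley with a probe of
1.4 Å and a deterministic golden-spiral point set (960 points/atom
default; totals change by <0.5 % at 5000). Determinism matters:
calibration must be bit-reproducible. Radii are element-based
(C 1.7, N 1.55, O 1.52, S 1.8, H 1.2, P 1.8 Å).

## What the synthetic fixtures do and do not show

The generator provides toy residues with exactly known isolated-sphere
areas, ideal α-helices (1.5 Å rise, 100°/residue, one bead per
residue at ±0.03 kcal mol⁻¹ Å⁻² per-area energies — the magnitude a
leucine-like side chain reaches over a ~60 Å² bead), with either a
uniformly hydrophobic surface or faces alternating at the 3.6-residue
period, and a barrel-like hollow shell with a hydrophobic outer
mid-band. They make every stage testable offline: the hydrophobic
helix must bury in the core, the amphipathic helix must sit in the
headgroup region with its hydrophobic face down, the barrel must
stabilise core-inserted. Passing these tests shows the energy model,
geometry and samplers are wired correctly; it does *not* show the
model reproduces real partitioning data — real proteins have
conformational flexibility, heterogeneous exposure and charged
termini that the fixtures deliberately lack, and validating against
experimental structures requires externally supplied input
(`scripts/external_benchmark.R`).

## Problem sizes used by the shipped tests

Monte Carlo equilibration checks run 15 000 steps at 2 seeds for the
two 18-residue helix fixtures in a ±40 Å box, starting in contact with
the headgroup region, and locate the occupied basin by the median
|depth| of the trailing window (robust against transient water
excursions). The detailed-balance check runs 10⁵ single-particle steps
on a bounded two-state landscape plugged in through the membrane
contract. Calibration exactness is verified over 100 random 20-residue
scales on the shipped template database. Mesh cross-checks use 90 × 90 Å
planar meshes down to 1 Å spacing and a sphere of radius 100 Å.

## Known limitations

No electrostatics, lateral pressure, curvature stress, or
lipid-specific energetics (the lipid presets change the *geometry*
only — re-parameterising $E_{tr}$/$a_{lip}$ per lipid would need a
consistent set of lipid-specific transfer measurements). Mixed-lipid
membranes and membrane undulation dynamics are out of scope. The
mesh depth is vertex-based (nearest vertex, not nearest point on the
triangulated surface): at coarse resolutions the `euclidean` mode
inherits the corresponding error, which is the object of the
resolution benchmark rather than a defect to hide.
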