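---
title: "Methods: building-block prediction of protein electrical properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building-block prediction of protein electrical properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockpol)
```

# Overview

`blockpol` reconstructs the dipole moment and dipole polarizability of a
protonated protein from per-fragment database entries, then corrects them
for two environmental effects: fractional charges on ionizable groups at a
chosen pH, and polarization by nearby ions and waters through a damped
dipole interaction model.  All physics is carried out in atomic units
(dipoles in e·bohr, polarizabilities in bohr³, fields in Eₕ/(e·bohr));
coordinates cross the PDB boundary in ångström (1 Å = 1.8897259886 bohr).

This vignette documents the model, the parameter choices, the synthetic
inputs used for testing, and the numerical decisions a maintainer would
want to know about.

# Structure decomposition

Residues are split into *building blocks*: one backbone unit (N, H, Cα,
Hα, C, O), one side-chain unit (all remaining atoms; glycine has none),
plus one NTER block (the –NH₃⁺ nitrogen and its hydrogens, taken from the
first residue) and one CTER block (C, O, OXT of the last residue) per
chain.  The blocks partition the atom set exactly, which the test suite
asserts on every fixture.  The true fragmentation used by quantitative
per-fragment databases is defined by quantum-topological partitioning in
their own reference literature; the backbone/side-chain/terminal scheme
here is a documented stand-in with the same granularity, and the `db_key`
mapping is the extension point for finer schemes.

Point charges are placed at a block's centre of "mass" with masses replaced
by atomic numbers, `Σ Zᵢrᵢ / Σ Zᵢ` — heavier atoms dominate the placement.
Alternate conformers are reduced to the highest-occupancy one so a given
file always yields one deterministic geometry.

# The block database

Each entry stores a dipole vector and a symmetric positive-definite 3×3
polarizability tensor in a *local frame* anchored on three named atoms of
the block; placement builds a Gram–Schmidt rotation (axis 1 along
atom1→atom2, axis 2 in the atom1/2/3 plane) and rotates both properties
into the global frame, preserving tensor eigenvalues.  The two
terminal-residue backbone blocks lack the generic (N, CA, C) anchors —
their N or C moved into a terminal block — so the pipeline anchors those
two on the block's first three non-collinear atoms instead;
`place_entry()` itself keeps the strict contract and errors on missing
anchors.

No quantitative per-fragment entries are published for this method, so the
shipped database is synthetic and seeded (`synthesize_db()`):

* tensors are random SPD with mean eigenvalue `base_iso` × (heavy-atom
  count) and eigenvalue spread set by `anisotropy_frac`;
* `base_iso` defaults to 11 bohr³ per heavy atom, a typical in-molecule
  heavy-atom polarizability scale; it puts a 29-residue helix near
  α_iso ≈ 2.2×10³ bohr³, the right order of magnitude for a peptide of
  that size;
* `anisotropy_frac` defaults to 0.3 (moderately anisotropic fragments);
* dipoles point along the block's first frame axis with magnitude
  U(0.5, 2) e·bohr, i.e. O(1) a.u. fragment dipoles.

The JSON format (sorted keys, 12 significant digits) round-trips
byte-for-byte, and loading validates symmetry and positive
semi-definiteness per entry.  Synthetic values exercise every vector and
tensor pathway but carry no chemical information: agreement of magnitudes
with any particular measured protein is out of scope by construction.

# Protonation model

Fractional charges follow the Henderson–Hasselbalch ionized fraction,

* acidic: `q = −1 / (1 + 10^(pKa − pH))`
* basic:  `q = +1 / (1 + 10^(pH − pKa))`

with the built-in pKa table: GLU/ASP 4.4, CYS 8.5, TYR 10.1 (acidic); ARG
12.5, LYS 10.6, HIS 6.6 (basic); C-terminus 4.0, N-terminus 8.0.  Terminal
groups are a special case: database entries describe the zwitterion
(–NH₃⁺/–COO⁻), so terminals receive the *compensating* charge
`q_applied = q_effective − q_zwitterion` (q_zwitterion = +1 for NTER, −1
for CTER) — an N terminus at effective +0.6 gets −0.4 applied.  This is why
the bookkeeping signs of the terminals look inverted relative to their
chemistry.

The isoelectric point bisects the net charge (true chemical signs,
terminals included as ordinary acid/base groups) over pH 0–14 to
|net| < 1e-9; the net charge is strictly monotone in pH so the root is
unique.  With the built-in table, the glucagon-like composition (3 ASP,
2 TYR, CTER; 2 ARG, 1 LYS, 1 HIS, NTER — 11 groups) titrates to pI = 7.30;
at that pH the HIS (+0.166) and NTER (−0.166 applied) fractions cancel
exactly because their pKa values sit symmetrically about 7.3.

In `mode = "standard"` no charges are applied at all: this is the
zwitterion reference against which the database entries were defined, and
it is the baseline for environment-free predictions.

# Ions and the charge dipole

Binding criteria: Cl⁻ binds LYS, ARG or the N terminus when within 2.5 Å
of one of the group's polar hydrogens (an H–Cl bond distance); Na⁺ binds
ASP, GLU or the C terminus within 3.5 Å of a carboxylate oxygen (O–Na).
Each ion binds at most one residue and vice versa; conflicts resolve
greedily by smallest distance with residue-order tie-breaks, which is
deterministic and order-independent.  A bound residue is *neutralized*:
excluded from the charge dipole yet retained, with the ion, as a Coulomb
field source for the core-dipole correction.

The charge dipole is computed as `μ_charge = Q⁺·R`, with `R` running from
the |q|-weighted centroid of the negative charges to that of the positive
ones.  For a neutral set this equals `Σ qᵢrᵢ` and is origin independent —
the reason the method insists on charge-balanced NaCl additions.  When a
*terminal* is neutralized, the remaining applied charges are legitimately
unbalanced (the removed compensating charge was fractional); `Q⁺·R` is
still origin independent, and the pipeline therefore disables the
neutrality warning that the standalone `charge_dipole()` emits by default
above |Σq| = 0.01 e.

Core dipoles are corrected per block, `μ_Ω = μ⁰_Ω + α_Ω·F_Ω`, with `F`
the superposed bare-Coulomb field (`q/r²`, atomic units) of every charge
except the block's own, evaluated at the block's charge centre.  Fields
from charges never alter the polarizability tensors — an invariant the
tests assert bitwise.  Unbound ("far") ions contribute to these fields by
default (`include_far_ion_fields`), and are *also* polarizable sites in
the interaction model below; the flag exists to ablate the double role.

# Ion-pair configurations

With four canonical cation sites (A–D: the three ASP plus CTER) and four
anion sites (X, Y, Z, W: LYS, the two ARG, NTER), charge balance restricts
arrangements to equal-sized subsets: `Σₖ C(4,k)² = 70` configurations.
Names concatenate the sorted Na letters padded with `-` to width 3 and the
sorted Cl letters likewise (`AC-ZW-`); the empty and full cases are
`standard` and `ABCDXYZW`.  Numbering is 1 (standard), 2–17 (one pair),
18–53 (two), 54–69 (three), 70 (full), lexicographic within each class —
the class ranges are fixed by the combinatorics, the within-class order is
this package's convention and can be remapped externally if a different
published ordering must be matched.  `sweep_configurations()` reruns the
full prediction for each subset of the eight placed ions; all 70 runs share
one configuration, including the charged mode, so the zero-ion row is the
charged, ion-free prediction (the zwitterion reference remains available
as `mode = "standard"`).

# Environment cutoff

Waters are kept only inside the minimum-volume enclosing ellipsoid of the
protein atoms grown by `cutoff` (default 8 Å) along each semi-axis; ions
are kept unconditionally, wherever they are, to preserve charge balance.
The MVEE is solved as the dual D-optimal design problem with a
Khachiyan-type first-order iteration, accelerated by Wolfe–Atwood away
steps (linear convergence, so the 1e-6 relative-gap tolerance is
practical) and Harman–Pronzato elimination of provably interior points.
Coplanar/degenerate geometries fall back to a bounding sphere around the
centroid.  Containment at the boundary is exact only to the solver
tolerance; the monotonicity guarantee (a smaller cutoff never keeps more
waters) holds because the same fitted ellipsoid is inflated per call.

# Dipole interaction model

Every interaction site (protein block at its charge centre; each ion; each
water as a single site at its oxygen) carries a tensor α and permanent
dipole μ⁰ (zero for environment sites).  The undamped dipole field tensor
is `T = (3r̂r̂ᵀ − I)/r³`.  Sites within the same molecule do not interact —
intra-protein coupling is already folded into the database entries — so an
environment-free protein returns its database properties unchanged, and
all computed changes are attributable to the environment.

Short-range screening uses the scaled distance
`u = b·r/(α_iso,Ω · α_iso,Λ)^(1/6)` with `b = 2.6` (the commonly used
polarizable-force-field value).  The default scheme multiplies `T` by

`S(u) = 1 − (1 + u + u²/2 + u³/6)·e^(−u)`,

the exponential (Thole-style) screening: S is monotone, reaches 1 to
better than 1e-10 for u > 40, and behaves as u⁴/24 at small u so the
damped tensor itself vanishes (linearly in r) at contact — no polarization
catastrophe.  The Drude-literature factor `1 − (1 + u/2)e^(−u)` is
available as `damping = "drude_exp"`; it screens more weakly (S ~ u/2), so
the damped tensor still grows as 1/r² at very short range — which is why
it is not the default here — and a piecewise `thole_linear` variant and
`none` complete the strategy set.  Both exponential factors are evaluated
through their exact series remainders at small u; the naive
`1 − (...)e^(−u)` form loses all significant digits below u ≈ 1e-4.
Sites with zero isotropic polarizability are exempt from damping (they
behave as bare point sites).

The mutual-induction equations `μ_ind = α(F_ext + T(μ⁰ + μ_ind))` are
solved by one dense factorization of the relay system
`B = (A⁻¹ − T)⁻¹` (A block-diagonal in the site tensors): induced dipoles
are `B(F_ext + Tμ⁰)` and the environment-corrected polarizability of site
Ω is the row sum `Σ_Λ B_ΩΛ`; the system tensor is the grand sum,
symmetrized after asserting its asymmetry is below 1e-8.  Permanent block
dipoles act as field sources on other sites by default
(`include_permanent_dipoles`).  Dense solves are appropriate at the
intended scale (hundreds to a few thousand sites); a singular system —
possible only at unphysical geometries or with damping off — raises an
error advising a larger `b`.  Sites with an exactly zero tensor are
removed from the relay and passed through uncorrected.

The implementation is verified against independent routes: explicit
supermatrix inversion and damped fixed-point iteration for the induced
dipoles; the finite-difference response `d(Σμ)/dF` under a uniform field
and the two-site closed form (α∥ = 2α/(1 − 2α/r³), α⊥ = 2α/(1 + α/r³))
for the corrected polarizabilities.

# Pipeline order and reported quantities

`run_prediction()` fixes the stage order: (1) pH charges and ion
neutralization → μ_charge; (2) Coulomb-field correction of the core
dipoles; (3) ellipsoid water cutoff; (4) the interaction-model solve over
blocks + environment; (5) totals.  There is no iteration between stages —
the correction is a single pass.  Reported:

* `mu_total = mu_charge + mu_core` (exact additivity, asserted);
  `mu_core` sums the protein blocks' corrected-plus-induced dipoles.
* `alpha_total` sums the corrected tensors of the protein blocks *and any
  bound ions* — a bound Cl⁻ contributes its ~30 bohr³, matching the
  physical picture of the ion pair as part of the coordinated compound;
  free ions and waters are environment only.
* `alpha_iso = Tr(α)/3` and the first anisotropy invariant
  `Δα = sqrt(((α₁−α₂)² + (α₂−α₃)² + (α₃−α₁)²)/2)` over the eigenvalues,
  both rotation invariant; eigenvalues are reported ascending, with the
  largest aligning with the long molecular axis for elongated systems.

# Synthetic fixtures: what they emulate and what they do not

`make_fixture()` builds ideal-geometry α-helical peptides (φ = −57°,
ψ = −47°, canonical backbone bond lengths/angles via internal-coordinate
chain construction) with all hydrogens; side chains are laid out
procedurally with correct atom names and plausible bond distances rather
than rotamer-accurate geometry.  The `saltbox` kind reproduces the
glucagon-like ionizable composition — basic groups near the N terminus,
the three ASP near the C terminus — and coordinates one ion at every
canonical site, at 2.1 Å (Cl···H) and 2.3 Å (Na···O) by default, inside
the binding thresholds.  Waters are scattered in a deterministic seeded
shell (2.8–5.5 Å from random surface atoms).

Passing tests on these fixtures demonstrates the correctness of the
machinery — decomposition, charge assignment, binding logic, field sums,
the induction algebra, the combinatorics — and the *direction* of the
physical trends (e.g. the mean |μ| across the 70-configuration sweep is
non-increasing in the number of bound pairs, because each pair removes a
± charge from well-separated centroids).  They do not demonstrate
quantitative accuracy for real proteins: that requires the real fragment
database and reference geometries, which are out of scope here.

# Problem sizes and defaults

The shipped tests and the acceptance script run a 29-residue, 60-block
fixture with 8 ions (and a 14–15-residue variant for unit tests); the full
70-configuration sweep at that size takes on the order of ten seconds.
Key defaults: pH 7.3; b = 2.6; cutoff 8 Å; thresholds 2.5/3.5 Å; ion
polarizabilities Na⁺ 0.3, Cl⁻ 30, water 9.8 bohr³ (isotropic, all
overridable in `run_config()`).

# Known limitations

* The fragmentation and every database number are synthetic stand-ins;
  only structure and scale are realistic.
* pKa values are intrinsic (no structure-based shifts or coupled-site
  titration); hydrogens must be present in the input (no protonation
  engine).
* Fields are evaluated at block centres, not per atom (a per-atom mode is
  a possible extension point; the choice matters only at close range).
* No periodic boundary conditions, no quadrupole or charge-flow terms in
  the interaction model.
* The within-class ordering of configuration numbers 2–69 is a package
  convention.
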