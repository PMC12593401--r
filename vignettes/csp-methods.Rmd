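---
title: "Methods: desk-scale crystal structure prediction with surrogate potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale crystal structure prediction with surrogate potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cspkit)
```

`cspkit` implements the stages of a machine-learning-potential crystal
structure prediction (CSP) workflow as independent, testable components.
This vignette records the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic fixtures do and do
not demonstrate. Internal units are Å, eV, amu and K throughout; relative
lattice energies are reported in kJ/mol **per molecule** via
1 eV = 96.48533 kJ/mol (the per-molecule convention is an explicit choice —
per-cell numbers would differ by a factor of Z — and is flagged in the
landscape tables).

## Structure generation

A candidate crystal is built by sampling a unit cell with a volume drawn
from a ±15 % window around a van-der-Waals-sphere estimate
(`estimate_volume()`, packing coefficient 0.55 — a typical value for
organic molecular crystals), placing one rigid molecule at a random
fractional position with a uniform random orientation (normalized
quaternions), and replicating it with the general-position operators of the
requested space group. The supported groups — P1, P-1, P21, P21/c, C2/c,
P212121, Pna21, Pbca — cover the most common molecular-crystal groups;
special Wyckoff positions are out of scope, so Z must be a multiple of the
general-position multiplicity. Candidates are screened by the
close-contact criterion: an intermolecular atom pair is physical only if
its minimum-image distance exceeds `s_r` times the sum of the two van der
Waals radii, with `s_r` between 0.7 and 0.9 (default 0.8). A pair of sites
belonging to the same molecule is exempt only at the single periodic image
consistent with the unwrapped molecule; contacts of a molecule with its own
periodic copies are screened like any other intermolecular contact.

The **rigid press** stage first expands the accepted cell isotropically
(default factor 1.6) and then compresses it: the outer loop shrinks the
cell by a strain step (starting at 4 % per axis, halved on failure, stopping
below 0.1 %), and after each shrink a gradient descent with backtracking
drives the smooth overlap penalty Σ max(0, s_r(r_A + r_B) − d)² back to
zero over molecular translations, rotations and the *traceless* part of the
cell strain. Projecting out the isotropic strain is essential: otherwise
the steepest way to relieve an overlap is simply to undo the compression.
Molecules move as rigid bodies, so internal geometry is preserved to
round-off; space-group symmetry is deliberately *not* preserved. The result
is a jammed packing: re-pressing an exactly contact-limited crystal changes
its volume by well under 1 %.

## Cluster sampling

`molecular_shell()` returns every whole, unwrapped molecule (including
distinct periodic images of the same molecule) with any atom within a
cutoff of any atom of the central molecule. `enumerate_nmers()` builds
n-mers (n = 1–8) as the central molecule plus (n−1) shell members: the
first combination takes the nearest members by minimum intermolecular
atom–atom distance — centroid distance was rejected because it misorders
elongated molecules — and further combinations are random without
replacement, deterministically per seed. `tethered_sampling()` runs BAOAB
Langevin dynamics with a per-atom harmonic tether (default
k = 0.005 eV/Å², 300 K, 1 fs timestep, friction 0.01 fs⁻¹, every 100th
frame kept) and no bond constraints. The timestep must resolve the fastest
oscillation (ω·dt ≲ 0.2); probing stiff tethers of ~10³ eV/Å² therefore
requires dt ≈ 0.05 fs, which the tests use.

## Energy models

All models implement one Calculator contract (`calc_eval()`): energy,
forces (= −∇E), and stress (dE/dε / V), with central-difference fallbacks
when an analytic derivative is unavailable. Pair potentials
(Lennard-Jones, Buckingham, harmonic springs) sum over **all lattice
images** within the cutoff rather than a single minimum image — the image
sum is what makes a 2×1×1 supercell exactly twice the cell energy, an
invariant the test suite enforces at 10⁻¹⁰ relative. Ewald summation uses
the standard real/reciprocal/self split; the splitting parameter is derived
from the accuracy target (default 10⁻⁸) and the 15 Å real-space cutoff, and
when a splitting parameter is supplied explicitly the cutoffs are rederived
from the accuracy so the result is splitting-independent to ~10× the
accuracy. Two-body dispersion uses Becke–Johnson-style rational damping
−C6/(r⁶ + r0⁶) and participates in optimization; the Axilrod–Teller–Muto
three-body term C9(3cosθᵢcosθⱼcosθₖ + 1)/(rᵢⱼ rⱼₖ rₖᵢ)³ is evaluated only
as a single-point correction on final geometries, with user-supplied
uniform or per-triple C9 (ab initio coefficient generation is out of
scope).

The trainable surrogate is a linear regression over smooth radial
descriptors: per neighbour element, sums of Gaussians (8 centres spanning
0.5 Å to the 5 Å environment cutoff) times a cosine cutoff function, which
makes predictions exactly invariant to rotation, translation and atom
permutation and lets energies decompose into atomic contributions. The
training loss combines per-atom-weighted energies with force residuals
(weight 0.1) through analytic descriptor gradients, solved as ridge
regression (penalty 10⁻⁸), so training is deterministic. This is the
minimal model that honours the workflow structure — atomic energy
contributions, a 5 Å receptive field, an ensemble of 4 — while remaining
desk-fast; the Calculator contract keeps a real neural potential pluggable.

Flexible-molecule teachers combine `pair_potential(...,
intermolecular_only = TRUE)` with `bond_calculator()` harmonic bonds: a
plain Lennard-Jones term between covalently bonded atoms at ~1.1 Å would
dwarf every other energy scale.

## Active learning

Ensemble uncertainty is σ = sd(E₁…E₄)/√N with the *sample* standard
deviation (ddof = 1; the convention had to be fixed somewhere) and N the
atom count. Selection takes exactly {i : σᵢ > 2·median(σ)} with a strict
inequality, the median taken per n-mer order over that order's full pool.
Ensemble diversity comes from training each member on an independent 80 %
random subset. One selection pass is made per order, ascending, labeling
selected geometries with the teacher and retraining all members.
`al_vs_random_benchmark()` packages the study design used by the tests: a
flexible-diatomic teacher, 40 perturbed monomers, pools of 200 dimers and
100 trimers in which 80 % are weakly interacting (closest contact
4.5–8 Å) and 20 % are close contacts (3.0–3.8 Å), and a 60-cluster
hold-out spanning 3–6 Å. The heterogeneous pool is the realistic feature
that matters: uncertainty selection earns its keep by finding the
informative minority. Note one degeneracy the tests document: beyond the
5 Å descriptor cutoff all ensemble members coincide by construction, so
uncertainties evaluated there are spuriously small; uncertainty-based
probes should stay inside the model's receptive field.

## Relaxation, symmetrization, deduplication

`relax()` is BFGS with an Armijo backtracking line search over fractional
positions and a symmetric cell strain (so atomic and cell moves share one
quasi-Newton state). Convergence requires RMS atomic force ≤ 0.001 eV/Å
and, in cell modes, max |σ + pI| ≤ 10⁻⁶ eV/Å³ — tight because soft van der
Waals crystals (bulk moduli ~0.02 eV/Å³) need residual stresses of ~10⁻⁶
to pin lattice constants to ~10⁻³ Å. Fixed-volume mode projects the
isotropic component out of the strain gradient and renormalises the
determinant exactly each step. External pressure enters the objective as
+pV.

`symmetrize()` has an honest, narrow contract: it tests each whitelisted
group's operator set (plus the full 192-operation face-centred cubic set,
which recognises the fcc fixture) for invariance of the site list at
`symprec` (default 0.2 Å), with an origin-shift search, and orbit-averages
the sites of the richest matching group. The averaging is iterated to its
fixed point so the operation is strictly idempotent, and it falls back to
P1. It is not a general space-group finder — structures outside the
whitelist are reported as P1.

`structures_match()` Niggli-reduces both lattices (Krivy–Gruber), scans the
signed axis permutations whose metric matches within the fractional length
tolerance (0.2) and angle tolerance (5°), and for each candidate runs a
translation search (site-alignment seeds plus a coarse 0.25 grid, refined
by recentring on the mean displacement) with greedy species-aware
nearest-neighbour assignment; a match requires site RMS ≤ 0.2 Å in both
directions. Duplicate removal takes the transitive closure and keeps the
lowest-energy member of each cluster when energies are supplied (first
seen otherwise) — so cluster membership is order-invariant but the
representative can differ without energies.

## Phonons and free energies

Force constants couple the reference-cell atoms to every atom of the
smallest supercell whose lattice vectors all reach 10 Å, computed from the
analytic Hessian when the calculator provides one and otherwise by central
finite displacements of 0.005 Å; the two routes agree to 10⁻⁴ eV/Å² on the
fixtures. The translational acoustic sum rule is enforced on the self
blocks — except for deliberately translation-breaking models (Einstein
site tethers), for which `asr = FALSE` preserves the physical flat
spectrum. The dynamical matrix at a wave vector uses minimum-image cell
offsets with ties split evenly, which is exact whenever the interaction
range is under half the supercell; the 1-D chain fixture reproduces
ω(q) = 2√(k/m)|sin(qa/2)| to 10⁻⁸ relative at arbitrary q.

The q-mesh is Γ-centred with uniform weights and no symmetry reduction
(correctness over speed at this scale); the conventional production mesh
is 8×8×8, and the packaged studies use 3×3×3 or 4×4×4 meshes, which the
convergence behaviour of the toy fixtures comfortably supports. Modes with
|eigenvalue| below 10⁻¹⁰ eV/(Å² amu) are treated as numerical zeros;
imaginary modes either raise an error (strict policy) or drop the affected
volume point from the quasi-harmonic scan (the scan default, logged) — the
choice is configurable because no single policy suits both diagnostics and
production scans.

The quasi-harmonic scan relaxes the structure at zero pressure, then for
each volume factor runs a fixed-volume variable-cell relaxation, computes
the spectrum, and forms F(T,V) = U(V) + F_vib(T,V). The default factor
grid is 0.95 to 1.15 in steps of 0.0125 — an inclusive 17-point grid; the
16-point count sometimes quoted for this window with this step does not
close the endpoint, so the factor list is exposed explicitly and the
17-point grid kept as default. Per temperature the F–V points are fitted
to the third-order Birch–Murnaghan form (Nelder–Mead then BFGS from a
quadratic-fit start; exact synthetic data round-trip to 10⁻⁶ relative);
G(T,p) is the fitted minimum plus pV and V(T) the argmin. At p = 0 the
Helmholtz and Gibbs energies coincide, which is how the ranking is run.
C_p = −T ∂²G/∂T² by central differences on a uniform 10 K grid (one-sided
at the endpoints, exact for quadratic G).

Two fixture choices deserve a note. The room-temperature expansion study
uses a Lennard-Jones fcc solid with ε = 0.1 eV (ε/k_B ≈ 1160 K): a
rare-gas ε of ~0.01 eV melts far below 300 K and has no free-energy
minimum in the scanned volume window at that temperature, so a deeper well
is the physically meaningful stand-in for a molecular crystal stable at
room temperature. The zero-thermal-expansion control couples an Einstein
crystal (volume-independent frequencies) to a volume-only equation-of-state
term (`eos_calculator()`), for which V(T) must be exactly constant.

## Ranking and comparison

Landscape tables convert per-molecule energies to kJ/mol above the global
minimum, sorting ascending with ties broken by structure id. Agreement
statistics are MAE, RMSE, and Kendall's τ-b (tie-aware, computed from the
O(n²) definition; `stats::cor` serves as an independent cross-check in the
tests). The matched fraction applies the duplicate-removal criterion to
paired relaxed/reference structures. `cluster_rmsd()` approximates
cluster-overlay similarity: shells of up to 15 molecules (configurable;
full 30-molecule overlays are supported but the toys are small), greedy
centroid-based molecule correspondence after centring, Kabsch least-squares
superposition over matched atoms with hydrogens excluded by default, and
the larger of the two directed values reported since greedy matching is
not perfectly symmetric. These values are comparable in spirit, not
numerically, to proprietary packing-similarity tools.

## What the fixtures show — and what they do not

The synthetic fixtures (`make_fixture()`) have closed-form references:
fcc geometry at the pair-optimum spacing, the rocksalt Madelung constant,
Einstein and 1-D-chain spectra, exact Birch–Murnaghan curves. Passing
tests therefore demonstrate the *machinery* — sums, derivatives,
transforms, selection rules, bookkeeping — at tight tolerances. They do
not demonstrate chemical accuracy for real organic crystals: toy teachers
are two-body, molecules are diatomics, conformational flexibility and
long-range electrostatics of polar organics are not represented, and the
descriptor-regression surrogate is far less expressive than a neural
potential. The package's claim is that each stage is correct and the
interfaces are production-shaped, so that a real potential and real
molecules can be substituted without restructuring.

## Package shape

The core objects (crystals, calculators, force constants, spectra) are
plain S3 with base-R internals, matching how structural simulation
packages are written; tabular results (landscape tables, thermodynamic
summaries, AL histories) are returned as tibbles and plotted with ggplot2,
which is where a data-frame-first interface genuinely fits.

## Known limitations

General positions only (no Wyckoff machinery); the symmetry detector is a
whitelist, not a general finder; no LO–TO splitting or anharmonic
corrections; rigid press does not preserve space-group symmetry; greedy
molecule matching in `cluster_rmsd()` can mispair molecules when shell
membership flips near the cutoff; desk-scale throughput (10²–10⁴
structures, not 10⁶).
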