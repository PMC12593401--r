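# cspkit

Crystal structure prediction (CSP) for molecular solids asks: given a
molecule, which periodic packings are thermodynamically plausible, and in
what order of stability? `cspkit` implements a desk-scale version of the
modern machine-learning-potential CSP workflow for R users — computational
chemists and method developers who want every stage of the pipeline to be a
testable, composable function rather than a cluster job:

1. **Generation** — random symmetry-constrained packing of a rigid molecule
   on the general positions of common space groups, screened by the
   van der Waals close-contact rule *d*<sub>A,B</sub> >
   *s*<sub>r</sub>(*r*<sub>A</sub> + *r*<sub>B</sub>) with the specific
   radius ratio *s*<sub>r</sub> ∈ [0.7, 0.9], followed by a rigid-body
   compression stage ("rigid press") that densifies loosely placed cells.
2. **Cluster sampling** — molecular shells and *n*-mers (*n* = 1–8)
   extracted from candidate crystals, diversified by tethered Langevin
   dynamics (harmonic tethers, default 0.005 eV/Å², 300 K, no bond
   constraints).
3. **Active learning** — a 4-member ensemble of descriptor-regression
   surrogate potentials; per *n*-mer uncertainty σ = sd(E)/√N, selection of
   σ > 2·median(σ), teacher labeling, retraining, iterating order by order.
4. **Energy models** — a pluggable Calculator contract with Lennard-Jones /
   Buckingham / harmonic pair potentials, point-charge Ewald summation
   (accuracy 10⁻⁸, 15 Å real-space cutoff), Becke–Johnson-damped two-body
   dispersion, and the Axilrod–Teller–Muto three-body correction applied as
   a final single point.
5. **Relaxation** — BFGS with backtracking over positions plus a symmetric
   cell strain (RMS force tolerance 0.001 eV/Å), fixed-volume variable-cell
   mode for the quasi-harmonic scan, whitelist symmetrization (symprec
   0.2 Å) and duplicate removal (site tolerance 0.2 Å, length 20 %,
   angle 5°).
6. **Free-energy ranking** — harmonic phonons from analytic or
   finite-displacement (0.005 Å) force constants on ≥ 10 Å supercells,
   F<sub>vib</sub> = Σ<sub>q,i</sub> [ħω/2 + k<sub>B</sub>T ln(1 −
   e^(−ħω/k<sub>B</sub>T))], the quasi-harmonic approximation over a
   0.95–1.15 volume scan (17 points, step 0.0125) with third-order
   Birch–Murnaghan fitting, G(T,p) = min<sub>V</sub>[U(V) +
   F<sub>vib</sub>(T,V) + pV], and C<sub>p</sub> = −T ∂²G/∂T².
7. **Reporting** — energy–density landscapes (kJ/mol per molecule above the
   global minimum), MAE/RMSE/Kendall-τ agreement statistics, and a
   molecular-cluster RMSD between crystal packings.

Everything runs on packaged synthetic fixtures (Lennard-Jones fcc, rocksalt
ions, Einstein crystals, 1-D chains, flexible-diatomic toy crystals) with
known closed-form reference values, so the whole workflow is exercised end
to end in minutes on one CPU.

## Worked example

Generate toy diatomic crystals, relax them with a molecular teacher
(intermolecular Lennard-Jones + harmonic bonds), deduplicate and rank:

```r
library(cspkit)
man <- run_pipeline(n_structures = 10, seed = 3)
man$stages$rank$landscape
#> # A tibble: 8 × 5
#>   structure_id density   E_rel  rank space_group
#> 1            2   1.18  0           1           1
#> 2            1   1.18  3.26e-9     2           1
#> 3            5   1.23  3.33e+0     3           1
#> 4            8   1.20  3.49e+0     4           1
#> ...
```

Ten random candidates relax into 8 distinct packings; two pairs found the
same minimum (duplicates merged, E_rel agreeing to ~10⁻⁹ kJ/mol). `E_rel`
is the lattice energy per molecule above the best structure in kJ/mol and
`density` is in g/cm³ — the axes of the usual CSP landscape
(`plot_landscape(...)` draws it).

The physics layers can be used directly; for example the Ewald module
recovers the rocksalt Madelung constant from the computed lattice energy:

```r
rs <- make_fixture("rocksalt_ions")
-ewald_energy(rs)$energy * attr(rs, "reference")$d_nn /
  (csp_constants$coulomb * 4)
#> [1] 1.747565
```

A thin command-line front end with `generate`, `relax`, `rank`, `qha` and
`pipeline` subcommands is installed at `inst/cli/cspkit`.

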