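---
title: "Converting ssRNA aptamer models to ssDNA: methods and design notes"
author: "aptaconv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting ssRNA aptamer models to ssDNA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptaconv)
```

## The problem

RNA aptamers selected by cell-SELEX recognize their targets through their
three-dimensional fold, but single-stranded RNA is chemically fragile and
rapidly degraded by ribonucleases. A pragmatic route to a more stable
reagent is to convert a selected ssRNA aptamer into its ssDNA analogue
*in silico*, starting from a 3D model of the RNA and editing the
chemistry while leaving the fold untouched, and then to ask with
molecular-dynamics descriptors whether the DNA analogue retains the
parent conformation. `aptaconv` implements that workflow's two
computational kernels:

1. **structure editing** — an atomically exact ssRNA to ssDNA conversion
   of a 3D model, and
2. **conformational descriptors** — superposition RMSD time series and
   intramolecular hydrogen-bond counts over trajectories, with summary
   and plateau-onset analysis,

plus the supporting machinery each needs: PDB/GRO I/O with naming-dialect
handling, an idealized-helix fixture generator with known ground truth,
and emission of the MD protocol as GROMACS-style parameter files.

## The conversion algorithm

Chemically, ribose differs from deoxyribose by the 2'-hydroxyl, and
uracil differs from thymine by the C5 methyl group. The conversion
therefore needs exactly three sequential edits, applied by
`convert_structure()` in this order:

1. `strip_2prime_hydroxyl()` deletes `O2'` (and its hydroxyl hydrogen if
   hydrogens are present) from every residue. Nothing else is touched.
2. `methylate_uracil()` replaces the uracil `H5` (deleted when present)
   with a methyl carbon `C7`, converting the base into thymine.
3. `rename_to_dna()` maps the residue codes A/C/G/U to DA/DC/DG/DT. It
   refuses to run on any residue that still carries an `O2'`, so the
   pipeline order is enforced.

The central invariant is **conformation preservation**: no retained atom
ever moves. Both deletions and the renaming are coordinate-neutral, and
the methyl construction only *adds* atoms, so the coordinates of every
atom present in both input and output are bit-identical and the
superposition RMSD over shared atoms is exactly zero. The test suite
asserts this with `identical()` on the coordinate matrices, not with a
tolerance.

### Methyl construction geometry

The methyl carbon is placed from heavy atoms only — C4, C5, C6 — so
hydrogen-free models (the usual output of structure-prediction servers)
convert identically to hydrogenated ones:

* direction: the exterior bisector of the C4–C5–C6 angle (the position
  H5 occupied), projected into the best-fit plane of the pyrimidine
  ring;
* distance: `c5_c7_bond` = 1.50 Å, the standard thymine value;
* if the ring deviates from planarity by more than `coplanarity_tol`
  (0.15 Å) a warning is emitted and the best-fit plane is still used.

All four geometric parameters live in `methyl_geometry()` (bond lengths
in Å, angle in degrees) because the conversion protocol itself fixes no
geometry — these are conventional stereochemical values, not fitted
quantities. When (and only when) the parent residue carries hydrogens,
three methyl hydrogens `H71`/`H72`/`H73` are added at `c_h_bond`
= 1.09 Å, tetrahedrally, staggered relative to C5–C4. Adding isolated
methyl hydrogens to an otherwise hydrogen-free model would produce a
mixed topology that downstream MD tooling rejects, which is why the
hydrogens are conditional.

### Validation

`validate_dna()` checks the product against idealized residue templates
(`residue_templates()`): heavy-atom inventory per residue (5'-terminal
residues may lack the phosphate), absence of any `O2'`, the C5–C7 bond
in (1.3, 1.7) Å, intra-residue bond lengths within ±0.25 Å of template
values, and backbone O3'–P links in (1.4, 1.9) Å. Findings are reported,
not raised; `strict = TRUE` (or `--strict` on the command line) turns
failures into errors. The `ConversionReport` records every removed,
added and renamed entity and serializes to JSON via `report_to_json()`.

### The truncated published DNA string

The published DNA version of the second aptamer (57 nt) omits one
U-derived triplet relative to its 60-nt parent. `convert_sequence()` is
deliberately strict — same length in, same length out, every U becomes a
T, residues are never deleted — because an unexplained deletion is not a
chemistry-preserving operation. The package ships both printed strings
(`aptamer_sequences()`); the strict conversion of the parent therefore
*differs* from the printed 57-nt string, and the tests pin down exactly
where (one `CCT` triplet).

## Trajectory descriptors

### Superposition RMSD

`kabsch_superpose()` solves the weighted orthogonal Procrustes problem
via SVD of the weighted covariance matrix, with the determinant
correction that excludes reflections, and reports

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{\sum_i w_i}\textstyle\sum_i w_i\,
  \lVert R\,x_i + t - y_i\rVert^2}.$$

Degenerate inputs (fewer than 3 atoms, collinear point sets) are
rejected. The implementation is verified in the tests against an
independent quaternion-method oracle (Horn's 4×4 key-matrix
eigendecomposition) on a thousand random instances, to 1e-6.

`rmsd_series()` superposes every frame onto a fixed reference structure
(by default the trajectory topology; a flag-equivalent argument selects
any reference) over an atom selection, with mass weighting by default —
the convention of standard MD analysis tools. Output is in **nm**;
per-run summary tables in this field print RMSD values whose magnitudes
(0.5–1.7) are only consistent with nanometres, so nm is the package-wide
series unit.

For a trajectory that is the reference plus i.i.d. Gaussian noise of
standard deviation σ per coordinate, the pre-fit expectation of the RMSD
is σ√3; the rigid-body fit absorbs 6 of the 3N degrees of freedom,
giving the corrected expectation σ√3·√(1 − 6/(3N)). The tests and the
acceptance script verify the recovered mean against this closed form
(within 5%) and against the same-seed quaternion recomputation
(exactly), on 200 frames of a ~1200-atom helix — sizes chosen so the
whole suite runs in seconds while keeping the Monte-Carlo error well
under the tolerances.

### Hydrogen bonds

`find_hbonds()` uses the geometric criterion of the common MD toolchain:
donor–acceptor distance ≤ 0.35 nm and hydrogen–donor–acceptor angle
≤ 30°, donors being N/O atoms with a covalently attached hydrogen and
acceptors any N/O. Covalent bonds are inferred once per topology by
distance (heavy–heavy < 1.8 Å, H–heavy < 1.25 Å); pairs separated by two
covalent bonds or fewer are excluded, the standard way of removing
trivially "bonded" neighbours from the count. Both thresholds are
configurable in `hbond_criteria()`.

Models without hydrogens cannot support the angle term, so
`heavy_only_mode` provides a clearly labelled proxy: donor–acceptor
pairs ≤ 0.32 nm, donors taken from the residue-template classification
(e.g. guanine N1/N2, cytosine N4, the ribose O2'). Proxy counts are
never comparable to hydrogen-aware counts and the series label says so.

### Summaries and plateaus

`summarize_series()` computes the arithmetic mean and sample SD
(n−1 denominator) over frames with time ≥ `discard_before`; the default
of 0 discards nothing, since published per-run tables do not state an
equilibration cutoff. `compare_runs()` arranges several summaries into
the familiar molecule × temperature grid with H-bond and RMSD columns.

`detect_plateau()` declares a plateau at the earliest time t such that
*every* sliding window from t to the end of the series has
least-squares slope magnitude ≤ `slope_tol` and SD ≤ `fluctuation_tol`.
Defaults — window 20 ns, slope 0.005 nm/ns, fluctuation 0.1 nm — are
chosen so that the qualitative stabilization readings reported for
aptamer trajectories (onsets around 75–100 ns in 200 ns runs) are
*representable*; they are detection settings, not claims about any
particular molecule. The implementation is tested against an exhaustive
window-scan oracle and recovers a known 75 ns onset within one window.

## The fixture generator

No aptamer model or trajectory is deposited anywhere, so the package
generates its own ground truth:

* `build_helix()` stamps idealized nucleotide monomers along a helical
  axis (A-form defaults 32.7°/2.81 Å per residue for RNA, B-form
  36.0°/3.38 Å for DNA). Monomers are built in code from standard bond
  lengths, ring geometry and sugar-pucker torsions (C3'-endo ribose,
  C2'-endo deoxyribose, planar bases as regular polygons); the rigid
  placement relative to the axis is solved numerically, once per
  (sugar, twist, rise), so that consecutive O3'–P distances land at
  bond range (≈1.60 Å) without steric clashes. The result is
  chemically plausible and self-consistent with the validation
  templates — it is *not* a folding prediction. Helices are
  single-stranded with no base pairing, matching the single-stranded
  objects under study.
* `make_noise_trajectory()` adds seeded i.i.d. Gaussian coordinate noise
  and optional rigid drift to a reference, giving trajectories whose
  RMSD statistics have closed-form expectations.
* `make_plateau_series()` produces ramp-then-plateau series with known
  onset.
* `build_gc_pair()` places guanine and cytosine bases (with polar
  hydrogens) at standard Watson–Crick geometry by a small least-squares
  fit to the three canonical donor–acceptor distances; it is the
  positive control for the hydrogen-bond detector (exactly 3 bonds under
  default criteria).

Because the fixtures are idealized, passing tests demonstrate
*algorithmic* correctness — exact conformation preservation, correct
superposition, correct counting — not that any real aptamer is stable.
Real MD trajectories have correlated, anisotropic fluctuations that the
Gaussian generator deliberately does not emulate; nothing in the
package's statistics assumes otherwise.

## Protocol emission

`protocol_spec()` captures the simulation protocol (CHARMM27 + TIP3P,
triclinic box neutralized with Na⁺/Cl⁻, steepest-descent minimization,
100 ps NVT and NPT equilibration, 200 ns NPT production, 1.2 nm
cutoffs, PME, velocity-rescale thermostat — the GROMACS realization of
the "modified Berendsen" scheme — and Parrinello–Rahman barostat at
1 atm, runs at 300 K and 310 K). `emit_mdp()` renders each stage as a
`.mdp` parameter file whose step counts satisfy steps × timestep =
duration exactly (200 ns at 2 fs → 100,000,000 steps; 100 ps → 50,000),
and `emit_run_plan()` writes the ordered workflow. The 2 fs timestep and
the coupling constants (τ_t 0.1 ps, τ_p 2.0 ps) are conventional values
the protocol leaves unstated; the emitted file headers flag them as
assumptions. No MD engine is invoked: execution, force-field assignment
and topology generation are out of scope.

## Numerical and interface choices

* **Units.** Coordinates are Å internally (PDB native); GRO input is
  converted from nm on read; RMSD series are reported in nm; H-bond
  criteria are stated in nm.
* **Dialects.** Modern (v3: `O2'`, `OP1`, `DA`…) and legacy (v2: `O2*`,
  `O1P`, single-letter DNA codes) PDB naming are interconvertible with
  `as_dialect()`; detection is automatic on read; the mapping is a
  bijection on covered names and anything else passes through with a
  warning. Legacy single-letter codes are classified DNA on
  normalization when the residue lacks a 2'-oxygen.
* **Terminal residues.** Generated helices carry a 5'-phosphate;
  validation accepts both 5'-phosphate and 5'-OH inventories. Sugar
  stripping applies to every residue including termini.
* **Alternate locations** other than blank/'A' are dropped with a
  warning on read; single-stranded aptamer models have no alternate
  conformers.
* **Determinism.** Every stochastic generator takes a seed and is
  bit-reproducible; the helix placement optimization is deterministic
  (fixed multi-start Nelder–Mead/BFGS).
* **Command line.** `run_cli()` maps argv to an exit code (0 success, 1
  validation failure under `--strict`, 2 usage error) and is exercised
  end-to-end in the tests; `inst/cli/aptaconv` is the installed
  launcher.

## Known limitations

* The helix generator produces idealized single-stranded geometry; it
  is a fixture factory, not a substitute for secondary-structure-driven
  3D modelling of real aptamers.
* mmCIF, protein residues and binary trajectory formats (XTC/DCD) are
  not handled; trajectories enter as multi-model PDB or GRO frame
  series, and anything else should be converted upstream or adapted to
  a frame sequence.
* The heavy-only hydrogen-bond proxy trades the angle criterion for
  applicability to hydrogen-free models; its absolute counts are not
  comparable to hydrogen-aware analyses.
* Conversion covers the four canonical bases; modified nucleotides are
  out of scope.
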