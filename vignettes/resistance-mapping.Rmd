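---
title: "Mapping backbone resistance of protein surfaces by steered pulling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping backbone resistance of protein surfaces by steered pulling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The method

Protein surfaces are not mechanically uniform: some surface residues resist
local deformation of their backbone while their neighbours comply easily.
`resistmap` quantifies this with a per-residue *resistance coefficient*
obtained from constant-velocity steered pulling:

1. **Surface selection.** Residues with solvent-accessible surface area
   (SASA) strictly greater than 30 Å² are the pulling targets.  SASA is
   computed by the Shrake–Rupley method on heavy atoms with Bondi radii, a
   1.4 Å water probe and 960 deterministic spiral points per atom.
2. **Pulling geometry.** For each selected residue the SMD atom is its Cα.
   The pull direction is the unit vector from the centre of mass of all
   atoms within 4 Å of the SMD atom to the SMD atom itself, which
   approximates the outward local surface normal.  All atoms within 13 Å of
   the SMD atom move freely; Cα atoms outside that zone are held fixed;
   other atoms outside it are unrestrained.
3. **Constant-velocity pulling.** A virtual dummy atom starts at the SMD
   atom and moves along the pull direction at 0.15 Å/ps.  It is coupled to
   the SMD atom by a harmonic spring of 7 kcal/mol/Å² (486.3 pN/Å) acting
   along the pull direction; the reported force is the spring tension
   projected on that direction, in pN.
4. **Regression.** Spring force is regressed on dummy displacement by
   ordinary least squares (intercept free) over the first 2.5 Å.  The slope,
   in pN/Å, is the resistance coefficient.  Pulls are repeated at least 12
   times with independent thermostat seeds; the mean and SEM are reported.
5. **Interpretation.** Residues are classed *low* (< 100 pN/Å), *mid*, or
   *high* (> 300 pN/Å).  Spatially adjacent high-resistance residues
   (Cα–Cα ≤ 8 Å) form *stability patches*.  Comparing two conformations of
   the same protein residue-by-residue (restricted to residues
   surface-exposed in both) gives a delta profile; changes beyond ±70 pN/Å
   are classed stabilized/destabilized.

Equilibrium (unbiased) runs provide per-residue Cα RMSD profiles whose
correlation with resistance coefficients is typically moderately negative:
thermal fluctuation influences, but does not determine, mechanical
resistance.  An in silico alanine scan mutates the residues around a focus
residue one at a time, re-equilibrates, re-measures the focus residue's
coefficient and compares mutant versus wild-type replicate slopes with a
two-tailed unpaired pooled-variance t-test.

## Force fields and the integrator

The pipeline is force-field-agnostic.  Two in-repo backends make it testable
at desk scale:

* **Harmonic tethers** — each bead bound to its reference position with
  stiffness $k_t$.  A pulled bead then has the closed-form coefficient
  $k_t k_p/(k_t + k_p)$ (tether and pulling spring in series), which is the
  package's primary analytic oracle.
* **Elastic network** — Hookean springs between heavy-atom pairs within a
  10 Å cutoff of the reference structure (default 1 kcal/mol/Å²), with
  optional per-region stiffness multipliers to emulate, e.g.,
  ligand-induced stiffening.

Dynamics are BAOAB-discretized Langevin (2 fs timestep, 1 ps⁻¹ friction,
310 K), which reduces to velocity Verlet at zero temperature and friction.
Forces and integration run in compiled code for these backends; any backend
without a native descriptor falls back to an R-level loop driven by its
`evaluate()` closure.  That loop is also the reference path for adapters
wrapping external all-atom engines: initialize from a `mol_structure` and a
`pull_spec`, run, return a force-extension trace.  Nothing downstream of the
trace cares which engine produced it.  Explicit solvent, Ewald
electrostatics and constraint algorithms are deliberately out of scope: the
contribution here is the protocol and the statistic, not the force field.

At 0.15 Å/ps pulling is near-quasi-static for these systems: the friction
drag on a 100 amu bead moving at ≤ 0.15 Å/ps is ~1 pN, under 0.5% of the
forces being regressed, and measured slopes at 0.6/0.3/0.15 Å/ps converge
monotonically to the analytic series-spring value.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sasa_threshold` | 30 | Å² | surface-residue selection (strict >) |
| `neighborhood_radius` | 4 | Å | pull-direction centre of mass |
| `free_radius` | 13 | Å | mobile zone around the SMD atom (inclusive ≤) |
| `spring_constant` | 7 | kcal/mol/Å² | dummy–SMD spring (= 486.3 pN/Å) |
| `pull_velocity` | 0.15 | Å/ps | dummy speed |
| `max_dummy_displacement`, `fit_range` | 2.5 | Å | pull length and regression window |
| `n_replicates` | 12 | — | thermostat-seed replicates |
| `temperature` | 310 | K | Langevin bath |
| `class_low`, `class_high` | 100, 300 | pN/Å | mobility classes (strict) |
| `delta_threshold` | 70 | pN/Å | conformation-pair classes (strict) |
| `patch_linkage_cutoff`, `patch_min_size` | 8, 2 | Å, — | patch clustering |

All protocol constants live in `default_protocol_config()`; no analysis code
path hard-codes them.

## Design choices where the protocol is open

* **"4 Å hemisphere" / "13 Å free hemisphere".**  Both neighbourhoods are
  implemented as spheres (balls) around the SMD atom: a hemisphere needs a
  defining plane that the protocol does not supply, and for a genuine
  surface atom the centre of mass of the 4 Å ball already lies toward the
  interior, so the direction points outward either way.  Radii are
  configurable.
* **Boundary ties.**  Distances exactly at 4 Å or 13 Å are included
  (≤ convention); classification and delta thresholds are strict
  inequalities, so 100/300/±70 pN/Å and 30 Å² map to the *middle*/unchanged/
  unselected side.  Ties have measure zero but the convention is fixed for
  determinism.
* **Regression intercept.**  The fit keeps a free intercept even though an
  ideal trace passes through the origin: at finite temperature the spring
  carries a thermal offset at pull start.
* **Reported force.**  The spring acts and is reported along the pull
  direction (projection); magnitude and projection coincide for axial
  deflection.
* **Delta profiles across differing surface sets.**  Comparison is
  restricted to the intersection of the two selections, mapped by residue
  index.
* **Per-residue RMSD.**  Cα only, matching the Cα-centric resistance
  statistic; frames are superposed over all Cα onto the first collection
  frame by default (`reference = "average"` uses the mean structure — the
  variance-based closed forms quoted in the tests assume this reference).
  For an isotropic 3D harmonic bead about its mean, the expected RMSD is
  $\sqrt{3 k_B T/k}$.
* **Equilibration restraints.**  The staged "release of constraints" is
  realized by immobilizing the restrained selection per stage after a
  zero-temperature minimization; the toy backends have no solvent, so
  softer harmonic restraints would only add parameters without changing
  what the stage accomplishes.
* **t-test.**  "Two-tailed unpaired t-test" is implemented as pooled-variance
  Student's t (the common default in the graphing packages used for such
  analyses), with Welch's form available by flag.
* **Alanine-scan neighbours.**  Residues with any heavy atom within 5 Å of
  the focus side chain, excluding Ala and Gly, including the focus itself;
  the radius is configurable because published mutant lists rarely state
  their selection rule.
* **Seeds.**  Scan seeds derive as
  `seed_base·10⁶ + residue_index·100 + replicate`, so per-residue streams
  are disjoint and every run is exactly reproducible.

## What the synthetic fixtures do and do not show

The generators produce bead systems whose mechanics are known in closed
form (single tethered beads, graded-stiffness chains, a stiffened-region
wheel, a two-state pair engineered for a +150 pN/Å shift) and an ideal
poly-alanine helix for geometry-level tests.  They validate the *protocol
and statistics*: that the pipeline recovers engineered stiffness ranks,
classifies engineered deltas exactly, matches series-spring and
equipartition closed forms, and keeps its promises about determinism and
boundary conventions.

They do **not** emulate real proteins: no excluded volume, no anisotropic
packing, no side-chain chemistry, no solvent.  In particular, a uniform
elastic network is nearly insensitive to deleting a single side-chain stub
(the dense backbone network dominates the Cα response) — so alanine-scan
effect sizes on toy systems are meaningful only where the fixture is
constructed to make the deleted atoms load-bearing.  Reproducing all-atom
resistance values or the published CaM N-lobe correlations (−0.319 apo,
−0.493 Ca²⁺-loaded) requires an external engine through the adapter
contract and is out of scope for the in-repo backends.

## Numerical notes and problem sizes

Unit system: Å, ps, amu, kcal/mol; 1 kcal/mol/Å = 69.4769 pN (from
1 kcal = 4184 J and N_A = 6.02214076×10²³); k_B = 1.98720×10⁻³ kcal/mol/K.
Blow-ups raise errors naming the failing step or stage.  Sampling is every
10 integrator steps.  The test suite runs pulls on 8–24-bead systems with
12 replicates where ranking or classification is asserted (about a minute
in total), 1 ns-scale single-bead runs for equipartition, and
10⁶-sample Monte-Carlo surface integration as the SASA oracle; these sizes
were chosen so each stochastic assertion sits several standard errors away
from its pass boundary.

## Known limitations

* Shrake–Rupley SASA is numerical; with 960 points per atom, isolated-atom
  areas are exact and overlap errors are well under 1%, but exact analytic
  SASA is a non-goal.
* The elastic-network response to *deleting* atoms is weak by construction
  (see above); mutation effects on toys should be engineered, not assumed.
* `mol_structure` handles single chains of standard residues plus bead
  systems; mmCIF, protonation and hydrogen rebuilding are out of scope.
* Pulling probes the linear-response regime (2.5 Å); unfolding, work
  accumulation and free-energy estimates are deliberately absent.
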