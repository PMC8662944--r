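---
title: "Quantum refinement with continuum solvation: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum refinement with continuum solvation: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the energy model, the assumptions behind each term, the parameters that
matter, the numerical choices made where the design was genuinely open,
and what the synthetic validation does and does not demonstrate.

## The combined energy

Standard restrained refinement minimizes `w_A * E_Xray + E_MM`.
Replacing the restraints of a selected region ("system 1") with a
region-specific energy gives the combined functional minimized by
`refine_coordinates()`:

```
E_total = E_QM1(eps) + w_MM * ( E_MM - E_MM1 + w_A * E_Xray )
```

* `E_QM1` -- the region energy.  The package treats the backend as a
  contract (coordinates + elements + charges + dielectric in; energy +
  gradient out; declared units; deterministic).  The built-in surrogate
  is classical: harmonic bonds/angles (optional cosine torsions and
  one-sided repulsion), point-charge Coulomb with the standard 1-2/1-3
  exclusions, optional Lennard-Jones pairs, and a COSMO solvation term.
  A genuine quantum backend can be attached through
  `run_external_backend()`; nothing in the refinement machinery depends
  on what produces the energy, which is the point of the contract.  The
  surrogate uses no point-charge embedding of the environment; the
  environment acts on the region only through `E_MM` cross terms and the
  X-ray data.
* `E_MM` / `E_MM1` -- restraint energy of the whole model and of the
  terms entirely internal to system 1; the subtraction avoids double
  counting.  Terms touching link atoms are never part of `E_MM1` (link
  atoms are bookkeeping of the capped region, not model atoms), and
  cross-boundary terms always stay in `E_MM`.  Restraints contain no
  electrostatics.
* `E_Xray` -- either weighted least squares on amplitudes,
  `sum w_h (|Fo| - k|Fc|)^2` with `w_h = 1/sigma_h^2` and the
  working-set scale `k`, or an acentric Rice (maximum-likelihood)
  negative log-likelihood on normalized amplitudes with per-shell
  `sigma_A` from moment matching.  Free-set reflections contribute to no
  target, scale or shell estimate.  All centric handling collapses to
  acentric because the toys are P1.

Structure factors use the independent-atom model: 4-Gaussian published
scattering factors (`f(0)` equals the electron count to 2%, verified in
the tests), isotropic Debye-Waller factors `exp(-B s^2)` with
`s = 1/(2d)`, direct summation over atoms and explicit symmetry
operators.  Direct summation is exact and fast at toy scale (under ~500
atoms and ~20 000 reflections); an FFT path is out of scope.  Coordinate
and B gradients of both targets are analytic (adjoint accumulation
through the phases), including the chain rule through the scale factor
`k`; everything is verified against central finite differences.

## Weights

* `w_A` balances data against chemistry.  `"auto"` uses gradient-norm
  matching, `w_A = rms(grad E_MM) / rms(grad E_Xray)` over the mobile
  atoms at the starting model, resolved once per run.  The estimate is
  meaningful when the start is an already data-consistent model that is
  chemically strained -- the normal situation when re-refining a
  deposited structure -- because both gradient norms are then on their
  working scales.  At a randomly perturbed start the X-ray gradient is
  inflated and the estimate is biased low; explicit values override, and
  published per-structure values can be supplied directly.
* `w_MM` converts restraint units to energy units.  The shipped default
  is 1/3, following the original quantum-refinement convention; it is a
  plain scalar in the configuration and should be reviewed whenever the
  restraint set changes.

## COSMO

The conductor-like screening model places apparent charges on a
molecular surface.  Each atom sphere (published COSMO-optimized radii;
metals default to 2.0 A) is tessellated with a deterministic Fibonacci
spiral lattice; points buried in another sphere are dropped (binary
keep/drop), each survivor owning area `4 pi R^2 / n_points`.  The
screening charges solve `A q = -f(eps) Phi` with `A_kl = 1/|r_k - r_l|`,
the standard self-interaction closure `A_kk = 1.07 sqrt(4 pi / area_k)`,
and `f(eps) = (eps - 1)/(eps + 0.5)`; `dG_solv = Phi' q / 2 <= 0`,
computed in atomic units and reported in kJ/mol.  Two numerical choices
deserve note:

* *Seam cleanup.*  With overlapping spheres, segments of different atoms
  can approach each other arbitrarily closely along the intersection
  seam, destroying the positive definiteness of `A`.  Cross-atom segment
  pairs closer than 0.8 of the local segment radius are merged
  area-conservingly.  Isolated spheres are untouched, so the
  conductor-Born and exposed-area validations are unaffected.
* *Factor caching.*  `A` depends only on the surface, so its Cholesky
  factor is computed once per cavity and reused by every solve.

The solver is validated against the closed-form conductor-Born energy
`-f(eps) q^2 / (2R)` (within 1% at 2000 segments), the Gauss law
`sum q = -f(eps) sum z` (within 1%), the exact vacuum limit, `q^2`
scaling, and monotonicity in `eps`.  There is no outlying-charge
correction and no self-consistency loop: solute charges are fixed, which
matches the point-charge surrogate.  The fixed-cavity gradient is
`q' dPhi/dx` (exact for the frozen surface); the motion of the surface
itself is neglected by default.  Because of that neglect the
fixed-cavity force field is *not* rigid-motion invariant -- a real,
documented property of the approximation, not a discretization error.
`cosmo_gradient(rebuild = TRUE)` adds the finite-difference
cavity-rebuild correction, which restores force conservation at the cost
of `6n` extra solves.

## Minimization

Coordinate refinement is organized in outer cycles around an inner
L-BFGS run:

1. at the cycle start the slowly varying context is frozen -- the COSMO
   cavity and, for the likelihood target, the shell parameters
   (`sigma_A`, normalizations, scale), mirroring macro-cycle practice;
2. the inner quasi-Newton run minimizes the then-smooth energy inside a
   per-coordinate trust radius (`max_step`, default 0.25 A).  The bound
   is essential: the fixed-cavity energy is unbounded below as a charge
   approaches the frozen surface, so unrestricted inner steps can escape
   the region where the frozen context is valid;
3. the context is rebuilt at the candidate geometry and the cycle is
   accepted only if the rebuilt energy did not rise (within
   `energy_tol`); a rejected cycle halves the trust radius.  Collapse of
   the trust radius terminates the run as converged -- no downhill move
   exists at the resolution of the tolerances.

Convergence thresholds: max per-atom shift `coord_tol` (default 1e-3 A)
or energy change below `energy_tol` (default 0.01 kJ/mol), up to
`max_cycles` (default 200).  Frozen atoms receive exactly zero gradient
and never move.  Dataless (free) region optimization -- used by strain
energies and by the toy generator -- additionally projects the
translations and rotations out of the inner search space (SVD complement
of the rigid modes): the exact rebuilt-cavity energy is rigid-invariant,
so any rigid component of the fixed-cavity gradient is artifact, and
without the projection a free optimization drifts rigidly without
bound.

ADP refinement is a separate stage at fixed coordinates: L-BFGS-B over
the mobile atoms' isotropic B values with a hard lower bound of 1 A^2
and a bonded-pair similarity restraint `b_sim (B_i - B_j)^2`
(default weight 0.1).  Because the overall scale `k` is refit
continuously, the bound activates exactly for an atom whose data favour
`B < 1` only while the remaining atoms anchor the scale.

Dual-conformation (2QM) refinement runs two capped-region energies, one
per conformer, both unweighted; the fixed occupancies `(p, 1-p)` act
only through the calculated structure factors (atoms carry them as
occupancies; they are never refined).  The unweighted-energy convention
follows the two-separate-calculations picture and is isolated in one
place should the occupancy-weighted variant be preferred.  `p = 1` with
an empty second conformer reduces exactly to single-conformer
refinement, which the tests assert to 1e-9.

## Validation machinery

* *Difference maps.*  Coefficients `(w_o |Fo| - w_c k |Fc|) exp(i phi_c)`
  with model phases, synthesized by FFT on a grid with spacing at most
  `d_min / 2.5` (default `d_min / 3`) and no index aliasing; verified
  against a point-wise Fourier sum.  Simple (`w_o = w_c = 1`) weighting
  is the default and keeps the least-squares pipeline self-contained;
  sigma-A weighting (`m`, `D` from the shell estimates) is available
  after a likelihood target.  Free reflections are included in maps, as
  is standard; the flag is recorded.
* *RSZD.*  For each validation group `(chain, residue, conformer)` the
  grid points within 1.5 A of its atoms (minimum image) are collected;
  the positive and negative density sums, in map-sigma units, are
  converted to Z scores against their pure-noise expectation
  (`Z = (S - n phi(0)) / sqrt((1/2 - phi(0)^2) n os)`, `os` the
  oversampling factor, grid points per independent datum), and
  `RSZD = max(|Z+|, |Z-|)`.  This estimator is inspired by the
  real-space difference-density Z score of standard validation tools but
  is not bit-compatible with them.  The uncentred variant (dividing the
  raw positive sum by `sqrt(n_indep)`) fails its own noise calibration
  -- the half-normal mean grows as `sqrt(n)` -- which is why the centred
  form is used.  Calibration, asserted in the tests: a null map gives
  exactly 0 for every group; pure-noise maps give a mean near 0.7
  (below 1) across 20 seeds; a deleted atom drives its group far above
  the conventional quality threshold of 3.
* *Strain energy.*  `E_QM1` at the crystallographically refined region
  geometry minus `E_QM1` at the freely optimized one (same backend, same
  dielectric, free optimization started from the refined geometry).
  Non-negative within the optimizer tolerance; a one-bond harmonic
  system held 0.1 A off its ideal length by the data reproduces the
  closed-form value of 10 kJ/mol.
* *Dielectric scans.*  For each `eps` in the grid (default 1-20 by 1,
  20-80 by 5; 32 values): full refinement, ADP stage, map, per-residue
  RSZD, strain.  Rows are independent (each starts from the same input
  model); a failing value marks its row and the scan continues.
  The order is coordinates, then ADPs, then maps, with shell parameters
  re-estimated at map time.

## The toy generator and what it shows

`make_toy_crystal()` builds a P1 cell containing a small bonded cluster
(a metal centre with 1-6 ligand atoms at 2.2 A, harmonic bonds
`k = 800 kJ/mol/A^2` and angles `k = 150 kJ/mol/rad^2`, typical
metal-ligand stiffness) plus uncharged environment atoms, computes
amplitudes from the true model to `d_min`, adds relative Gaussian noise
(`sigma = noise |F|`, truncation at `0.1 |F|`), assigns seeded free
flags, and perturbs the region of the start model to an exact RMSD.
Everything is deterministic per seed.

One design choice defines the dielectric-trend experiments: for a
*charged* cluster the data-generating geometry is equilibrated in
solvent (`geom_eps = 80` by default) while the restraint ideal values
stay at the vacuum geometry.  Crystals grow from aqueous solution, so
the observed conformation of a charged site is the solvated one; a
vacuum region energy then fights the data (elevated strain and residual
difference density) while a solvated one agrees with them.  Without
this, the vacuum surrogate would trivially match the data and the
dielectric trend would carry no information.  The shipped demo fixture
(`demo_fixture()`: net charge -5 over five atoms, 1.2 A data, 2% noise,
a lightly perturbed 0.05 A start emulating re-refinement of a deposited
model) is the substrate for those experiments.

What passing these tests shows: the machinery -- targets, gradients,
minimizer, solvation, validation scores -- is internally consistent and
reproduces every closed-form oracle it has.  What it does not show:
anything about real proteins.  The toys have no solvent contribution to
the data, no bulk-solvent correction, no realistic geometry or
anisotropy, single-digit residue counts, and a classical surrogate in
place of an electronic-structure method.  Problem sizes were chosen for
these properties to be testable in minutes: ~20 atoms, 1.2-1.8 A
resolution, 1 500-3 500 reflections, a few hundred COSMO segments per
atom.

## Known limitations

* The surrogate cannot express electronic effects (polarization, charge
  transfer, spin states); conclusions about chemistry require a real
  backend behind the contract.
* Fixed-cavity COSMO forces are approximate; free optimizations rely on
  the rigid-mode projection and refinements on the trust-region
  accept/reject to stay on the rebuilt-energy surface.
* The likelihood target freezes its shell parameters within a cycle;
  gradients are exact for the frozen-parameter functional, not for the
  re-estimated one.
* No occupancy refinement, no anisotropic ADPs, no bulk solvent, no
  twinning, no space-group tables beyond explicit operator lists.
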