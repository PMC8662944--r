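# qrlite

Desk-scale quantum refinement of macromolecular crystal structures with
COSMO continuum solvation.

## The problem

Crystallographic refinement minimizes a compromise between the data and
chemical prior knowledge,

    E = w_A * E_Xray + E_MM ,

where `E_Xray` measures how well calculated structure-factor amplitudes
reproduce the observed ones and `E_MM` is an empirical restraint (force
field) energy.  Restraints are excellent for amino acids but poor for
metal sites, cofactors and ligands.  *Quantum refinement* replaces the
restraints of a chemically interesting region ("system 1", the active
site) by a quantum-chemical energy:

    E_total = E_QM1(eps) + w_MM * ( E_MM - E_MM1 + w_A * E_Xray )

`E_MM1`, the restraint energy internal to system 1, is subtracted to
avoid double counting; `w_MM` converts restraint (statistical) units into
energy units; `w_A` balances data against chemistry.  Highly charged
active sites (metalloclusters carrying charges of -5 or more) are poorly
described by a vacuum region energy; immersing system 1 in a COSMO
conductor-like continuum solvent with dielectric constant `eps`
(`f(eps) = (eps-1)/(eps+0.5)` scaling, 1 = vacuum, 4 = protein-like,
80 = water) screens the excess charge and improves the refined models.

`qrlite` implements this machinery at desk scale for toy crystals, with
the quantum backend replaced by a pluggable contract whose built-in
surrogate is classical (bonded terms + point-charge Coulomb with 1-2/1-3
exclusions + optional Lennard-Jones + COSMO solvation).  It provides:

* PDB and reflection (TSV / structure-factor mmCIF) I/O, explicit
  symmetry-operator lists (P1 default), hydrogen link atoms capping cut
  bonds;
* independent-atom structure factors by direct summation with isotropic
  Debye-Waller factors, least-squares and maximum-likelihood (Rice)
  amplitude targets with analytic coordinate and B gradients, automatic
  `w_A` by gradient-norm matching;
* a COSMO solver (Fibonacci-lattice cavities, apparent surface charges,
  analytic fixed-cavity gradients) validated against the conductor-Born
  closed form;
* trust-region quasi-Newton coordinate refinement with a frozen
  environment, dual-conformation (2QM) refinement with fixed
  occupancies, and a post-refinement isotropic ADP stage;
* validation: difference-map synthesis, per-residue real-space
  difference-density Z scores (RSZD; |RSZD| < 3 marks a locally good
  model), strain energies and dielectric-constant scans;
* a deterministic toy-crystal generator that produces every test input
  synthetically.

## Worked example

```r
library(qrlite)

# a -5-charged five-atom cluster in a P1 cell, 1.2 A data, 2% noise
demo <- demo_fixture(seed = 1)
cfg <- refinement_config(mm_params = demo$mm_params,
                         region_params = demo$region_params,
                         w_A = "auto", epsilon = 80)

res <- refine_coordinates(demo$start, demo$region, demo$refl, cfg)
cfg$w_A <- res$w_A
res2 <- refine_adps(res$model, demo$refl, cfg)
map <- difference_map(res2$model, demo$refl)
zt <- rszd(map, res2$model)
st <- strain_energy(res2$model, demo$region, cfg)

tail(res$trace[, c("cycle", "e_total", "r_work", "r_free", "max_shift")], 1)
#    cycle   e_total    r_work    r_free    max_shift
# 18    18 -5791.323 0.1575816 0.1516758 0.0008027808
sum(zt$rszd[zt$resno == 1])   # region RSZD, eps = 80
# [1] 12.19585
st$strain                     # kJ/mol
# [1] 0
```

Repeating the same refinement with `epsilon = 1` (vacuum) gives a region
RSZD sum of 28.4 and a strain of 0.10 kJ/mol: for this charged site the
solvated region energy agrees with the data where the vacuum one fights
them, which is the effect the dielectric scan (`dielectric_scan()`, grid
`eps_grid_default()`: 1-20 in steps of 1, 20-80 in steps of 5, 32 values)
quantifies per residue.

A thin command-line front end is installed as `exec/qrl`
(`qrl simulate`, `qrl refine`, `qrl cosmo-born`, `qrl rszd`, `qrl strain`,
`qrl scan-eps`); see the header of that script for usage.

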