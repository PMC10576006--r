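# bindstates

Quantitative evidence chain for protein-complex binding kinetics and
oligomeric state, built around the question a structural-biology lab asks of
a small GTPase binding an effector RA domain: *what binding scheme do the
sensorgrams follow, and is the complex a 1:1 heterodimer or a 2:2
heterotetramer in solution?*

The package implements, with seeded synthetic generators for every input
modality:

* **BLI kinetics** — forward models (1:1 Langmuir closed form, 2:1
  heterogeneous ligand, 1:2 bivalent analyte via an adaptive Dormand–Prince
  ODE integrator), double referencing, global multi-start least-squares
  fitting with shared rate constants, and RSS-based model discrimination
  with a "2:1 collapses onto 1:1" rule.
* **NMR chemical shift perturbation** — combined CSP
  `sqrt(ddH^2 + (0.1 ddN)^2)`, intensity fold changes with 0.5/1.5 guide
  lines, residue classification, the exact two-state fraction-bound
  quadratic, and titration saturation analysis.
* **Rotational diffusion** — Lipari–Szabo model-free forward model
  (¹⁵N R1/R2/NOE from dipolar + CSA spectral densities), alternating
  model-free fitting of a global tau_c, the Stokes–Einstein–Debye relation
  `tau_c = 4 pi eta r^3 / (3 kB T)`, and log-space dimer/tetramer
  discrimination.
* **Mass photometry** — event-mass histograms, deterministic EM Gaussian
  mixture fitting (with a binned least-squares cross-check), theoretical
  oligomer mass ladders and relative-error component assignment.
* **Interface contacts** — fixed-width PDB parsing, LIGPLOT-style hydrogen
  bond / salt bridge / hydrophobic contact detection between chains, and
  overlap (Jaccard) between structural interface residues and NMR-perturbed
  residues.
* **Pipeline** — an INI-configured `run_pipeline()` producing a combined,
  byte-reproducible evidence report, plus a CLI
  (`inst/cli/bindstates`).

## Worked example

```r
library(bindstates)

# Theoretical tumbling times for a 25 A dimer and a 35 A tetramer
sed_tau_c(0.890, 298.0, c(25, 35))
#> [1] 14.15791 38.84930

# A fitted tau_c of 14.7 ns is a dimer call
assign_oligomer(14.7, c(dimer = 14.2, tetramer = 38.8))$state
#> [1] "dimer"

# Simulate noiseless 1:1 sensorgrams at the published rate constants and
# refit: the derived KD reproduces the printed ~1.48 uM affinity
d <- gen_bli_dataset("one_to_one", list(kon = 1.37e5, koff = 0.20, rmax = 1),
                     noise = noise_spec(0))
fit_global(d, "one_to_one")
#> <kinetic_fit> model = one_to_one, converged = TRUE, rss = 4.26e-24
#>   parameters:
#>     kon    = 137000
#>     koff   = 0.2
#>     rmax   = 1
#>   KD (M): site1=1.46e-06

# A 68 kD mass component lands on the 61.7 kD heterotetramer rung
lad <- mass_ladder(default_subunits(),
                   list(heterodimer = c(kras_g12v = 1, rgl2ra = 1),
                        heterotetramer = c(kras_g12v = 2, rgl2ra = 2)))
assign_components(68, lad)
#>          component_mass        species expected_mass rel_error assigned
#> heterotetramer       68 heterotetramer          61.7 0.1021070     TRUE

# End-to-end synthetic demo: kinetic discrimination + dimer tau_c call +
# tetramer mass assignment + CSP/interface overlap in one run
cfg <- system.file("extdata", "demo_run.ini", package = "bindstates")
report <- run_pipeline(cfg, outdir = tempfile(), seed = 1)
#  [fit_bli.wt] best kinetic model: heterogeneous_ligand, effective: heterogeneous_ligand (dominant site fraction 0.64)
#  [fit_bli.g12v] best kinetic model: heterogeneous_ligand, effective: one_to_one (2:1 collapsed) (dominant site fraction 1.00)
#  [tauc_fit] rotational diffusion: tau_c 14.8 ns -> dimer
#  [massphot] mass components -> heterotetramer
#  [csp_titration] CSP/interface Jaccard = 1.00
```

The numbers mean: the wild-type-like analyte needs a two-site description
while the mutant-like analyte is effectively 1:1; the fitted rotational
correlation time sits at the dimer's hydrodynamic prediction; the mass peak
is assigned to the heterotetramer; and the NMR-perturbed residues coincide
exactly with the planted structural interface.

## Layout

* `R/` — implementation; `src/` — bivalent-analyte ODE integrator (Rcpp)
* `tests/testthat/` — unit, property and acceptance suites
* `vignettes/oligomer-evidence.Rmd` — models, assumptions, numerical
  choices and limitations
* `inst/extdata/demo_run.ini` — the shipped end-to-end demo configuration
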