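---
title: "Kinetic, relaxation, mass and interface evidence for oligomeric state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic, relaxation, mass and interface evidence for oligomeric state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindstates)
```

# Scope and model

`bindstates` implements the quantitative chain used to characterise a small
GTPase binding its effector's Ras-association (RA) domain and to weigh the
evidence that the complex populates a 2:2 heterotetramer in solution. Four
orthogonal measurements feed the verdict:

1. **BLI kinetics** — which binding scheme describes the sensorgrams, and
   does a two-site description collapse onto one site?
2. **¹⁵N relaxation** — is the overall rotational correlation time closer to
   the hydrodynamic prediction for a dimer or a tetramer?
3. **Mass photometry** — which rung of the theoretical oligomer mass ladder
   does the fitted event-mass peak land on?
4. **NMR titration vs crystal interface** — do the perturbed residues
   coincide with the structural interface?

Every stage has a seeded synthetic generator so the full pipeline is
exercisable (and its recovery properties testable) without instrument data.

# Binding kinetics

## Forward models

The 1:1 Langmuir model is closed form: association
$R(t) = R_{eq}\,(1 - e^{-(k_{on}C + k_{off})t})$ with
$R_{eq} = R_{max}C/(C + K_D)$, $K_D = k_{off}/k_{on}$, and exponential
dissociation from the phase boundary. The 2:1 heterogeneous-ligand model is
the sum of two independent 1:1 site classes. The 1:2 bivalent-analyte model
integrates the sequential surface reaction

$$\frac{dR_1}{dt} = 2k_{a1}C\,F - k_{d1}R_1 - k_{a2}R_1 F + 2k_{d2}R_2,
\qquad \frac{dR_2}{dt} = k_{a2}R_1 F - 2k_{d2}R_2,$$

with free sites $F = R_{max} - R_1 - 2R_2$ and signal $R_1 + R_2$. The
statistical factors (2 on the first association and the second dissociation)
follow mainstream SPR evaluation software; consequently the
$k_{a2} = k_{d2} = 0$ limit equals 1:1 kinetics with $k_{on} = 2k_{a1}$.
$k_{a2}$ carries response-unit⁻¹s⁻¹ units because the second step is a
surface-species reaction. Integration uses an adaptive Dormand–Prince 5(4)
pair at relative tolerance $10^{-10}$; no mass-transport term is modelled.

## Global fitting and numerical choices

`fit_global()` minimises the plain (unweighted) residual sum of squares over
all traces with rate constants and $R_{max}$ shared across concentrations —
plain RSS because that is the comparison statistic the instrument software
reports. Optimisation runs in log₁₀ space (all parameters positive, spanning
decades) inside a generous box, from a multi-start grid (default 4×4 over
$k_{on} \in [10^2, 10^8]$ M⁻¹s⁻¹, $k_{off} \in [10^{-5}, 10]$ s⁻¹). Ties
between optima break by lowest RSS, then lowest $k_{off}$, so results are
deterministic given the grid. Starts for the two- site and bivalent models
are seeded from the fitted 1:1 optimum with the extra site/step zeroed, which
makes the nested-model inequality $RSS_{2:1} \le RSS_{1:1}$ hold by
construction. The final polish (Nelder–Mead) is projected back into the box:
unconstrained polishing can otherwise park a *phantom site* — enormous
$R_{max}$ with vanishing occupancy — that improves RSS by fitting noise
drift while contributing nothing physical.

That phantom also motivates a semantic choice: *binding-type fractions* are
reported as $R_{max,i}/\sum R_{max}$ (the conventional definition), but the
pipeline's "2:1 collapses to 1:1" verdict judges dominance by each site's
equilibrium response share at the top analyte concentration, which a phantom
site cannot dominate. A 2:1 fit collapses when the dominant site carries
≥ 95% of that response and its constants sit within 10% of the 1:1 solution.

Fit failure is defined as no start converging or parameters pinned at the
box boundary; both are recorded (`converged`, `pinned`, `notes`) rather than
silently dropped, and `compare_models()` excludes failed fits from the
ranking while reporting them.

# NMR titration analysis

The combined chemical shift perturbation is
$\Delta\delta_{ave} = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2}$
in ppm with $\alpha = 0.1$, the conventional nitrogen scaling; $\alpha$ is a
parameter because conventions vary. Binding arithmetic is the exact
two-state quadratic: with protein $P$, ligand $L$ and dissociation constant
$K_D$,

$$f_b = \frac{(K_D + L + P) - \sqrt{(K_D + L + P)^2 - 4LP}}{2P}.$$

Under fast exchange the observed shift is $\delta_{free} + f_b\,\Delta\delta$,
so noiseless synthetic trajectories are exactly proportional to $f_b$ — the
property the tests assert. Classification uses the intensity fold-change
guide lines 0.5/1.5 and a CSP threshold defaulting to mean + 1 SD over
assigned residues (no cutoff is canonical; the threshold is exposed).
Unassigned or proline residues are carried as `missing`, never imputed. A
titration is flagged *saturated* when the mean CSP changes < 5% over the
last two points — with micromolar $K_D$ at 100 µM protein saturation occurs
by ratio 2, whereas a weak (hundreds of µM) interaction visibly does not,
which is the diagnostic the saturation analysis encodes.

The generator's intensity model — linear decay with fraction bound,
$I = I_0(1 - c\,f_b)$, floored at 0 — is a deliberate simplification: real
intensity loss comes from line broadening with complex size and exchange,
which the source experiments report only qualitatively. A green intensity
test therefore establishes the plumbing, not a broadening model.

# Rotational diffusion

The Lipari–Szabo model-free spectral density

$$J(\omega) = \tfrac{2}{5}\left[\frac{S^2\tau_c}{1 + (\omega\tau_c)^2}
 + \frac{(1 - S^2)\tau'}{1 + (\omega\tau')^2}\right],
 \quad \tau'^{-1} = \tau_c^{-1} + \tau_e^{-1},$$

feeds the standard ¹⁵N dipolar + CSA expressions for $R_1$, $R_2$ and the
heteronuclear NOE, with $r_{NH} = 1.02$ Å and $\Delta\sigma = -160$ ppm
(conventional values, exposed as arguments; the analysis is insensitive to
them at the level of the dimer/tetramer call). Tumbling is isotropic only —
the real complexes are ellipsoidal, so reported $\tau_c$ is an effective
isotropic value and the limitation is flagged here rather than modelled.
$R_{ex}$ defaults to 0.

`fit_model_free()` alternates per-residue bounded least squares on
$(S^2, \tau_e)$ with a 1-D refinement of the global $\tau_c$, initialised
from the rigid-limit $R_2/R_1$ ratio (10%-trimmed mean over residues with
NOE > 0.65, which discards flexible tails and exchange-broadened outliers).
Residuals are relative for $R_1$/$R_2$ and absolute for the NOE, whose
magnitude is order one but can pass through zero. Convergence is a relative
change below $10^{-6}$ in both $\tau_c$ and the objective.

One point where a textbook shorthand fails: the NOE does *not* tend to 1 as
$\tau_c \to \infty$; the cross-relaxation to $R_1$ ratio tends to a
field-dependent plateau (≈ 0.91 at 600 MHz). The test suite asserts the
plateau against a direct evaluation of the $J$-ratio rather than the naive
limit.

The hydrodynamic side is the Stokes–Einstein–Debye relation
$\tau_c = 4\pi\eta r^3/(3k_BT)$. With $\eta = 0.890$ mPa·s and $T = 298$ K
it gives 14.2 ns at $r = 25$ Å and 38.8 ns at $r = 35$ Å. The input radius
is treated as an *effective hydrodynamic radius*: the radii quoted for the
two oligomers are nominally radii of gyration, and using them directly in
SED is the approximation the analysis inherits — a caveat, not a bug, and
the reason the discrimination is made in log space (`assign_oligomer()`
picks the candidate nearest in $\log\tau_c$, natural for a quantity scaling
as $r^3$).

# Mass photometry

Event masses are fitted as a 1-D Gaussian mixture by EM on the raw events
(the vendor's method is unspecified; raw-event ML avoids binning bias), with
deterministic k-means++-style seeding, a per-iteration assertion that the
log-likelihood never decreases, and one re-initialisation before flagging a
degenerate (σ → 0) component. A binned least-squares fit
(`fit_mixture_binned()`) is kept as an independent cross-check; the two
agree on means within ~0.5 kD at the default 2.5 kD binning. The number of
components is user-chosen, matching practice where peaks are identified
visually.

The theoretical ladder is built from subunit masses: the shipped default
profile uses the GTP-loaded GTPase construct masses (19.856/19.898 kD) and
derives the RA-domain mass (10.952 kD) from the published ~61.7 kD
heterotetramer, since the monomer mass is not printed; sequence-based mass
computation is out of scope. Components are assigned to the relative-error-
nearest rung, unassigned beyond 15% — wide enough to accept the observed
~68 kD peak as the 61.7 kD tetramer (relative error 0.102) while rejecting
a hypothetical 45 kD component (error 0.27). The generator's default event
σ of 6 kD stands in for typical instrument resolution (not printed either).

# Interface contacts

PDB parsing is fixed-width with line-numbered rejection of malformed
records, highest-occupancy altloc selection and first-model-only default.
Contact classes use LIGPLOT-style heavy-atom cutoffs — hydrogen bond N/O–N/O
≤ 3.35 Å, salt bridge carboxylate-O to Lys/Arg/His basic N ≤ 4.0 Å,
hydrophobic apolar-C/S pair ≤ 3.9 Å — with the most specific class winning
per pair (salt_bridge ⊃ hbond ⊃ hydrophobic) so summaries do not double
count. No hydrogens are placed and no angles are scored: at ~3 Å crystal
resolution, distance-only criteria are the honest granularity. The apolar
atom table (side-chain C/S not bonded to N/O) is explicit in the source; it
is a reasonable LIGPLOT approximation, not guaranteed to match any
particular LIGPLOT version atom-for-atom.

The toy-structure generator plants one minimal residue pair per requested
contact, 20 Å apart between plants, so detection tests have exact planted
truth with zero possible cross-talk. `csp_overlap()` closes the loop between
structure and NMR: the Jaccard index between interface residues and
CSP-perturbed residues, with a numbering-mismatch warning when the ranges
are disjoint.

# Synthetic world and seeds

Generator defaults are the stated experimental conditions where known
(400 s/400 s BLI phases, five concentrations 0.2–15 µM, titration ratios up
to 1:3 at 100 µM protein, 600 MHz field) and documented choices elsewhere
(BLI noise σ = 0.02 response units; relaxation noise multiplicative at 2%
CV; event σ = 6 kD). Noise is additive Gaussian for responses and shifts,
multiplicative for relaxation times and intensities — qualitatively like
the instruments, and simple enough that recovery tests have analysable
expectations. One global seed expands to per-generator streams by a fixed
counter scheme (`stream_seed()`), so adding a stage to a pipeline never
shifts the random numbers of existing stages, and identical configs rerun
byte-identically.

The bivalent recovery truth (ka1 = 6·10⁴ M⁻¹s⁻¹, kd1 = 0.25 s⁻¹,
ka2 = 0.02 RU⁻¹s⁻¹, kd2 = 5·10⁻³ s⁻¹) was chosen so the doubly bound
species carries substantial amplitude: no bivalent constants are published
for this system, and a recovery test of a parameter the data cannot see
would be vacuous. The noisy-recovery criterion is read as a bias criterion —
the mean recovered constant over 20 seeds within 5% of truth — because
single-seed errors of the weakly identified minor-site/second-step
parameters reach 5–9% at 2% noise.

What a green suite does **not** establish: real sensorgrams carry drift,
mass-transport limitation and well-to-well scaling the generator omits;
real titrations have exchange-regime line shapes; real relaxation data have
anisotropic tumbling and exchange terms; real mass-photometry calibration
has contrast nonlinearity. The package validates the inference chain, not
the instruments.

# Worked example

```{r example, eval = FALSE}
library(bindstates)

# kinetics: simulate the mutant-like 1:1 analyte and discriminate models
d <- gen_bli_dataset("one_to_one",
                     list(kon = 2.38e5, koff = 0.36, rmax = 1),
                     noise = noise_spec(0.002, seed = 1))
compare_models(d, c("one_to_one", "heterogeneous_ligand"))

# rotational diffusion: is 14.7 ns a dimer or a tetramer?
assign_oligomer(14.7, c(dimer = sed_tau_c(0.890, 298, 25),
                        tetramer = sed_tau_c(0.890, 298, 35)))

# full pipeline
cfg <- system.file("extdata", "demo_run.ini", package = "bindstates")
report <- run_pipeline(cfg, outdir = tempfile(), seed = 1)
report
```

# Known limitations

* Isotropic tumbling only; no model selection between spectral-density
  models (no AIC over the relax-style model set).
* No steady-state-only affinity analysis, no drift correction beyond double
  referencing, no mass-transport term.
* Gaussian mixture components only; no surface-binding or ratiometric
  corrections for mass photometry.
* Contact typing is distance-only and the hydrophobic atom table is an
  approximation of LIGPLOT's version-dependent typing.
* Residue numbering consistency between coordinate files and NMR tables is
  asserted by the caller; the package only warns on disjoint ranges.
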