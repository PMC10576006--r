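# Synthetic end-to-end demo: plants the qualitative evidence pattern of a
# GTPase-effector interaction whose wild-type sensorgrams need a two-site
# description while the oncogenic mutant is plain 1:1, whose fitted tumbling
# time sits near the dimer SED prediction, whose mass-photometry peak lands
# on the heterotetramer rung, and whose NMR perturbation map coincides with
# the planted structural interface.

[run]
seed = 1
outdir = bindstates_demo

# wild-type-like analyte: genuinely heterogeneous two-site surface
[simulate_bli.wt]
model = heterogeneous_ligand
param.kon1 = 1.37e5
param.koff1 = 0.20
param.rmax1 = 0.65
param.kon2 = 2.0e3
param.koff2 = 1.5e-3
param.rmax2 = 0.35
concentrations_uM = 0.2, 0.6, 1.9, 5.6, 15
noise_sd = 0.002

[fit_bli.wt]
data = wt
models = one_to_one, heterogeneous_ligand

# mutant-like analyte: true 1:1 kinetics
[simulate_bli.g12v]
model = one_to_one
param.kon = 2.38e5
param.koff = 0.36
param.rmax = 1.0
concentrations_uM = 0.2, 0.6, 1.9, 5.6, 15
noise_sd = 0.002

[fit_bli.g12v]
data = g12v
models = one_to_one, heterogeneous_ligand

[tauc_sed]
eta = 0.890
temperature = 298.0
radii_A = dimer=25, tetramer=35

[simulate_relaxation.relax]
n_residues = 40
s2_min = 0.8
s2_max = 0.95
tau_e_ps = 50
tau_c_ns = 14.7
field = 600
noise_cv = 0.01

[tauc_fit.relax]
data = relax

[simulate_massphot.mp]
components = 68:6:1
n_events = 3000

[massphot.mp]
data = mp
k = 1

[simulate_interface.iface]
plants = GLU:OE1:ARG:NH1:3.0:37:653; GLY:O:GLY:N:2.9:40:655; LEU:CD1:VAL:CG1:3.6:43:659

[contacts.iface]
data = iface
chains = A,B

[csp_titration.csp]
kd_uM = 5
protein_conc_uM = 100
intensity_decay = 0.6
noise_sd = 0
perturb_chain = B
n_background = 40
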