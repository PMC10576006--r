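# Shared planted truths. Tests use coarser sampling (dt = 4 s) than the
# 400 s/400 s default to stay inside the CI time budget; recovery accuracy
# is unaffected at these tolerances.

wt_one_to_one <- list(kon = 1.37e5, koff = 0.20, rmax = 1)
g12v_one_to_one <- list(kon = 2.38e5, koff = 0.36, rmax = 1)
het_truth <- list(kon1 = 1.37e5, koff1 = 0.20, rmax1 = 0.65,
                  kon2 = 2e3, koff2 = 1.5e-3, rmax2 = 0.35)
biv_truth <- list(ka1 = 6e4, kd1 = 0.25, ka2 = 0.02, kd2 = 5e-3, rmax = 1)

test_concs <- c(0.2, 0.6, 1.9, 5.6, 15) * 1e-6

gen_noiseless <- function(model, params, dt = 4) {
  gen_bli_dataset(model, params, concentrations = test_concs,
                  t_assoc = 400, t_dissoc = 400, dt = dt,
                  noise = noise_spec(0))
}

# toy interface with one plant per contact class
toy_plants <- list(
  planted_contact("GLU", "OE1", "ARG", "NH1", 3.0, 37, 653),
  planted_contact("GLY", "O", "GLY", "N", 2.9, 40, 655),
  planted_contact("LEU", "CD1", "VAL", "CG1", 3.6, 43, 659))

make_free_peaks <- function(n = 30, seed = 7) {
  set.seed(seed)
  peak_list(seq_len(n), runif(n, 7.5, 9.5), runif(n, 105, 130))
}
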