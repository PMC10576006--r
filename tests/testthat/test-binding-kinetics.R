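test_that("1:1 closed form matches its analytic values", {
  # Req = rmax*C/(C+KD): KD = 2 uM, C = 2 uM -> 0.5; half-rise at ln2/kobs
  expect_equal(simulate_one_to_one(1e5, 0.2, 1, 2e-6, 400, 400), 0.5,
               tolerance = 1e-6)
  expect_equal(simulate_one_to_one(1e5, 0.2, 1, 2e-6, log(2) / 0.4, 400),
               0.25, tolerance = 1e-9)
  expect_equal(simulate_one_to_one(1e5, 0.2, 1, 0, c(1, 10, 100), 400),
               rep(0, 3))
  # dissociation: one half-life after t_assoc halves the response
  r_end <- simulate_one_to_one(1e5, 0.2, 1, 2e-6, 400, 400)
  r_half <- simulate_one_to_one(1e5, 0.2, 1, 2e-6, 400 + log(2) / 0.2, 400)
  expect_equal(r_half, r_end / 2, tolerance = 1e-9)
  expect_error(simulate_one_to_one(1e5, 0.2, 1, -1e-6, 1, 400), "concentration")
  expect_error(simulate_one_to_one(-1e5, 0.2, 1, 1e-6, 1, 400), "> 0")
})

test_that("equilibrium plateau follows the binding isotherm across concentrations", {
  kon <- 2e5; koff <- 0.1; kd <- koff / kon
  for (C in c(1e-7, 5e-7, 2e-6, 1e-5)) {
    t_eq <- 8 / (kon * C + koff)
    expect_equal(simulate_one_to_one(kon, koff, 1, C, t_eq, t_eq),
                 C / (C + kd), tolerance = 1e-3)
  }
})

test_that("heterogeneous model reduces to 1:1 when the second site vanishes", {
  t <- seq(0, 800, 4)
  r1 <- simulate_one_to_one(1.37e5, 0.2, 1, 2e-6, t, 400)
  rh <- simulate_model("heterogeneous_ligand",
                       list(kon1 = 1.37e5, koff1 = 0.2, rmax1 = 1,
                            kon2 = 1e4, koff2 = 1, rmax2 = 0),
                       2e-6, t, 400)
  expect_lt(max(abs(r1 - rh)), 1e-10)
})

test_that("bivalent ODE matches 1:1 closed form when the second step is off", {
  t <- seq(0, 800, 2)
  r1 <- simulate_one_to_one(1e5, 0.2, 1, 2e-6, t, 400)
  # statistical factor 2: ka1 = kon/2 reproduces 1:1
  r2 <- simulate_model("bivalent_analyte",
                       list(ka1 = 5e4, kd1 = 0.2, ka2 = 0, kd2 = 0, rmax = 1),
                       2e-6, t, 400)
  # relative where the signal is nonzero; absolute (vs rmax) in the decayed tail
  expect_lt(max(abs(r1 - r2) / pmax(abs(r1), 1e-3)), 1e-6)
})

test_that("bivalent surface sites are conserved even with fast second step", {
  t <- seq(0, 800, 2)
  m <- bindstates:::simulate_bivalent_species(
    list(ka1 = 1e5, kd1 = 0.1, ka2 = 5, kd2 = 1e-3, rmax = 1), 5e-6, t, 400)
  bound_sites <- m[, "R1"] + 2 * m[, "R2"]
  expect_true(all(bound_sites <= 1 + 1e-8))
  expect_true(all(m >= -1e-10))
})

test_that("simulate_model rejects unknown models and incomplete parameters", {
  expect_error(simulate_model("conformational_change", list(), 1e-6, 1, 1),
               "one_to_one")
  expect_error(simulate_model("one_to_one", list(kon = 1e5, koff = 0.1),
                              1e-6, 1, 1), "rmax")
  expect_error(simulate_model("bivalent_analyte",
                              list(ka1 = 1, kd1 = 1, ka2 = 1, kd2 = 1),
                              1e-6, 1, 1), "rmax")
})

test_that("noiseless global fit recovers generating constants and the KD", {
  d <- gen_noiseless("one_to_one", wt_one_to_one)
  f <- fit_global(d, "one_to_one")
  expect_true(f$converged)
  expect_equal(f$params$kon, 1.37e5, tolerance = 1e-3)
  expect_equal(f$params$koff, 0.20, tolerance = 1e-3)
  expect_equal(unname(f$kd_derived["site1"]), 0.20 / 1.37e5, tolerance = 1e-3)
  # kd_derived is exactly koff/kon
  expect_identical(unname(f$kd_derived["site1"]), f$params$koff / f$params$kon)
  # rss equals sum of squared residuals
  expect_equal(f$rss, sum(f$residuals^2), tolerance = 1e-9)
})

test_that("fit rejects NaN-contaminated data", {
  d <- gen_noiseless("one_to_one", wt_one_to_one)
  d$traces[[2]]$response[5] <- NaN
  expect_error(fit_global(d, "one_to_one"), "NaN")
})

test_that("kd_derived is invariant under kon/C rescaling of the truth", {
  a <- 10
  d1 <- gen_bli_dataset("one_to_one", list(kon = 1e5, koff = 0.2, rmax = 1),
                        concentrations = c(1, 3, 9) * 1e-6, dt = 4,
                        noise = noise_spec(0))
  d2 <- gen_bli_dataset("one_to_one", list(kon = a * 1e5, koff = 0.2, rmax = 1),
                        concentrations = c(1, 3, 9) * 1e-6 / a, dt = 4,
                        noise = noise_spec(0))
  f1 <- fit_global(d1, "one_to_one")
  f2 <- fit_global(d2, "one_to_one")
  expect_equal(unname(f1$kd_derived * 1), unname(a * f2$kd_derived),
               tolerance = 1e-3)
})

test_that("model comparison ranks planted heterogeneous data correctly", {
  d <- gen_noiseless("heterogeneous_ligand", het_truth)
  cmp <- compare_models(d, c("one_to_one", "heterogeneous_ligand"))
  expect_identical(cmp$ranking[1], "heterogeneous_ligand")
  expect_gt(cmp$rss[["one_to_one"]], 10 * cmp$rss[["heterogeneous_ligand"]])
  fr <- cmp$fits$heterogeneous_ligand$site_fractions
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  expect_equal(sort(unname(fr)), c(0.35, 0.65), tolerance = 0.01)
})

test_that("single requested model yields a ranking of length 1", {
  d <- gen_noiseless("one_to_one", wt_one_to_one)
  cmp <- compare_models(d, "one_to_one")
  expect_length(cmp$ranking, 1L)
  expect_error(compare_models(d, character(0)), "at least one")
})

test_that("kon unit conversion round-trips exactly", {
  expect_identical(convert_kon(convert_kon(1.37e5, "per_ms"), "per_s"), 1.37e5)
  expect_equal(convert_kon(1.37e5, "per_ms"), 137)
})

test_that("double referencing subtracts planted drift and is identity on zeros", {
  d <- gen_noiseless("one_to_one", wt_one_to_one)
  t <- d$traces[[1]]$time_s
  zero <- sensorgram_set(list(data.frame(time_s = t, response = 0)),
                         1e-9, d$t_assoc)
  out <- double_reference(d, zero, zero)
  for (i in seq_along(d$traces))
    expect_equal(out$traces[[i]]$response, d$traces[[i]]$response)
  # planted linear drift removed exactly on the shared grid
  drift <- 0.05 + 1e-4 * t
  drifted <- d
  drifted$traces <- lapply(d$traces, function(tr)
    data.frame(time_s = tr$time_s, response = tr$response + drift))
  ref <- sensorgram_set(list(data.frame(time_s = t, response = drift)),
                        1e-9, d$t_assoc)
  corrected <- double_reference(drifted, ref, zero)
  for (i in seq_along(d$traces))
    expect_equal(corrected$traces[[i]]$response, d$traces[[i]]$response,
                 tolerance = 1e-12)
})

test_that("double referencing interpolates offset grids within tolerance", {
  kon <- 1.37e5; koff <- 0.2
  t <- seq(0, 800, 2)
  t_off <- t + 1  # offset by dt/2
  drift_fun <- function(x) 0.02 * sin(x / 50)
  sample <- sensorgram_set(
    list(data.frame(time_s = t,
                    response = simulate_one_to_one(kon, koff, 1, 2e-6, t, 400) +
                      drift_fun(t))), 2e-6, 400)
  ref <- sensorgram_set(
    list(data.frame(time_s = t_off, response = drift_fun(t_off))), 1e-9, 400)
  out <- double_reference(sample, ref, NULL)
  truth <- simulate_one_to_one(kon, koff, 1, 2e-6, t, 400)
  inner <- t >= min(t_off) & t <= max(t_off)
  expect_lt(max(abs(out$traces[[1]]$response[inner] - truth[inner])), 1e-3)
  # non-overlapping ranges rejected
  far <- sensorgram_set(list(data.frame(time_s = t + 1e4, response = 0)),
                        1e-9, 400)
  expect_error(double_reference(sample, far, NULL), "overlap")
})

test_that("sensorgram CSV round-trips", {
  d <- gen_noiseless("one_to_one", wt_one_to_one)
  path <- tempfile(fileext = ".csv")
  write_sensorgrams(d, path)
  d2 <- read_sensorgrams(path)
  expect_equal(d2$conc, d$conc)
  expect_equal(d2$t_assoc, d$t_assoc)
  expect_equal(d2$traces[[3]]$response, d$traces[[3]]$response)
})
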