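test_that("generators are deterministic given a seed", {
  d1 <- gen_bli_dataset("one_to_one", wt_one_to_one, dt = 10,
                        noise = noise_spec(0.02, 11))
  d2 <- gen_bli_dataset("one_to_one", wt_one_to_one, dt = 10,
                        noise = noise_spec(0.02, 11))
  expect_identical(d1$traces, d2$traces)
  t1 <- gen_relaxation_table(1:10, 0.85, 50, 14.7, noise_cv = 0.02, seed = 3)
  t2 <- gen_relaxation_table(1:10, 0.85, 50, 14.7, noise_cv = 0.02, seed = 3)
  expect_identical(t1, t2)
  e1 <- gen_mp_events(list(mixture_component(62, 6, 1)), 500, seed = 5)
  e2 <- gen_mp_events(list(mixture_component(62, 6, 1)), 500, seed = 5)
  expect_identical(e1$masses, e2$masses)
  # different seeds differ
  e3 <- gen_mp_events(list(mixture_component(62, 6, 1)), 500, seed = 6)
  expect_false(identical(e1$masses, e3$masses))
})

test_that("per-stream seeds are a pure documented function of (seed, stream)", {
  expect_identical(stream_seed(1, 1), 10008L)
  expect_identical(stream_seed(1, 2), 20015L)
  expect_identical(stream_seed(2^31 - 1, 0), 0L)
})

test_that("noiseless sensorgrams equal the forward model and are continuous at phase boundary", {
  d <- gen_bli_dataset("one_to_one", list(kon = 1e5, koff = 0.2, rmax = 1),
                       concentrations = 2e-6, t_assoc = 400, t_dissoc = 400,
                       dt = 2, noise = noise_spec(0))
  tr <- d$traces[[1]]
  expect_equal(tr$response,
               simulate_one_to_one(1e5, 0.2, 1, 2e-6, tr$time_s, 400))
  # plateau at 0.5 for C = KD = 2 uM; continuity across association end
  expect_equal(tr$response[tr$time_s == 400], 0.5, tolerance = 1e-6)
  r_right <- simulate_one_to_one(1e5, 0.2, 1, 2e-6, 400 + 1e-9, 400)
  expect_equal(r_right, tr$response[tr$time_s == 400], tolerance = 1e-6)
  # C = 0 gives identically zero response
  d0 <- gen_bli_dataset("one_to_one", list(kon = 1e5, koff = 0.2, rmax = 1),
                        concentrations = 0, dt = 50, noise = noise_spec(0))
  expect_true(all(d0$traces[[1]]$response == 0))
})

test_that("generator rejects bad kinetic inputs", {
  expect_error(gen_bli_dataset("not_a_model", wt_one_to_one), "one_to_one")
  expect_error(gen_bli_dataset("one_to_one",
                               list(kon = -1, koff = 0.2, rmax = 1)),
               "positive")
  expect_error(gen_bli_dataset("one_to_one", wt_one_to_one,
                               concentrations = -1e-6), ">= 0")
})

test_that("round trip: noiseless 5-concentration set recovers rates within 0.1%", {
  d <- gen_noiseless("one_to_one", wt_one_to_one)
  f <- fit_global(d, "one_to_one")
  expect_equal(f$params$kon, wt_one_to_one$kon, tolerance = 1e-3)
  expect_equal(f$params$koff, wt_one_to_one$koff, tolerance = 1e-3)
})

test_that("fast-exchange titration follows the exact quadratic", {
  free <- make_free_peaks(10)
  deltas <- data.frame(residue = 1:10, ddH = 0.1, ddN = 1)
  # P = L = KD -> f_b = (3 - sqrt(5))/2 = 0.382 for every residue
  s <- gen_titration_peaklists(free, deltas, kd = 1e-4, protein_conc = 1e-4,
                               ratios = c(0, 1))
  fb <- (3 - sqrt(5)) / 2
  expect_equal(s$peaklists[[2]]$dH, free$dH + fb * 0.1, tolerance = 1e-9)
  expect_equal(s$peaklists[[2]]$dN, free$dN + fb * 1, tolerance = 1e-9)
  # ratio 0 reproduces the free state exactly
  expect_equal(s$peaklists[[1]]$dH, free$dH)
  # stoichiometric limit: kd -> 0, ratio >= 1 -> full shift
  s2 <- gen_titration_peaklists(free, deltas, kd = 1e-15, protein_conc = 1e-4,
                                ratios = c(0, 1.5))
  expect_equal(s2$peaklists[[2]]$dH, free$dH + 0.1, tolerance = 1e-6)
  # intensity decays linearly with f_b, floored at zero
  s3 <- gen_titration_peaklists(free, deltas, kd = 1e-15, protein_conc = 1e-4,
                                ratios = c(0, 2), intensity_decay = 1.5)
  expect_true(all(s3$peaklists[[2]]$intensity == 0))
  expect_error(gen_titration_peaklists(free[0, ], deltas, 1e-4, 1e-4),
               "empty")
})

test_that("relaxation generator is consistent and monotone in tau_c", {
  t10 <- gen_relaxation_table(1:8, 0.85, 50, 10)
  t20 <- gen_relaxation_table(1:8, 0.85, 50, 20)
  expect_true(all(t20$T2 < t10$T2))  # slower tumbling, faster transverse decay
  expect_error(gen_relaxation_table(1:5, 1.2, 0, 10), "0, 1")
})

test_that("mass event generator respects weights and the CLT", {
  ev <- gen_mp_events(list(mixture_component(62, 6, 1)), 2000, seed = 2)
  expect_equal(mean(ev$masses), 62, tolerance = 0.4 / 62)
  ev2 <- gen_mp_events(list(mixture_component(31, 3, 0.5),
                            mixture_component(200, 3, 0.5)), 4000, seed = 3)
  frac <- mean(ev2$masses < 100)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 4000))
  expect_error(gen_mp_events(list(mixture_component(62, 6, 0.7)), 100),
               "sum to 1")
  expect_error(gen_mp_events(list(), 100), "empty")
  # instrument range filter reports what it removed
  ev3 <- gen_mp_events(list(mixture_component(31, 6, 1)), 2000, seed = 4,
                       instrument_range = c(30, 5000))
  expect_gt(ev3$n_filtered, 0)
  expect_true(all(ev3$masses >= 30))
})

test_that("toy interface generator plants exact geometry", {
  txt <- gen_toy_interface(toy_plants)
  coords <- parse_structure(txt)
  a <- coords$atoms
  glu <- a[a$atom_name == "OE1", ]
  arg <- a[a$atom_name == "NH1", ]
  d <- sqrt((glu$x - arg$x)^2 + (glu$y - arg$y)^2 + (glu$z - arg$z)^2)
  expect_equal(d, 3.0, tolerance = 0.01)
  expect_error(gen_toy_interface(list(
    planted_contact("GLU", "OE1", "ARG", "NH1", 0.5, 1, 2))), "overlap")
  expect_identical(gen_toy_interface(list()), "END")
})
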