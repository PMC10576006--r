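test_that("histogram conserves counts with left-closed right-open bins", {
  ev <- event_list(rep(62, 100))
  h <- build_histogram(ev)
  expect_identical(sum(h$count), 100L)
  expect_identical(sum(h$count > 0), 1L)
  h2 <- build_histogram(ev, bin_width = 1.25)
  expect_identical(sum(h2$count), 100L)
  # boundary mass falls in the bin it opens
  ev3 <- event_list(c(32.5, 32.5))
  h3 <- build_histogram(ev3, 2.5)
  expect_identical(h3$count[h3$lower == 32.5], 2L)
  expect_error(build_histogram(event_list(numeric(0))), "empty")
  expect_error(build_histogram(ev, 0), "> 0")
})

test_that("events outside the instrument range are filtered and counted", {
  ev <- event_list(c(10, 40, 6000, 62), c(30, 5000))
  expect_identical(ev$n_filtered, 2L)
  expect_identical(sort(ev$masses), c(40, 62))
})

test_that("EM recovers a planted single component within the CLT bound", {
  ev <- gen_mp_events(list(mixture_component(62, 6, 1)), 2000, seed = 2)
  f <- fit_mixture(ev, 1, seed = 2)
  expect_equal(f$components$mean, 62, tolerance = 0.4 / 62)
  expect_equal(f$components$weight, 1)
})

test_that("EM recovers a planted two-component dimer/tetramer mixture", {
  ev <- gen_mp_events(list(mixture_component(31, 6, 0.3),
                           mixture_component(62, 6, 0.7)), 5000, seed = 1)
  f <- fit_mixture(ev, 2, seed = 1)
  expect_equal(f$components$mean, c(31, 62), tolerance = 1 / 31)
  expect_equal(f$components$weight, c(0.3, 0.7), tolerance = 0.03 / 0.3)
  # k = 1 on bimodal data: inflated sd, strictly worse likelihood
  f1 <- fit_mixture(ev, 1, seed = 1)
  expect_gt(f1$components$sd, 10)
  expect_lt(f1$loglik, f$loglik)
  # deterministic given seed
  f_again <- fit_mixture(ev, 2, seed = 1)
  expect_identical(f$components, f_again$components)
  expect_error(fit_mixture(ev, 600), "10\\*k")
})

test_that("EM is scale-equivariant", {
  ev <- gen_mp_events(list(mixture_component(31, 6, 0.4),
                           mixture_component(62, 6, 0.6)), 2000, seed = 3)
  f <- fit_mixture(ev, 2, seed = 5)
  ev_scaled <- event_list(ev$masses * 3, c(-Inf, Inf))
  f3 <- fit_mixture(ev_scaled, 2, seed = 5)
  expect_equal(f3$components$mean, 3 * f$components$mean, tolerance = 1e-5)
  expect_equal(f3$components$sd, 3 * f$components$sd, tolerance = 1e-4)
})

test_that("binned least-squares cross-check agrees with EM on means", {
  ev <- gen_mp_events(list(mixture_component(31, 6, 0.3),
                           mixture_component(62, 6, 0.7)), 5000, seed = 1)
  em <- fit_mixture(ev, 2, seed = 1)
  ls <- fit_mixture_binned(ev, 2)
  expect_equal(ls$components$mean, em$components$mean, tolerance = 0.5 / 31)
})

test_that("mass ladder arithmetic and validation", {
  lad <- mass_ladder(c(kras = 19.9, rgl2 = 11.0),
                     list(heterodimer = c(kras = 1, rgl2 = 1),
                          heterotetramer = c(kras = 2, rgl2 = 2)))
  expect_equal(unname(lad["heterodimer"]), 30.9)
  expect_equal(unname(lad["heterotetramer"]), 61.8)
  # default profile reproduces the printed ~61.7 kD tetramer
  lad2 <- mass_ladder(default_subunits(),
                      list(tetramer = c(kras_g12v = 2, rgl2ra = 2)))
  expect_equal(unname(lad2["tetramer"]), 61.7, tolerance = 1e-3)
  expect_length(mass_ladder(c(a = 1), list()), 0L)
  expect_error(mass_ladder(c(a = 1), list(c(b = 2))), "unknown subunit")
})

test_that("component assignment uses relative error with a tolerance gate", {
  lad <- mass_ladder(c(kras = 19.9, rgl2 = 11.0),
                     list(heterodimer = c(kras = 1, rgl2 = 1),
                          heterotetramer = c(kras = 2, rgl2 = 2)))
  a68 <- assign_components(68, lad)
  expect_identical(a68$species, "heterotetramer")
  expect_equal(a68$rel_error, abs(68 - 61.8) / 61.8, tolerance = 1e-12)
  exact <- assign_components(30.9, lad)
  expect_equal(exact$rel_error, 0)
  a45 <- assign_components(45, lad)
  expect_false(a45$assigned)
  expect_equal(a45$rel_error, abs(45 - 61.8) / 61.8, tolerance = 1e-9)
  # assignment invariant to ladder ordering
  lad_rev <- structure(rev(unclass(lad)), class = "oligomer_ladder")
  expect_identical(assign_components(68, lad_rev)$species, "heterotetramer")
  expect_error(assign_components(68, mass_ladder(c(a = 1), list())), "empty")
})

test_that("planted ladder species recovered end to end", {
  lad <- mass_ladder(default_subunits(),
                     list(heterodimer = c(kras_g12v = 1, rgl2ra = 1),
                          heterotetramer = c(kras_g12v = 2, rgl2ra = 2)))
  ev <- gen_mp_events(list(mixture_component(unname(lad[1]), 6, 0.4),
                           mixture_component(unname(lad[2]), 6, 0.6)),
                      5000, seed = 11)
  f <- fit_mixture(ev, 2, seed = 11)
  asg <- assign_components(f, lad)
  expect_identical(asg$species, c("heterodimer", "heterotetramer"))
  expect_true(all(asg$assigned))
})

test_that("event CSV round-trips", {
  ev <- gen_mp_events(list(mixture_component(62, 6, 1)), 200, seed = 4)
  path <- tempfile(fileext = ".csv")
  write_events(ev, path)
  ev2 <- read_events(path, c(-Inf, Inf))
  expect_equal(ev2$masses, ev$masses)
})
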