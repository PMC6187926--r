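test_that("default medium constants and flow rate are the reference values", {
  p <- default_physical_params()
  expect_equal(p$rho, 993.3)
  expect_equal(p$mu, 6.92e-4)
  expect_equal(p$Q, 5e-9 / 60)          # 5 uL/min in m^3/s
  expect_equal(p$Q, 8.3333e-11, tolerance = 1e-4)
})

test_that("default species carry the reference transport constants", {
  ox <- default_species("oxygen")
  expect_equal(ox$D_medium, 2.6e-9)
  expect_equal(ox$D_pdms, 3.4e-9)
  expect_equal(ox$D_tissue, 1.83e-9)
  expect_equal(ox$S_pdms, 6)
  expect_equal(ox$S_tissue, 4.81)
  expect_equal(ox$Vmax, 0.0203)
  expect_equal(ox$Km, 0.00463)
  expect_equal(ox$c_inlet, 0.2)
  expect_true(ox$pdms_permeable)

  gl <- default_species("glucose")
  expect_equal(gl$D_medium, 9.27e-10)
  expect_equal(gl$D_tissue, 2.7e-10)
  expect_equal(gl$S_tissue, 1)
  expect_equal(gl$Vmax, 0.01076)
  expect_equal(gl$Km, 0.04)
  expect_equal(gl$c_inlet, 11)
  expect_false(gl$pdms_permeable)

  expect_error(default_species("lactate"))
})

test_that("knudsen_number matches the continuum-check value and is scale free", {
  expect_identical(knudsen_number(0.25e-9, 80e-6), 3.125e-6)
  expect_identical(knudsen_number(1e-6, 1e-6), 1)
  expect_identical(knudsen_number(0.25e-9, 1e-3), 2.5e-7)
  expect_error(knudsen_number(-1e-9, 1e-6))
  expect_error(knudsen_number(1e-9, 0))
  # homogeneity of degree 0
  set.seed(7)
  for (i in 1:20) {
    lam <- runif(1, 1e-10, 1e-8); L <- runif(1, 1e-6, 1e-3)
    s <- runif(1, 0.1, 100)
    expect_equal(knudsen_number(s * lam, s * L), knudsen_number(lam, L))
  }
})

test_that("parameter objects round-trip through config serialization", {
  sc <- scenario(geometry = small_chip_spec(), spacing = 10e-6)
  lst <- scenario_to_list(sc)
  sc2 <- scenario_from_list(lst)
  expect_equal(unclass(sc2$physical), unclass(sc$physical))
  expect_equal(lapply(sc2$species, unclass), lapply(sc$species, unclass))
  expect_equal(unclass(sc2$geometry), unclass(sc$geometry))
  expect_equal(sc2$spacing, sc$spacing)
  # JSON file round trip
  f <- tempfile(fileext = ".json")
  write_scenario_config(sc, f)
  sc3 <- read_scenario_config(f)
  expect_equal(unclass(sc3$geometry), unclass(sc$geometry), tolerance = 1e-12)
  expect_equal(unclass(sc3$physical), unclass(sc$physical), tolerance = 1e-12)
})

test_that("unknown config keys are rejected with the offending name", {
  expect_error(scenario_from_list(list(geometry = list(trap_heihgt = 600))),
               "trap_heihgt")
  expect_error(aggtrap:::species_from_list(list(name = "oxygen", Vmax2 = 1)),
               "Vmax2")
  expect_error(aggtrap:::physical_params_from_list(list(rho = 1, muu = 2)),
               "muu")
})
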