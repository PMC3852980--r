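test_that("total-water mole fraction counts dissociated ions", {
  w <- water_species(); s <- nacl_species()
  pure <- fs_composition(c(water = 55.35), list(w), chamber = "I")
  expect_equal(total_water_mole_fraction(pure), 1)
  saline <- fs_composition(c(water = 55.35, nacl = 0.15), list(w, s),
                           chamber = "I")
  expect_equal(total_water_mole_fraction(saline), 55.35 / 55.65)
  expect_error(total_water_mole_fraction(
    fs_composition(c(water = 0, nacl = 0.1), list(w, s), chamber = "I")),
    "solvent")
})

test_that("free-water mole fraction removes bound water and bound ion-moles", {
  w <- water_species(); s <- nacl_species()
  p <- fs_species("p", "protein", 5e4)
  comp <- fs_composition(c(water = 50, p = 0.001, nacl = 0.01),
                         list(w, p, s))
  b <- fs_binding(matrix(c(1000, 5), 2, 1,
                         dimnames = list(c("water", "nacl"), "p")))
  # hand arithmetic: free water 49, complex 0.001, free ions 2 x 0.005
  expect_equal(free_water_mole_fraction(comp, b), 49 / 49.011,
               tolerance = 1e-15)
  # zero binding degenerates to the total-water fraction
  b0 <- fs_binding_zero(c("water", "nacl"), "p")
  expect_equal(free_water_mole_fraction(comp, b0),
               total_water_mole_fraction(comp))
  # protein-free chamber: binding is irrelevant
  ch1 <- fs_composition(c(water = 50, nacl = 0.01), list(w, s),
                        chamber = "I")
  expect_equal(free_water_mole_fraction(ch1, b),
               total_water_mole_fraction(ch1))
})

test_that("infeasible binding errors name the exhausted species", {
  w <- water_species(); s <- nacl_species()
  p <- fs_species("p", "protein", 5e4)
  comp <- fs_composition(c(water = 10, p = 0.01, nacl = 0.01),
                         list(w, p, s))
  expect_error(free_water_mole_fraction(comp,
    fs_binding(matrix(c(2000, 0), 2, 1,
                      dimnames = list(c("water", "nacl"), "p")))),
    "water")
  expect_error(free_water_mole_fraction(comp,
    fs_binding(matrix(c(0, 5), 2, 1,
                      dimnames = list(c("water", "nacl"), "p")))),
    "nacl")
})

test_that("ideal pressure follows the log mole-fraction ratio", {
  sys <- bsa_reference_system()
  ch <- system_chambers(sys, 0)
  expect_equal(osmotic_pressure_ideal(ch$II, ch$I, sys$conditions), 0)
  # a mole-fraction ratio of exp(-1) gives exactly RT/V1
  w <- water_species()
  cond <- fs_conditions(298.15)
  n <- 55
  x_ratio_target <- exp(-1)
  p <- fs_species("p", "protein", 5e4)
  n2 <- n * (1 / x_ratio_target - 1)
  cII <- fs_composition(c(water = n, p = n2), list(w, p))
  cI <- fs_composition(c(water = n), list(w), chamber = "I")
  expect_equal(osmotic_pressure_ideal(cII, cI, cond),
               cond$gas_constant * 298.15 / cond$solvent_molar_volume,
               tolerance = 1e-12)
})

test_that("dilute, salt-free pressure approaches the van't Hoff limit", {
  w <- water_species()
  p <- bsa_species()
  cond <- fs_conditions(298.15)
  for (conc in c(0.25, 1)) {
    cII <- composition_from_prep(conc, p, 0, NULL)
    cI <- composition_from_prep(0, p, 0, NULL, chamber = "I")
    pi <- osmotic_pressure_ideal(cII, cI, cond)
    vant_hoff <- cond$gas_constant * 298.15 * conc / 66430 * 1000  # Pa
    expect_lt(abs(pi - vant_hoff) / vant_hoff, 0.01)
  }
})

test_that("free-solvent pressure: zero binding, identity and oracle value", {
  sys <- bsa_reference_system()
  ch <- system_chambers(sys, 300)
  b0 <- fs_binding_zero(c("water", "nacl"), "bsa")
  expect_equal(
    osmotic_pressure_freesolvent(ch$II, ch$I, b0, sys$conditions),
    osmotic_pressure_ideal(ch$II, ch$I, sys$conditions))
  # identical chambers (no protein) give zero pressure for any feasible nu
  ch0 <- system_chambers(sys, 0)
  b <- freesolvent:::system_binding(sys)
  expect_equal(
    osmotic_pressure_freesolvent(ch0$II, ch0$I, b, sys$conditions), 0)
  # 300 g/L BSA against the 50-digit reference evaluation
  expect_equal(
    osmotic_pressure_freesolvent(ch$II, ch$I, b, sys$conditions),
    bsa300_oracle$pi_freesolvent, tolerance = 1e-12)
  expect_equal(free_water_mole_fraction(ch$II, b),
               bsa300_oracle$x_free_II, tolerance = 1e-14)
  expect_equal(total_water_mole_fraction(ch$II),
               bsa300_oracle$x_total_II, tolerance = 1e-14)
})

test_that("pressure is increasing in concentration and hydration, decreasing in ion binding", {
  sys <- bsa_reference_system()
  curve <- predict_osmotic_pressure(sys, seq(0, 450, by = 50))
  expect_true(all(diff(curve$pressure) > 0))
  pi_at <- function(nu_w, nu_s) {
    s <- fs_scenario("bsa_ph4.5", hydration = nu_w, ion_binding = nu_s)
    predict_osmotic_pressure(s, 350)$pressure
  }
  grid_w <- vapply(seq(500, 5000, length.out = 8), pi_at, numeric(1),
                   nu_s = 8)
  expect_true(all(diff(grid_w) > 0))
  # binding a salt formula unit removes its ion-moles from the chamber-II
  # free pool, so more ion binding lowers the pressure (chamber I fixed)
  grid_s <- vapply(seq(0, 15, length.out = 8), function(ns)
    pi_at(3000, ns), numeric(1))
  expect_true(all(diff(grid_s) < 0))
})

test_that("the single-protein monovalent-salt closed form matches the general path and the arbitrary-precision oracle", {
  # 100 seeded random instances evaluated at 50 decimal digits with mpmath,
  # frozen in oracle-pressures.csv
  oracle <- utils::read.csv(test_path("oracle-pressures.csv"))
  w <- water_species(); s <- nacl_species()
  for (i in seq_len(nrow(oracle))) {
    r <- oracle[i, ]
    cond <- fs_conditions(r$temperature, solvent_molar_volume = r$V1)
    pi_closed <- osmotic_pressure_closed_form(
      r$N1_II, r$N2, r$N3_II, r$N1_I, r$N3_I,
      r$nu_water, r$nu_salt, dissociation = 2, cond = cond)
    p <- fs_species("p", "protein", 6e4)
    cII <- fs_composition(c(water = r$N1_II, p = r$N2, nacl = r$N3_II),
                          list(w, p, s))
    cI <- fs_composition(c(water = r$N1_I, nacl = r$N3_I), list(w, s),
                         chamber = "I")
    b <- fs_binding(matrix(c(r$nu_water, r$nu_salt), 2, 1,
                           dimnames = list(c("water", "nacl"), "p")))
    pi_general <- osmotic_pressure_freesolvent(cII, cI, b, cond)
    expect_lt(abs(pi_general - pi_closed) / abs(pi_closed), 1e-12)
    expect_lt(abs(pi_general - r$pi_Pa) / abs(r$pi_Pa), 1e-12)
    expect_lt(abs(free_water_mole_fraction(cII, b) - r$x_free_II), 1e-13)
  }
})

test_that("pressure units convert through the standard constants", {
  expect_equal(convert_pressure(1, "atm", "Pa"), 101325)
  expect_equal(convert_pressure(760, "mmHg", "Pa"), 101325, tolerance = 1e-4)
  expect_equal(convert_pressure(convert_pressure(1234, "Pa", "mmHg"),
                                "mmHg", "Pa"), 1234)
  expect_error(convert_pressure(1, "bar", "Pa"), "unit")
})
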