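test_that("activity coefficient is exactly 1 with zero binding or zero protein", {
  sys <- bsa_reference_system()
  ch <- system_chambers(sys, 300)
  b0 <- fs_binding_zero(c("water", "nacl"), "bsa")
  expect_identical(predict_activity_coefficient(ch$II, ch$I, b0), 1)
  ch0 <- system_chambers(sys, 0)
  b <- freesolvent:::system_binding(sys)
  expect_equal(predict_activity_coefficient(ch0$II, ch0$I, b), 1,
               tolerance = 1e-15)
})

test_that("predicted activity coefficient matches the arbitrary-precision reference at 300 g/L", {
  sys <- bsa_reference_system()
  ch <- system_chambers(sys, 300)
  b <- freesolvent:::system_binding(sys)
  expect_equal(predict_activity_coefficient(ch$II, ch$I, b),
               bsa300_oracle$gamma, tolerance = 1e-13)
})

test_that("pressure inversion is the exact inverse of the forward relation", {
  sys <- bsa_reference_system()
  ch <- system_chambers(sys, 250)
  # the ideal pressure back-calculates to gamma = 1 by construction
  pi_id <- osmotic_pressure_ideal(ch$II, ch$I, sys$conditions)
  expect_equal(activity_coefficient_from_pressure(pi_id, ch$II, ch$I,
                                                  sys$conditions), 1,
               tolerance = 1e-12)
  # zero pressure across identical chambers
  ch0 <- system_chambers(sys, 0)
  expect_equal(activity_coefficient_from_pressure(0, ch0$II, ch0$I,
                                                  sys$conditions), 1,
               tolerance = 1e-15)
})

test_that("prediction and pressure-inversion agree over random feasible draws", {
  set.seed(42)
  for (rep in 1:50) {
    case <- random_feasible_case()
    ch <- system_chambers(case$sys, case$conc)
    b <- freesolvent:::system_binding(case$sys)
    # draws with small hydration and large ion binding legitimately give
    # gamma > 1, which warns by design; the identity must still hold
    g_pred <- suppressWarnings(
      predict_activity_coefficient(ch$II, ch$I, b))
    pi <- osmotic_pressure_freesolvent(ch$II, ch$I, b,
                                       case$sys$conditions)
    g_calc <- activity_coefficient_from_pressure(pi, ch$II, ch$I,
                                                 case$sys$conditions)
    expect_lt(abs(g_calc - g_pred) / g_pred, 1e-10)
  }
})

test_that("gamma is intensive: scaling all moles leaves it unchanged", {
  sys <- bsa_reference_system()
  b <- freesolvent:::system_binding(sys)
  ch <- system_chambers(sys, 320)
  scale_comp <- function(comp, k) {
    comp$moles <- comp$moles * k
    comp
  }
  g1 <- predict_activity_coefficient(ch$II, ch$I, b)
  g2 <- predict_activity_coefficient(scale_comp(ch$II, 7.3),
                                     scale_comp(ch$I, 7.3), b)
  expect_equal(g2, g1, tolerance = 1e-14)
})

test_that("gamma decreases from unity with concentration for realistic parameters", {
  for (name in c("bsa_ph4.5", "hb")) {
    sys <- fs_scenario(name)
    curve <- activity_curve(sys, conc = seq(0, 475, by = 25))
    expect_equal(curve$gamma[1], 1, tolerance = 1e-12)
    expect_true(all(diff(curve$gamma) < 0),
                info = paste("strictly decreasing for", name))
    expect_true(all(curve$gamma > 0 & curve$gamma <= 1))
  }
})

test_that("pathological parameters can push gamma above 1, with a warning", {
  sys <- fs_scenario("bsa_ph4.5", hydration = 1, ion_binding = 30)
  ch <- system_chambers(sys, 300)
  b <- freesolvent:::system_binding(sys)
  expect_warning(g <- predict_activity_coefficient(ch$II, ch$I, b),
                 "exceeds 1")
  expect_gt(g, 1)
})

test_that("activity_curve vectorizes both modes and collects per-row failures", {
  sys <- bsa_reference_system()
  expect_equal(nrow(activity_curve(sys, conc = numeric(0))), 0)
  one <- activity_curve(sys, conc = 0)
  expect_equal(one$gamma, 1, tolerance = 1e-15)
  # noiseless synthetic data: calculated curve equals predicted curve
  conc <- seq(0, 450, length.out = 10)
  d <- generate_osmotic_dataset(sys, conc = conc)
  pred <- activity_curve(sys, conc = conc, mode = "predicted")
  calc <- activity_curve(sys, dataset = d, mode = "calculated")
  expect_equal(calc$gamma, pred$gamma, tolerance = 1e-10)
  # a concentration beyond hydration saturation fails row-wise, not globally
  hungry <- fs_scenario("bsa_ph4.5", hydration = 9000)
  expect_warning(curve <- activity_curve(hungry, conc = c(100, 460)),
                 "rows failed")
  expect_false(is.na(curve$gamma[1]))
  expect_true(is.na(curve$gamma[2]))
  err <- attr(curve, "errors")
  expect_equal(err$row, 2L)
  expect_match(err$message, "infeasible")
})
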