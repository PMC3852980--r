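# Shared fixtures for the test suite.

bsa_species <- function() fs_species("bsa", "protein", 66430)
nacl_species <- function() fs_species("nacl", "salt", 58.443,
                                      dissociation_count = 2)
water_species <- function() fs_species("water", "solvent", 18.015)

# BSA in 0.15 M NaCl at 25 degC with hydration fixed at 1.144 g/g
# (equivalently 4218.480155... mol/mol) and 11.59 mol NaCl/mol BSA.
bsa_reference_system <- function() {
  fs_scenario("bsa_ph4.5", hydration_g_per_g = 1.144)
}

# Draw a random feasible (system, concentration) pair: BSA-like molar
# masses, physiological-to-concentrated salt, monolayer-scale hydration.
# Infeasible draws (hydration demand exceeding available water or salt)
# are rejected and redrawn.
random_feasible_case <- function() {
  repeat {
    M <- runif(1, 5e4, 8e4)
    conc <- runif(1, 5, 420)
    salt_M <- runif(1, 0.05, 0.3)
    nu_w <- runif(1, 500, 5000)
    nu_s <- runif(1, 0, 15)
    temp <- runif(1, 273.15, 310.15)
    n2 <- conc / M
    n1 <- 0.997 * (1000 - conc * 0.733) / 18.015
    if (n1 - nu_w * n2 <= 0.5 || salt_M - nu_s * n2 <= 0.005) next
    sys <- fs_system(
      protein = fs_species("prot", "protein", M),
      salt = nacl_species(), salt_molarity = salt_M,
      conditions = fs_conditions(temp),
      hydration = nu_w, ion_binding = nu_s,
      water = water_species())
    return(list(sys = sys, conc = conc))
  }
}

# Arbitrary-precision reference values for the BSA reference system at
# 300 g/L, evaluated at 50 decimal digits (mpmath) and truncated to double.
bsa300_oracle <- list(
  x_total_II = 0.99299599433320976,
  x_free_II = 0.99178377930243928,
  x_total_I = 0.99460846394843599,
  gamma = 0.99877923472230674,
  pi_freesolvent = 390180.11968192983,
  pi_ideal = 222598.15430483966,
  N1_II = 43.172894809880655,
  N2 = 0.0045160319132921873
)
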