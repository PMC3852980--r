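# Synthetic membrane-osmometry datasets: model pressures plus a seeded
# measurement-noise model, and the preset literature systems.

#' Measurement-noise model for synthetic osmometry
#'
#' @param kind `"none"`, `"multiplicative_gaussian"` (pressure scaled by
#'   `1 + scale * eps`, `eps ~ N(0, 1)`; `scale` is a relative fraction) or
#'   `"additive_gaussian"` (`scale` in Pa).
#' @param scale non-negative noise scale.
#' @param seed integer RNG seed; the same seed and parameters always
#'   reproduce the same dataset.  `NULL` uses the current RNG state.
#' @return An object of class `fs_noise`.
#' @export
noise_model <- function(kind = c("none", "multiplicative_gaussian",
                                 "additive_gaussian"),
                        scale = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(scale) || length(scale) != 1L || scale < 0)
    stop("noise scale must be a single non-negative number", call. = FALSE)
  structure(list(kind = kind, scale = scale, seed = seed),
            class = "fs_noise")
}

# run expr under a local, seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic osmotic-pressure dataset
#'
#' Evaluates the free-solvent model of a system over a concentration grid
#' and applies the measurement-noise model, emulating a membrane-osmometry
#' series (the default grids span 0-475 g/L for proteins at 0.15 M salt,
#' the classic concentrated-BSA design).  With `kind = "none"` the output
#' is the exact model pressure, bit-stable across runs.
#'
#' @param sys an [fs_system()].
#' @param conc concentration grid in g/L; defaults to 20 evenly spaced
#'   points from 0 to `sys$conc_max`.
#' @param noise an [fs_noise()] from [noise_model()].
#' @return A data.frame with columns `conc` (g/L) and `pressure` (Pa), with
#'   attributes `system` and `noise`.  Concentrations that are infeasible
#'   under the system's binding raise an error listing the offending rows.
#' @examples
#' sim <- generate_osmotic_dataset(fs_scenario("bsa_ph7.4"),
#'   noise = noise_model("multiplicative_gaussian", 0.02, seed = 17))
#' @export
generate_osmotic_dataset <- function(sys,
                                     conc = seq(0, sys$conc_max,
                                                length.out = 20),
                                     noise = noise_model("none")) {
  stopifnot(inherits(sys, "fs_system"), inherits(noise, "fs_noise"))
  binding <- system_binding(sys)
  pressure <- numeric(length(conc))
  bad <- character(0)
  for (i in seq_along(conc)) {
    res <- tryCatch({
      ch <- system_chambers(sys, conc[i])
      osmotic_pressure_freesolvent(ch$II, ch$I, binding, sys$conditions)
    }, error = function(e) e)
    if (inherits(res, "error"))
      bad <- c(bad, sprintf("row %d (conc %g g/L): %s", i, conc[i],
                            conditionMessage(res)))
    else pressure[i] <- res
  }
  if (length(bad))
    stop("infeasible concentrations:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  pressure <- with_local_seed(noise$seed, {
    switch(noise$kind,
           none = pressure,
           multiplicative_gaussian =
             pressure * (1 + noise$scale * stats::rnorm(length(pressure))),
           additive_gaussian =
             pressure + noise$scale * stats::rnorm(length(pressure)))
  })
  out <- data.frame(conc = conc, pressure = pressure)
  attr(out, "system") <- sys
  attr(out, "noise") <- noise
  out
}

#' Preset literature systems
#'
#' Ready-made [fs_system()] configurations for the five classic osmometry
#' systems: concentrated BSA in 0.15 M NaCl at 25 degC (pH 4.5, 5.4, 7.4,
#' differing only in ion binding: 11.59, 10.62, 8.81 mol NaCl/mol BSA),
#' sheep hemoglobin in 0.1 M KCl at 0 degC (6 mol KCl/mol Hb), and sucrose
#' in water at 30 degC (zero ion binding).  Protein hydrations default to
#' the SASA monolayer values (BSA: 27746 A^2, 1.144 g/g; Hb: 24759 A^2,
#' 0.973 g/g); sucrose defaults to 6 mol water/mol sucrose (0.316 g/g),
#' with 3.5 mol/mol the low end of the literature range.
#'
#' @return `preset_scenarios()`: a named list of [fs_system()] objects.
#' @examples
#' names(preset_scenarios())
#' fs_scenario("hb")
#' @export
preset_scenarios <- function() {
  water <- fs_species("water", "solvent", fs_constants$water_molar_mass)
  nacl <- fs_species("nacl", "salt", fs_constants$nacl_molar_mass,
                     dissociation_count = 2)
  kcl <- fs_species("kcl", "salt", fs_constants$kcl_molar_mass,
                    dissociation_count = 2)
  bsa <- fs_species("bsa", "protein", fs_constants$bsa_molar_mass)
  hb <- fs_species("hb", "protein", fs_constants$hb_molar_mass)
  sucrose <- fs_species("sucrose", "protein",
                        fs_constants$sucrose_molar_mass)
  bsa_sys <- function(nu3)
    fs_system(protein = bsa, salt = nacl, salt_molarity = 0.15,
              conditions = fs_conditions(298.15),
              sasa = 27746, ion_binding = nu3, water = water,
              conc_max = 475)
  list(
    `bsa_ph4.5` = bsa_sys(11.59),
    `bsa_ph5.4` = bsa_sys(10.62),
    `bsa_ph7.4` = bsa_sys(8.81),
    hb = fs_system(protein = hb, salt = kcl, salt_molarity = 0.1,
                   conditions = fs_conditions(273.15),
                   sasa = 24759, ion_binding = 6, water = water,
                   conc_max = 475),
    sucrose = fs_system(protein = sucrose, salt = NULL,
                        conditions = fs_conditions(303.15),
                        hydration = 6, ion_binding = 0, water = water,
                        partial_specific_volume = 0.621,
                        conc_max = 900)
  )
}

#' @rdname preset_scenarios
#' @param name one of `"bsa_ph4.5"`, `"bsa_ph5.4"`, `"bsa_ph7.4"`, `"hb"`,
#'   `"sucrose"`.
#' @param hydration optional override, mol water per mol macromolecule.
#' @param hydration_g_per_g optional override in g/g.
#' @param ion_binding optional override, mol salt per mol macromolecule.
#' @return `fs_scenario()`: a single [fs_system()].
#' @export
fs_scenario <- function(name, hydration = NULL, hydration_g_per_g = NULL,
                        ion_binding = NULL) {
  sc <- preset_scenarios()
  if (!name %in% names(sc))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(sc), collapse = ", "), call. = FALSE)
  sys <- sc[[name]]
  if (!is.null(hydration_g_per_g))
    hydration <- hydration_g_per_g_to_mol_per_mol(
      hydration_g_per_g, sys$protein$molar_mass, sys$water$molar_mass)
  if (!is.null(hydration)) sys$hydration <- hydration
  if (!is.null(ion_binding)) sys$ion_binding <- ion_binding
  sys
}
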