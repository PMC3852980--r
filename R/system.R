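# A solution system: species + prep + binding + conditions, the bundle the
# curve, regression and simulation layers all operate on.

#' Describe a macromolecule/salt/solvent system
#'
#' Bundles everything needed to evaluate the free-solvent model at any
#' macromolecule concentration: the species, the chamber-I salt molarity,
#' the thermodynamic conditions, the two binding parameters (hydration and
#' ion binding, both per mole of macromolecule), and the water-accounting
#' knobs.  Hydration may be supplied as mol/mol, as g/g, or via a SASA
#' (monolayer rule); exactly one of the three must be given.
#'
#' @param protein an [fs_species()] with role `"protein"` (any
#'   non-diffusible solute, e.g. sucrose, takes this role).
#' @param salt an [fs_species()] with role `"salt"`, or `NULL`.
#' @param salt_molarity chamber-I (and initial chamber-II) salt mol/L.
#' @param conditions an [fs_conditions()].
#' @param hydration mol water bound per mol macromolecule.
#' @param hydration_g_per_g alternative: g water per g macromolecule.
#' @param sasa alternative: SASA in Angstrom^2, converted with `coverage`.
#' @param coverage water molecules per nm^2, used with `sasa`.
#' @param ion_binding mol salt formula units bound per mol macromolecule.
#' @param water solvent [fs_species()].
#' @param partial_specific_volume macromolecule partial specific volume,
#'   mL/g.
#' @param water_density solvent density, g/mL.
#' @param basis_volume basis volume in L for the mole bookkeeping.
#' @param conc_max a soft upper concentration (g/L) used by default
#'   simulation grids.
#' @return An object of class `fs_system`.
#' @examples
#' bsa_system <- fs_system(
#'   protein = fs_species("bsa", "protein", 66430),
#'   salt = fs_species("nacl", "salt", 58.443, dissociation_count = 2),
#'   salt_molarity = 0.15,
#'   conditions = fs_conditions(298.15),
#'   sasa = 27746, ion_binding = 11.59)
#' @export
fs_system <- function(protein, salt = NULL, salt_molarity = 0,
                      conditions,
                      hydration = NULL, hydration_g_per_g = NULL,
                      sasa = NULL,
                      coverage = fs_constants$monolayer_coverage,
                      ion_binding = 0,
                      water = fs_species("water", "solvent",
                                         fs_constants$water_molar_mass),
                      partial_specific_volume =
                        fs_constants$protein_partial_specific_volume,
                      water_density = fs_constants$water_density,
                      basis_volume = 1,
                      conc_max = 475) {
  stopifnot(inherits(protein, "fs_species"), protein$role == "protein",
            inherits(conditions, "fs_conditions"))
  if (!is.null(salt)) {
    stopifnot(inherits(salt, "fs_species"), salt$role == "salt")
  } else if (salt_molarity > 0) {
    stop("salt_molarity > 0 requires a salt species", call. = FALSE)
  }
  given <- c(hydration = !is.null(hydration),
             g_per_g = !is.null(hydration_g_per_g),
             sasa = !is.null(sasa))
  if (sum(given) != 1L)
    stop("supply exactly one of hydration (mol/mol), hydration_g_per_g, sasa",
         call. = FALSE)
  if (!is.null(sasa)) {
    hyd <- hydration_from_sasa(sasa, protein$molar_mass, coverage,
                               water$molar_mass)
    hydration <- hyd$molar_hydration
  } else if (!is.null(hydration_g_per_g)) {
    hydration <- hydration_g_per_g_to_mol_per_mol(
      hydration_g_per_g, protein$molar_mass, water$molar_mass)
  }
  if (hydration < 0 || ion_binding < 0)
    stop("binding parameters must be non-negative", call. = FALSE)
  if (ion_binding > 0 && is.null(salt))
    stop("ion_binding > 0 requires a salt species", call. = FALSE)
  structure(
    list(protein = protein, salt = salt, salt_molarity = salt_molarity,
         conditions = conditions, water = water,
         hydration = hydration, ion_binding = ion_binding,
         sasa = if (is.null(sasa)) NA_real_ else sasa,
         coverage = coverage,
         partial_specific_volume = partial_specific_volume,
         water_density = water_density, basis_volume = basis_volume,
         conc_max = conc_max),
    class = "fs_system"
  )
}

#' @export
print.fs_system <- function(x, ...) {
  cat(sprintf("<fs_system> %s", x$protein$id))
  if (!is.null(x$salt))
    cat(sprintf(" in %g M %s", x$salt_molarity, x$salt$id))
  cat(sprintf(", T = %g K\n", x$conditions$temperature))
  cat(sprintf("  hydration  : %.6g mol/mol (%.4g g/g)\n", x$hydration,
              hydration_mol_per_mol_to_g_per_g(x$hydration,
                                               x$protein$molar_mass,
                                               x$water$molar_mass)))
  cat(sprintf("  ion binding: %.6g mol/mol\n", x$ion_binding))
  invisible(x)
}

# Replace the binding parameters of a system (used by the regression).
system_with_binding <- function(sys, hydration = sys$hydration,
                                ion_binding = sys$ion_binding) {
  sys$hydration <- hydration
  sys$ion_binding <- ion_binding
  sys
}

#' Chamber compositions of a system at one concentration
#'
#' @param sys an [fs_system()].
#' @param conc macromolecule concentration in g/L (scalar).
#' @return A list with elements `II` and `I`, both [fs_composition()].
#' @export
system_chambers <- function(sys, conc) {
  stopifnot(inherits(sys, "fs_system"), length(conc) == 1L)
  args <- list(protein_conc = conc, protein = sys$protein,
               salt_molarity = sys$salt_molarity, salt = sys$salt,
               basis_volume = sys$basis_volume,
               partial_specific_volume = sys$partial_specific_volume,
               water_density = sys$water_density, water = sys$water)
  list(II = do.call(composition_from_prep, c(args, chamber = "II")),
       I = do.call(composition_from_prep, c(args, chamber = "I")))
}

# Binding matrix of a system, rows = diffusible species, col = macromolecule.
system_binding <- function(sys) {
  ids <- c(sys$water$id, if (!is.null(sys$salt)) sys$salt$id)
  nu <- matrix(c(sys$hydration, if (!is.null(sys$salt)) sys$ion_binding),
               ncol = 1, dimnames = list(ids, sys$protein$id))
  fs_binding(nu)
}

#' Predict osmotic pressure over a concentration grid
#'
#' Evaluates the free-solvent (or ideal) osmotic pressure of a system at
#' each macromolecule concentration.
#'
#' @param sys an [fs_system()].
#' @param conc numeric vector of concentrations in g/L.
#' @param model `"freesolvent"` (default) or `"ideal"`.
#' @return A data.frame with columns `conc` (g/L) and `pressure` (Pa).
#' @examples
#' sys <- fs_scenario("bsa_ph7.4")
#' predict_osmotic_pressure(sys, c(100, 300, 400))
#' @export
predict_osmotic_pressure <- function(sys, conc,
                                     model = c("freesolvent", "ideal")) {
  model <- match.arg(model)
  stopifnot(inherits(sys, "fs_system"))
  binding <- system_binding(sys)
  pressure <- vapply(conc, function(cc) {
    ch <- system_chambers(sys, cc)
    if (model == "freesolvent")
      osmotic_pressure_freesolvent(ch$II, ch$I, binding, sys$conditions)
    else
      osmotic_pressure_ideal(ch$II, ch$I, sys$conditions)
  }, numeric(1))
  data.frame(conc = conc, pressure = pressure)
}
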