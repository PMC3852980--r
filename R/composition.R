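# Species / solution bookkeeping and unit conversions.
#
# Conventions used throughout the package:
#   * amounts of substance in mol on a declared basis volume (L)
#   * temperature in K, pressure in Pa, molar masses in g/mol
#   * SASA in Angstrom^2, surface coverage in water molecules per nm^2
#   * salt binding counted in formula units of undissociated salt

#' Physical constants and reference molar masses
#'
#' Full-precision molar masses and defaults used by the preset scenarios and
#' the composition bookkeeping.  All values are overridable wherever they
#' appear as function arguments; this list is the single place the defaults
#' live.
#'
#' @format A named list:
#' \describe{
#'   \item{water_molar_mass}{18.015 g/mol}
#'   \item{water_density}{0.997 g/mL (25 degC)}
#'   \item{bsa_molar_mass}{66430 g/mol}
#'   \item{hb_molar_mass}{69700 g/mol}
#'   \item{sucrose_molar_mass}{342.30 g/mol}
#'   \item{nacl_molar_mass}{58.443 g/mol}
#'   \item{kcl_molar_mass}{74.551 g/mol}
#'   \item{monolayer_coverage}{15.2 water molecules per nm^2 of SASA}
#'   \item{protein_partial_specific_volume}{0.733 mL/g, typical globular protein}
#'   \item{gas_constant}{8.314462618 J/(mol K)}
#' }
#' @export
fs_constants <- list(
  water_molar_mass = 18.015,
  water_density = 0.997,
  bsa_molar_mass = 66430,
  hb_molar_mass = 69700,
  sucrose_molar_mass = 342.30,
  nacl_molar_mass = 58.443,
  kcl_molar_mass = 74.551,
  monolayer_coverage = 15.2,
  protein_partial_specific_volume = 0.733,
  gas_constant = 8.314462618
)

#' Define a chemical species
#'
#' A species is identified by a short label and carries the two quantities the
#' free-solvent model needs: a molar mass and a dissociation count (ions per
#' formula unit; 1 for the solvent, proteins and non-electrolytes, 2 for a
#' monovalent salt such as NaCl or KCl).
#'
#' @param id short character label, e.g. `"water"`, `"bsa"`, `"nacl"`.
#' @param role one of `"solvent"`, `"protein"`, `"salt"`.
#' @param molar_mass molar mass in g/mol; must be positive.
#' @param dissociation_count positive integer number of ions per formula unit.
#' @return An object of class `fs_species`.
#' @examples
#' fs_species("nacl", "salt", 58.443, dissociation_count = 2)
#' @export
fs_species <- function(id, role = c("solvent", "protein", "salt"),
                       molar_mass, dissociation_count = 1L) {
  role <- match.arg(role)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.numeric(molar_mass) || length(molar_mass) != 1L || molar_mass <= 0)
    stop("molar_mass must be a single positive number", call. = FALSE)
  d <- as.integer(dissociation_count)
  if (is.na(d) || d < 1L)
    stop("dissociation_count must be a positive integer", call. = FALSE)
  structure(
    list(id = id, role = role, molar_mass = molar_mass,
         dissociation_count = d),
    class = "fs_species"
  )
}

#' @export
print.fs_species <- function(x, ...) {
  cat(sprintf("<fs_species> %s (%s), M = %g g/mol, d = %d\n",
              x$id, x$role, x$molar_mass, x$dissociation_count))
  invisible(x)
}

#' Thermodynamic conditions of an osmometry experiment
#'
#' Bundles the temperature, gas constant and partial molar volume of the
#' solvent used in the pressure equations.
#'
#' @param temperature absolute temperature in K.
#' @param solvent_molar_volume partial molar volume of the solvent in m^3/mol;
#'   the default is the molar volume of water at 25 degC,
#'   `18.015 / 0.997 * 1e-6`.
#' @param gas_constant in J/(mol K).
#' @return An object of class `fs_conditions`.
#' @export
fs_conditions <- function(temperature,
                          solvent_molar_volume =
                            fs_constants$water_molar_mass /
                            fs_constants$water_density * 1e-6,
                          gas_constant = fs_constants$gas_constant) {
  if (!is.numeric(temperature) || length(temperature) != 1L || temperature <= 0)
    stop("temperature must be a single positive number (K)", call. = FALSE)
  if (!is.numeric(solvent_molar_volume) || solvent_molar_volume <= 0)
    stop("solvent_molar_volume must be positive (m^3/mol)", call. = FALSE)
  structure(
    list(temperature = temperature,
         solvent_molar_volume = solvent_molar_volume,
         gas_constant = gas_constant),
    class = "fs_conditions"
  )
}

#' @export
print.fs_conditions <- function(x, ...) {
  cat(sprintf("<fs_conditions> T = %g K, V1 = %g m^3/mol, R = %g J/(mol K)\n",
              x$temperature, x$solvent_molar_volume, x$gas_constant))
  invisible(x)
}

#' Chamber composition: moles of every species on a basis volume
#'
#' Describes one compartment of a two-chamber membrane osmometer.  Chamber II
#' holds the non-diffusible macromolecule; chamber I holds only solvent and
#' diffusible ions and therefore must contain no protein species.
#'
#' @param moles named numeric vector, species id -> mol; all non-negative.
#' @param species list of [fs_species()] covering every name in `moles`;
#'   exactly one must have role `"solvent"`.
#' @param chamber `"I"` or `"II"`.
#' @param basis_volume the solution volume (L) the moles refer to.
#' @return An object of class `fs_composition`.
#' @export
fs_composition <- function(moles, species, chamber = c("II", "I"),
                           basis_volume = 1) {
  chamber <- match.arg(chamber)
  if (is.null(names(moles)) || any(!nzchar(names(moles))))
    stop("moles must be a fully named numeric vector", call. = FALSE)
  if (any(moles < 0))
    stop("all species moles must be non-negative", call. = FALSE)
  if (inherits(species, "fs_species")) species <- list(species)
  ids <- vapply(species, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate species ids", call. = FALSE)
  missing_ids <- setdiff(names(moles), ids)
  if (length(missing_ids))
    stop("no species definition for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  species <- species[match(names(moles), ids)]
  roles <- vapply(species, `[[`, character(1), "role")
  if (sum(roles == "solvent") != 1L)
    stop("a composition must contain exactly one solvent species",
         call. = FALSE)
  if (chamber == "I" && any(roles == "protein" & moles > 0))
    stop("chamber I must not contain protein species", call. = FALSE)
  if (!is.numeric(basis_volume) || basis_volume <= 0)
    stop("basis_volume must be positive (L)", call. = FALSE)
  structure(
    list(moles = moles, species = species, chamber = chamber,
         basis_volume = basis_volume),
    class = "fs_composition"
  )
}

#' @export
print.fs_composition <- function(x, ...) {
  cat(sprintf("<fs_composition> chamber %s, basis %g L\n", x$chamber,
              x$basis_volume))
  roles <- vapply(x$species, `[[`, character(1), "role")
  for (i in seq_along(x$moles))
    cat(sprintf("  %-10s %-8s %g mol\n", names(x$moles)[i], roles[i],
                x$moles[i]))
  invisible(x)
}

# role lookup helpers used by the mole-fraction code
comp_roles <- function(comp) vapply(comp$species, `[[`, character(1), "role")
comp_dissoc <- function(comp)
  vapply(comp$species, function(s) as.numeric(s$dissociation_count), numeric(1))

#' Binding matrix: moles of diffusible species bound per mole of protein
#'
#' `nu[i, j]` is the number of moles of diffusible species `i` (solvent or
#' salt) bound to one mole of protein `j`.  Salt binding is counted in
#' formula units of the undissociated salt (e.g. mol NaCl per mol protein),
#' not in ion moles.  Feasibility (bound moles not exceeding available moles)
#' is checked at evaluation time against a concrete composition, because it
#' depends on the composition.
#'
#' @param nu numeric matrix with rownames = diffusible species ids and
#'   colnames = protein ids; all entries non-negative.  A named list of named
#'   vectors (`list(protein_id = c(species_id = nu))`) is also accepted.
#' @return An object of class `fs_binding`.
#' @examples
#' fs_binding(matrix(c(4218, 11.59), nrow = 2,
#'                   dimnames = list(c("water", "nacl"), "bsa")))
#' @export
fs_binding <- function(nu) {
  if (is.list(nu) && !is.matrix(nu)) {
    prot <- names(nu)
    sp <- unique(unlist(lapply(nu, names)))
    m <- matrix(0, nrow = length(sp), ncol = length(prot),
                dimnames = list(sp, prot))
    for (j in prot) m[names(nu[[j]]), j] <- nu[[j]]
    nu <- m
  }
  if (!is.matrix(nu) || is.null(rownames(nu)) || is.null(colnames(nu)))
    stop("nu must be a matrix with species rownames and protein colnames",
         call. = FALSE)
  if (any(nu < 0))
    stop("all binding coefficients must be non-negative", call. = FALSE)
  structure(list(nu = nu, salt_convention = "formula_units"),
            class = "fs_binding")
}

#' A zero-binding matrix (ideal-solution limit)
#'
#' @param species_ids diffusible species ids (rows).
#' @param protein_ids protein ids (columns).
#' @return An [fs_binding()] with all coefficients zero.
#' @export
fs_binding_zero <- function(species_ids, protein_ids) {
  fs_binding(matrix(0, length(species_ids), length(protein_ids),
                    dimnames = list(species_ids, protein_ids)))
}

#' @export
print.fs_binding <- function(x, ...) {
  cat("<fs_binding> mol bound per mol protein (salt in formula units)\n")
  print(x$nu)
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used when
#' comparing computed hydration values against printed 3-decimal literature
#' values (base R's `round()` rounds ties to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_away(0.3165, 3)  # 0.317
#' @export
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Hydration from solvent-accessible surface area
#'
#' Converts a SASA value to a monolayer hydration, assuming a fixed surface
#' coverage of water molecules per nm^2 of accessible area (default 15.2).
#' With SASA in Angstrom^2 and 1 nm^2 = 100 Angstrom^2, the molar hydration
#' is `sasa / 100 * coverage` mol water per mol macromolecule.
#'
#' @param sasa solvent-accessible surface area in Angstrom^2 (>= 0).
#' @param molar_mass macromolecule molar mass in g/mol.
#' @param coverage water molecules per nm^2 of surface area.
#' @param water_molar_mass molar mass of water in g/mol.
#' @return An object of class `fs_hydration` with fields `sasa`, `coverage`,
#'   `molar_hydration` (mol water / mol macromolecule) and
#'   `specific_hydration` (g water / g macromolecule).
#' @examples
#' # BSA homology model, GETAREA surface area
#' hydration_from_sasa(27746, molar_mass = 66430)
#' @export
hydration_from_sasa <- function(sasa, molar_mass,
                                coverage = fs_constants$monolayer_coverage,
                                water_molar_mass = fs_constants$water_molar_mass) {
  if (!is.numeric(sasa) || length(sasa) != 1L || sasa < 0)
    stop("sasa must be a single non-negative number (Angstrom^2)",
         call. = FALSE)
  stopifnot(coverage > 0, molar_mass > 0, water_molar_mass > 0)
  molar <- sasa / 100 * coverage
  structure(
    list(sasa = sasa, coverage = coverage,
         molar_hydration = molar,
         specific_hydration = molar * water_molar_mass / molar_mass,
         macromolecule_molar_mass = molar_mass,
         water_molar_mass = water_molar_mass),
    class = "fs_hydration"
  )
}

#' @export
print.fs_hydration <- function(x, ...) {
  cat(sprintf(
    "<fs_hydration> SASA %g A^2 @ %g /nm^2 -> %.6g mol/mol = %.6g g/g\n",
    x$sasa, x$coverage, x$molar_hydration, x$specific_hydration))
  invisible(x)
}

#' Hydration unit conversions
#'
#' Exact inverse conversions between specific hydration (g water per g
#' macromolecule) and molar hydration (mol water per mol macromolecule).
#'
#' @param h specific hydration in g/g (non-negative).
#' @param nu molar hydration in mol/mol (non-negative).
#' @param molar_mass macromolecule molar mass in g/mol.
#' @param water_molar_mass molar mass of water in g/mol.
#' @return The hydration in the other unit.
#' @examples
#' hydration_g_per_g_to_mol_per_mol(0.316, 342.30)  # sucrose, ~6 mol/mol
#' @export
hydration_g_per_g_to_mol_per_mol <- function(h, molar_mass,
                                             water_molar_mass = fs_constants$water_molar_mass) {
  if (any(h < 0)) stop("hydration must be non-negative", call. = FALSE)
  h * molar_mass / water_molar_mass
}

#' @rdname hydration_g_per_g_to_mol_per_mol
#' @export
hydration_mol_per_mol_to_g_per_g <- function(nu, molar_mass,
                                             water_molar_mass = fs_constants$water_molar_mass) {
  if (any(nu < 0)) stop("hydration must be non-negative", call. = FALSE)
  nu * water_molar_mass / molar_mass
}

#' Build chamber compositions from a solution prep
#'
#' Converts a bench-style description of a protein solution (protein in g/L,
#' salt molarity) into species moles on a basis volume.  Water fills the
#' volume not excluded by the protein, using the protein partial specific
#' volume; the volume of dissolved salt is neglected:
#' `N_water = rho_w * (1000 * V - C * V * v_p) / M_w`.
#' Chamber I is obtained by the same rule with the protein concentration set
#' to zero.
#'
#' @param protein_conc protein concentration in g/L (>= 0).
#' @param protein an [fs_species()] with role `"protein"`.
#' @param salt_molarity salt concentration in mol/L (>= 0).
#' @param salt an [fs_species()] with role `"salt"`, or `NULL` for a
#'   salt-free solution.
#' @param basis_volume basis volume in L.
#' @param partial_specific_volume protein partial specific volume in mL/g.
#' @param water_density solvent density in g/mL.
#' @param water the solvent [fs_species()].
#' @param chamber `"II"` (with protein) or `"I"` (protein-free filtrate).
#' @return An [fs_composition()].
#' @examples
#' bsa <- fs_species("bsa", "protein", 66430)
#' nacl <- fs_species("nacl", "salt", 58.443, dissociation_count = 2)
#' composition_from_prep(300, bsa, 0.15, nacl)
#' @export
composition_from_prep <- function(protein_conc, protein,
                                  salt_molarity = 0, salt = NULL,
                                  basis_volume = 1,
                                  partial_specific_volume =
                                    fs_constants$protein_partial_specific_volume,
                                  water_density = fs_constants$water_density,
                                  water = fs_species("water", "solvent",
                                                     fs_constants$water_molar_mass),
                                  chamber = c("II", "I")) {
  chamber <- match.arg(chamber)
  if (protein_conc < 0 || salt_molarity < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (chamber == "I") protein_conc <- 0
  if (protein_conc * partial_specific_volume >= 1000)
    stop(sprintf(
      "infeasible composition: protein volume %g mL exceeds the 1000 mL basis",
      protein_conc * partial_specific_volume), call. = FALSE)
  v <- basis_volume
  n_protein <- protein_conc * v / protein$molar_mass
  n_water <- water_density *
    (1000 * v - protein_conc * v * partial_specific_volume) /
    water$molar_mass
  moles <- c(n_water, n_protein)
  names(moles) <- c(water$id, protein$id)
  species <- list(water, protein)
  if (!is.null(salt)) {
    moles <- c(moles, stats::setNames(salt_molarity * v, salt$id))
    species <- c(species, list(salt))
  }
  # drop the protein entry entirely in the filtrate chamber
  if (chamber == "I") {
    keep <- names(moles) != protein$id
    moles <- moles[keep]
    species <- species[keep]
  }
  fs_composition(moles, species, chamber = chamber, basis_volume = v)
}
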