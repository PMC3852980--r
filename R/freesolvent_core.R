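# Free-solvent model core: total- and free-water mole fractions in both
# osmometer chambers and osmotic-pressure prediction.
#
# The model treats the protein plus its bound water and bound ions as a
# single "hydrated macromolecule" species; the remaining (free) solvent is
# then ideal.  Bound salt is removed in formula units and each removed
# formula unit takes its full dissociation count of ion-moles out of the
# free-ion pool.

#' Total-water mole fraction of a chamber
#'
#' The mole fraction of solvent counting all solvent (bound or not), with
#' salts contributing their dissociated ion moles:
#' `x1 = N1 / (N1 + sum_j N_j + sum_k d_k * N_k)` where `j` runs over
#' proteins and `k` over salts with dissociation count `d_k`.
#'
#' @param comp an [fs_composition()]; solvent moles must be positive.
#' @return The solvent mole fraction, in (0, 1].
#' @export
total_water_mole_fraction <- function(comp) {
  stopifnot(inherits(comp, "fs_composition"))
  t <- chamber_terms(comp)
  t$F / (t$F + t$D)
}

# Numerator/denominator decomposition of a chamber's solvent mole fraction:
# F = (free) solvent moles, D = everything else in the denominator
# (protein complexes plus dissociated free-ion moles), so x = F / (F + D).
# With binding = NULL all solvent and salt count as free (total-water case).
# Keeping F and D separate lets the pressure kernel evaluate the
# chamber-II/chamber-I ratio without cancellation (see pressure_from_terms).
chamber_terms <- function(comp, binding = NULL) {
  roles <- comp_roles(comp)
  d <- comp_dissoc(comp)
  solvent_id <- names(comp$moles)[roles == "solvent"]
  if (comp$moles[solvent_id] <= 0)
    stop("solvent moles must be positive", call. = FALSE)
  if (is.null(binding)) {
    free <- comp$moles[roles != "protein"]
  } else {
    bound <- bound_moles(comp, binding)
    free <- comp$moles[names(bound)] - bound
    bad <- names(free)[free < 0 | (names(free) == solvent_id & free <= 0)]
    if (length(bad))
      stop(sprintf(
        "infeasible binding: bound moles exceed available moles for %s",
        paste(bad, collapse = ", ")), call. = FALSE)
  }
  salts <- intersect(names(comp$moles)[roles == "salt"], names(free))
  list(F = unname(free[solvent_id]),
       D = sum(comp$moles[roles == "protein"]) +
         sum(d[match(salts, names(comp$moles))] * free[salts]))
}

# Bound moles of each diffusible species given a composition and binding
# matrix; returns a named vector over the composition's diffusible species.
bound_moles <- function(comp, binding) {
  roles <- comp_roles(comp)
  diffusible <- names(comp$moles)[roles != "protein"]
  proteins <- names(comp$moles)[roles == "protein"]
  bound <- stats::setNames(numeric(length(diffusible)), diffusible)
  if (length(proteins) == 0L) return(bound)
  nu <- binding$nu
  for (i in intersect(diffusible, rownames(nu))) {
    pj <- intersect(proteins, colnames(nu))
    if (length(pj))
      bound[i] <- sum(nu[i, pj] * comp$moles[pj])
  }
  bound
}

#' Free-water mole fraction of a chamber
#'
#' The mole fraction of solvent after the hydrated-macromolecule accounting:
#' bound water and bound ions are removed from both numerator and
#' denominator, while each hydrated protein still counts as one mole of
#' complex:
#' `x1_free = free_1 / (free_1 + sum_j N_j + sum_k d_k * free_k)`
#' with `free_i = N_i - sum_j nu_ij * N_j`.
#'
#' With zero binding, or in a protein-free chamber, this equals
#' [total_water_mole_fraction()].
#'
#' @param comp an [fs_composition()].
#' @param binding an [fs_binding()]; bound moles must not exceed available
#'   moles for any species (free water must remain positive).
#' @return The free-solvent mole fraction, in (0, 1].
#' @export
free_water_mole_fraction <- function(comp, binding) {
  stopifnot(inherits(comp, "fs_composition"), inherits(binding, "fs_binding"))
  t <- chamber_terms(comp, binding)
  t$F / (t$F + t$D)
}

# Pressure from the F/D decompositions of the two chambers.  The ratio of
# mole fractions is 1 + (F_II D_I - F_I D_II) / (F_I (F_II + D_II)); the
# expanded numerator cancels the common F_II * F_I term analytically, so
# log1p keeps full relative precision even for nearly identical chambers
# (a naive log(x_II / x_I) loses digits exactly where the pressure is
# small).
pressure_from_terms <- function(t_II, t_I, cond) {
  stopifnot(inherits(cond, "fs_conditions"))
  delta <- (t_II$F * t_I$D - t_I$F * t_II$D) /
    (t_I$F * (t_II$F + t_II$D))
  -(cond$gas_constant * cond$temperature / cond$solvent_molar_volume) *
    log1p(delta)
}

#' Ideal-solution osmotic pressure
#'
#' `pi = -(R T / V1) * log(x1_II / x1_I)` with total-water mole fractions,
#' i.e. the activity coefficient taken as unity in both chambers.
#'
#' @param comp_II chamber-II [fs_composition()] (with protein).
#' @param comp_I chamber-I [fs_composition()] (protein-free).
#' @param cond an [fs_conditions()].
#' @return Osmotic pressure in Pa.
#' @export
osmotic_pressure_ideal <- function(comp_II, comp_I, cond) {
  pressure_from_terms(chamber_terms(comp_II), chamber_terms(comp_I), cond)
}

#' Free-solvent osmotic pressure
#'
#' `pi = -(R T / V1) * log(x1_free_II / x1_free_I)` with free-water mole
#' fractions.  With zero binding this reduces to [osmotic_pressure_ideal()].
#' An infeasible binding (hydration demand exceeding available water at this
#' concentration) raises an error: it marks the model's saturation boundary.
#'
#' @inheritParams osmotic_pressure_ideal
#' @param binding an [fs_binding()].
#' @return Osmotic pressure in Pa.
#' @export
osmotic_pressure_freesolvent <- function(comp_II, comp_I, binding, cond) {
  pressure_from_terms(chamber_terms(comp_II, binding),
                      chamber_terms(comp_I, binding), cond)
}

#' Closed-form free-solvent pressure for one protein and one monovalent salt
#'
#' The single-protein, single-monovalent-salt specialization of the general
#' free-water mole-fraction accounting, written out directly from the raw
#' mole numbers:
#' \deqn{\hat x_1^{II} = \frac{N_1 - \nu_{12} N_2}
#'   {(N_1 - \nu_{12} N_2) + N_2 + d\,(N_3 - \nu_{32} N_2)}, \qquad
#'   \hat x_1^{I} = \frac{N_1^I}{N_1^I + d\,N_3^I}}
#' and `pi = -(R T / V1) * log(xhat_II / xhat_I)`.  It is a tested
#' specialization of [osmotic_pressure_freesolvent()], not a separate user
#' path.
#'
#' @param N1_II,N2,N3_II chamber-II moles of water, protein, salt.
#' @param N1_I,N3_I chamber-I moles of water and salt.
#' @param nu_water,nu_salt mol water / mol protein and mol salt formula
#'   units / mol protein.
#' @param dissociation salt dissociation count (2 for a monovalent salt).
#' @param cond an [fs_conditions()].
#' @return Osmotic pressure in Pa.
#' @export
osmotic_pressure_closed_form <- function(N1_II, N2, N3_II, N1_I, N3_I,
                                         nu_water, nu_salt,
                                         dissociation = 2, cond) {
  free_w <- N1_II - nu_water * N2
  free_s <- N3_II - nu_salt * N2
  if (free_w <= 0 || free_s < 0)
    stop("infeasible binding: bound moles exceed available moles",
         call. = FALSE)
  pressure_from_terms(
    list(F = free_w, D = N2 + dissociation * free_s),
    list(F = N1_I, D = dissociation * N3_I), cond)
}

#' Convert pressures between units
#'
#' @param x numeric pressures.
#' @param from,to one of `"Pa"`, `"kPa"`, `"mmHg"`, `"atm"`.
#' @return `x` expressed in unit `to` (1 atm = 101325 Pa, 1 mmHg =
#'   133.322 Pa).
#' @examples
#' convert_pressure(760, "mmHg", "Pa")
#' @export
convert_pressure <- function(x, from = "Pa", to = "Pa") {
  to_pa <- c(Pa = 1, kPa = 1000, mmHg = 133.322, atm = 101325)
  if (!from %in% names(to_pa) || !to %in% names(to_pa))
    stop("pressure unit must be one of: ", paste(names(to_pa), collapse = ", "),
         call. = FALSE)
  x * to_pa[[from]] / to_pa[[to]]
}
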