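# Activity coefficient of free-solvent: forward prediction from the binding
# parameters, and back-calculation from osmotic-pressure data.
#
# The activity coefficient of free-solvent in the protein-free chamber I is
# taken as exactly unity (it is a reference solution of solvent plus fully
# dissociated diffusible ions); this is a structural assumption of the
# model, not a tunable parameter.

#' Predict the activity coefficient of free-solvent
#'
#' The closed-form prediction from the solution composition and binding
#' parameters alone:
#' `gamma_II = (xfree_II / xtotal_II) * (xtotal_I / xfree_I)`.
#' In the protein-free chamber I the free and total fractions coincide, so
#' the value reduces to `xfree_II / xtotal_II`.  With zero binding the
#' coefficient is exactly 1.  Values above 1 are returned, not clamped:
#' systems whose ion binding dominates their hydration at low concentration
#' genuinely sit marginally (< 1e-6) above unity before hydration takes
#' over, and pathological parameter combinations (tiny hydration, large ion
#' binding) can exceed 1 substantially -- excesses beyond 1e-6 trigger a
#' warning.
#'
#' @param comp_II chamber-II [fs_composition()].
#' @param comp_I chamber-I [fs_composition()].
#' @param binding an [fs_binding()].
#' @return The dimensionless activity coefficient of free-solvent in
#'   chamber II.
#' @export
predict_activity_coefficient <- function(comp_II, comp_I, binding) {
  g <- (free_water_mole_fraction(comp_II, binding) /
          total_water_mole_fraction(comp_II)) *
    (total_water_mole_fraction(comp_I) /
       free_water_mole_fraction(comp_I, binding))
  if (g > 1 + 1e-6)
    warning(sprintf(
      "activity coefficient %.6g exceeds 1: check binding parameters", g),
      call. = FALSE)
  g
}

#' Back-calculate the activity coefficient from an osmotic pressure
#'
#' Inverts the non-ideal pressure relation
#' `pi = -(R T / V1) * log(gamma_II * x1_II / x1_I)` (chamber-I coefficient
#' unity) for the chamber-II activity coefficient:
#' `gamma_II = (x1_I / x1_II) * exp(-pi * V1 / (R T))`.
#' This is the exact inverse of the forward relation, so feeding it a
#' model-generated pressure reproduces [predict_activity_coefficient()] to
#' machine precision.
#'
#' @param pressure observed osmotic pressure in Pa (finite).
#' @param comp_II,comp_I chamber [fs_composition()] objects.
#' @param cond an [fs_conditions()].
#' @return The dimensionless activity coefficient of free-solvent in
#'   chamber II.
#' @export
activity_coefficient_from_pressure <- function(pressure, comp_II, comp_I,
                                               cond) {
  stopifnot(is.finite(pressure), inherits(cond, "fs_conditions"))
  x_II <- total_water_mole_fraction(comp_II)
  x_I <- total_water_mole_fraction(comp_I)
  (x_I / x_II) * exp(-pressure * cond$solvent_molar_volume /
                       (cond$gas_constant * cond$temperature))
}

#' Activity-coefficient curve over concentrations
#'
#' Vectorizes the two single-point operations over a concentration grid
#' (`mode = "predicted"`, from the binding parameters) or over an osmometry
#' dataset (`mode = "calculated"`, from measured pressures).  Both modes
#' share the same composition bookkeeping.  Rows whose evaluation fails
#' (e.g. a concentration beyond the hydration-saturation boundary) get
#' `NA` with the error recorded in the `errors` attribute
#' (a data.frame of row indices and messages) and a single warning.
#'
#' @param sys an [fs_system()].
#' @param conc concentration grid in g/L (`mode = "predicted"`).
#' @param dataset a data.frame with columns `conc` (g/L) and `pressure`
#'   (Pa), e.g. from [generate_osmotic_dataset()] or
#'   [read_osmotic_dataset()] (`mode = "calculated"`).
#' @param mode `"predicted"` or `"calculated"`.
#' @return A data.frame with columns `conc`, `gamma`, `mode`; failed rows
#'   are `NA` and listed in `attr(, "errors")`.
#' @examples
#' sys <- fs_scenario("bsa_ph4.5")
#' activity_curve(sys, conc = seq(0, 400, by = 100))
#' @export
activity_curve <- function(sys, conc = NULL, dataset = NULL,
                           mode = c("predicted", "calculated")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sys, "fs_system"))
  if (mode == "predicted") {
    if (is.null(conc))
      stop("mode = 'predicted' needs a concentration grid", call. = FALSE)
    cc <- as.numeric(conc)
    pp <- rep(NA_real_, length(cc))
  } else {
    if (is.null(dataset))
      stop("mode = 'calculated' needs a dataset", call. = FALSE)
    stopifnot(all(c("conc", "pressure") %in% names(dataset)))
    cc <- as.numeric(dataset$conc)
    pp <- as.numeric(dataset$pressure)
  }
  binding <- system_binding(sys)
  gamma <- rep(NA_real_, length(cc))
  errors <- list()
  for (i in seq_along(cc)) {
    res <- tryCatch({
      ch <- system_chambers(sys, cc[i])
      if (mode == "predicted")
        predict_activity_coefficient(ch$II, ch$I, binding)
      else
        activity_coefficient_from_pressure(pp[i], ch$II, ch$I,
                                           sys$conditions)
    }, error = function(e) e)
    if (inherits(res, "error"))
      errors[[length(errors) + 1L]] <- data.frame(row = i,
                                                  message = conditionMessage(res))
    else gamma[i] <- res
  }
  out <- data.frame(conc = cc, gamma = gamma,
                    mode = rep(mode, length.out = length(cc)))
  if (length(errors)) {
    err <- do.call(rbind, errors)
    attr(out, "errors") <- err
    warning(sprintf("%d of %d rows failed; see attr(, 'errors')",
                    nrow(err), length(cc)), call. = FALSE)
  }
  out
}
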