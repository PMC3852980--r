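# Regression of hydration and ion-binding parameters from osmotic-pressure
# datasets by bounded nonlinear least squares.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit hydration and ion-binding parameters to osmometry data
#'
#' Minimizes the sum of squared pressure residuals
#' `sum_i (pi_model(conc_i; nu) - pi_obs_i)^2` over the selected free
#' parameters with box constraints, using finite-difference L-BFGS-B.
#' Compositions where the binding is infeasible (hydration demand exceeding
#' available water) are handled by a large finite penalty that grows with
#' the parameters, so the optimizer never evaluates an invalid model and is
#' pushed back into the feasible box.  The fit is deterministic given the
#' starting values.
#'
#' @param dataset a data.frame with columns `conc` (g/L) and `pressure`
#'   (Pa), with at least two distinct concentrations; typically from
#'   [read_osmotic_dataset()] or [generate_osmotic_dataset()].
#' @param sys an [fs_system()] supplying species, chamber-I salt and
#'   conditions.  Its binding parameters serve as fixed values for
#'   parameters not being fitted, and as default starting values (when the
#'   system was built from a SASA these are the monolayer values).
#' @param free which parameters to fit: subset of
#'   `c("hydration", "ion_binding")`.
#' @param init optional named starting values for the free parameters;
#'   defaults to the system's configured values, or the box midpoint if the
#'   configured value is not finite.
#' @param lower,upper named box constraints; defaults: hydration in
#'   \[0, 12000\] mol/mol, ion binding in \[0, 50\] mol/mol.
#' @param weighting `"absolute"` (default) for raw pressure residuals or
#'   `"relative"` for residuals divided by the observed pressure (rows with
#'   zero observed pressure then use the absolute residual).
#' @return An object of class `fs_fit`: `estimates` (mol/mol, hydration
#'   also in g/g), `residuals` (Pa), `rmse` (Pa), `std_errors` (from the
#'   finite-difference Jacobian at the optimum), `converged`, `n_evals`,
#'   `message`.
#' @examples
#' sys <- fs_scenario("bsa_ph4.5")
#' d <- generate_osmotic_dataset(sys, conc = seq(25, 450, length.out = 12))
#' fit_binding_parameters(d, sys, init = c(hydration = 3000, ion_binding = 5))
#' @export
fit_binding_parameters <- function(dataset, sys,
                                   free = c("hydration", "ion_binding"),
                                   init = NULL, lower = NULL, upper = NULL,
                                   weighting = c("absolute", "relative")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(sys, "fs_system"),
            all(c("conc", "pressure") %in% names(dataset)))
  free <- match.arg(free, c("hydration", "ion_binding"), several.ok = TRUE)
  if (any(dataset$conc < 0) || any(!is.finite(dataset$pressure)))
    stop("dataset must have non-negative conc and finite pressure",
         call. = FALSE)
  if (length(unique(dataset$conc)) < 2L)
    stop("fitting needs at least two distinct concentrations", call. = FALSE)
  if (nrow(dataset) < length(free))
    stop("fewer rows than free parameters: under-determined fit",
         call. = FALSE)

  box_lower <- c(hydration = 0, ion_binding = 0)
  box_upper <- c(hydration = 12000, ion_binding = 50)
  if (!is.null(lower)) box_lower[names(lower)] <- lower
  if (!is.null(upper)) box_upper[names(upper)] <- upper
  start <- c(hydration = sys$hydration, ion_binding = sys$ion_binding)
  mid <- (box_lower + box_upper) / 2
  start[!is.finite(start)] <- mid[!is.finite(start)]
  if (!is.null(init)) start[names(init)] <- init
  start <- pmin(pmax(start, box_lower), box_upper)
  if (any(start[free] < box_lower[free] | start[free] > box_upper[free]))
    stop("starting values outside bounds", call. = FALSE)

  obs <- dataset$pressure
  w <- if (weighting == "relative") ifelse(obs != 0, abs(obs), 1) else
    rep(1, length(obs))
  n_evals <- 0L

  model_pressure <- function(theta) {
    s <- system_with_binding(sys,
                             hydration = theta[["hydration"]],
                             ion_binding = theta[["ion_binding"]])
    predict_osmotic_pressure(s, dataset$conc)$pressure
  }
  objective <- function(par) {
    n_evals <<- n_evals + 1L
    theta <- start
    theta[free] <- par
    pred <- tryCatch(model_pressure(theta), error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred)))
      return(1e16 * (1 + sum(theta[free] / box_upper[free])))
    sum(((pred - obs) / w)^2)
  }

  opt <- stats::optim(start[free], objective, method = "L-BFGS-B",
                      lower = box_lower[free], upper = box_upper[free],
                      control = list(maxit = 500, factr = 1e7))
  converged <- opt$convergence == 0L
  # a start at (or numerically on top of) the optimum makes the L-BFGS-B
  # line search abort; certify the point as a local minimum by probing
  # small relative perturbations of every free parameter
  if (!converged && grepl("LNSRCH", opt$message %||% "")) {
    f0 <- opt$value
    improves <- FALSE
    for (k in seq_along(free)) for (s in c(-1, 1)) {
      par <- opt$par
      par[k] <- min(max(par[k] * (1 + s * 1e-4) + s * 1e-8,
                        box_lower[free][k]), box_upper[free][k])
      if (objective(par) < f0 * (1 - 1e-10)) improves <- TRUE
    }
    if (!improves) {
      converged <- TRUE
      opt$message <- "line search stalled at a certified local minimum"
    }
  }
  theta <- start
  theta[free] <- opt$par

  pred <- tryCatch(model_pressure(theta), error = function(e) rep(NA_real_,
                                                                  length(obs)))
  resid <- pred - obs
  rmse <- sqrt(mean(resid^2))
  se <- fit_std_errors(model_pressure, theta, free, obs, w)

  structure(
    list(estimates = c(theta[free],
                       if ("hydration" %in% free)
                         c(hydration_g_per_g =
                             hydration_mol_per_mol_to_g_per_g(
                               theta[["hydration"]],
                               sys$protein$molar_mass,
                               sys$water$molar_mass))),
         fixed = theta[setdiff(names(theta), free)],
         residuals = resid, rmse = rmse, std_errors = se,
         converged = converged,
         n_evals = n_evals, message = opt$message,
         lower = box_lower[free], upper = box_upper[free],
         weighting = weighting),
    class = "fs_fit"
  )
}

# Gauss-Newton standard errors from a central-difference Jacobian of the
# weighted residuals at the optimum; NA if the normal matrix is singular.
fit_std_errors <- function(model_pressure, theta, free, obs, w) {
  p <- length(free)
  n <- length(obs)
  if (n <= p) return(stats::setNames(rep(NA_real_, p), free))
  J <- matrix(NA_real_, n, p, dimnames = list(NULL, free))
  for (k in free) {
    h <- max(1e-6 * abs(theta[[k]]), 1e-8)
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- max(dn[k] - h, 0)
    pu <- tryCatch(model_pressure(up), error = function(e) NULL)
    pd <- tryCatch(model_pressure(dn), error = function(e) NULL)
    if (is.null(pu) || is.null(pd)) return(stats::setNames(rep(NA_real_, p),
                                                           free))
    J[, k] <- (pu - pd) / ((up[k] - dn[k]) * w)
  }
  r <- tryCatch(model_pressure(theta), error = function(e) NULL)
  if (is.null(r)) return(stats::setNames(rep(NA_real_, p), free))
  sigma2 <- sum(((r - obs) / w)^2) / (n - p)
  cov <- tryCatch(solve(crossprod(J)) * sigma2, error = function(e) NULL)
  if (is.null(cov)) return(stats::setNames(rep(NA_real_, p), free))
  stats::setNames(sqrt(pmax(diag(cov), 0)), free)
}

#' @export
print.fs_fit <- function(x, ...) {
  cat("<fs_fit> bounded nonlinear least squares\n")
  est <- x$estimates
  for (nm in names(est)) {
    se <- x$std_errors[nm]
    cat(sprintf("  %-20s %.6g%s\n", nm, est[[nm]],
                if (!is.na(se)) sprintf("  (se %.3g)", se) else ""))
  }
  cat(sprintf("  rmse %.6g Pa, converged: %s, %d evaluations\n",
              x$rmse, x$converged, x$n_evals))
  invisible(x)
}
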