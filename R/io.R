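# Dataset and configuration I/O.  Datasets are plain CSV (comma-separated,
# UTF-8, header required, '.' decimal); configs are YAML with JSON accepted.
# Internally everything is Pa / K / mol.

#' Read an osmotic-pressure dataset from CSV
#'
#' Expected columns: `conc_g_per_L` and `pressure`, plus either a
#' `pressure_unit` column or the `pressure_unit` argument (default `"Pa"`).
#' Pressures are normalized to Pa.  A header-only file yields an empty
#' dataset with a warning.
#'
#' @param path CSV file path.
#' @param pressure_unit unit of the `pressure` column when the file has no
#'   `pressure_unit` column: `"Pa"`, `"kPa"`, `"mmHg"` or `"atm"`.
#' @return A data.frame with columns `conc` (g/L) and `pressure` (Pa).
#' @export
read_osmotic_dataset <- function(path, pressure_unit = "Pa") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("conc_g_per_L", "pressure")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) {
    warning("dataset has a header but no rows", call. = FALSE)
    return(data.frame(conc = numeric(0), pressure = numeric(0)))
  }
  units <- if ("pressure_unit" %in% names(df)) df$pressure_unit else
    rep(pressure_unit, nrow(df))
  bad <- which(!is.finite(df$conc_g_per_L) | df$conc_g_per_L < 0)
  if (length(bad))
    stop("negative or non-numeric conc_g_per_L at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$pressure))
  if (length(bad))
    stop("non-numeric pressure at row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pressure <- vapply(seq_len(nrow(df)), function(i)
    convert_pressure(df$pressure[i], from = units[i], to = "Pa"),
    numeric(1))
  data.frame(conc = df$conc_g_per_L, pressure = pressure)
}

#' Write an osmotic-pressure dataset to CSV
#'
#' @param dataset a data.frame with columns `conc` (g/L) and `pressure`
#'   (Pa).
#' @param path output CSV path.
#' @param pressure_unit unit to write the pressures in.
#' @return `path`, invisibly.
#' @export
write_osmotic_dataset <- function(dataset, path, pressure_unit = "Pa") {
  stopifnot(all(c("conc", "pressure") %in% names(dataset)))
  out <- data.frame(
    conc_g_per_L = dataset$conc,
    pressure = convert_pressure(dataset$pressure, "Pa", pressure_unit),
    pressure_unit = rep(pressure_unit, nrow(dataset)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_schema <- list(
  top = c("species", "conditions", "binding", "prep"),
  species = c("id", "role", "molar_mass", "dissociation_count"),
  conditions = c("temperature_K", "V1_m3_per_mol", "gas_constant"),
  binding = c("hydration_mol_per_mol", "hydration_g_per_g", "sasa_A2",
              "coverage_per_nm2", "ion_binding_mol_per_mol"),
  prep = c("salt_M", "basis_L", "partial_specific_volume_mL_per_g",
           "water_density_g_per_mL", "conc_max_g_per_L")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s: %s (allowed: %s)", where,
                 paste(extra, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
}

#' Read a run configuration into a system
#'
#' Parses a YAML (or JSON) configuration describing species, conditions,
#' binding parameters and the solution prep, and assembles an
#' [fs_system()].  Unknown keys are rejected with a message listing the
#' allowed ones.  The binding block accepts exactly one of
#' `hydration_mol_per_mol`, `hydration_g_per_g` or `sasa_A2` (the latter
#' with optional `coverage_per_nm2`), plus `ion_binding_mol_per_mol`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An [fs_system()].
#' @examples
#' cfg <- system.file("extdata", "bsa_ph4.5.yaml", package = "freesolvent")
#' read_run_config(cfg)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  check_keys(cfg, config_schema$top, "config")
  for (blk in c("species", "conditions", "binding"))
    if (is.null(cfg[[blk]]))
      stop("config is missing the '", blk, "' block", call. = FALSE)

  species <- lapply(cfg$species, function(s) {
    check_keys(s, config_schema$species, "species entry")
    fs_species(s$id, s$role, s$molar_mass,
               if (is.null(s$dissociation_count)) 1L else s$dissociation_count)
  })
  roles <- vapply(species, `[[`, character(1), "role")
  if (sum(roles == "solvent") != 1L)
    stop("config must define exactly one solvent species", call. = FALSE)
  if (sum(roles == "protein") != 1L)
    stop("config must define exactly one protein species", call. = FALSE)
  if (sum(roles == "salt") > 1L)
    stop("config supports at most one salt species", call. = FALSE)
  water <- species[[which(roles == "solvent")]]
  protein <- species[[which(roles == "protein")]]
  salt <- if (any(roles == "salt")) species[[which(roles == "salt")]] else NULL

  cnd <- cfg$conditions
  check_keys(cnd, config_schema$conditions, "conditions")
  if (is.null(cnd$temperature_K))
    stop("conditions.temperature_K is required", call. = FALSE)
  cond_args <- list(temperature = cnd$temperature_K)
  if (!is.null(cnd$V1_m3_per_mol))
    cond_args$solvent_molar_volume <- cnd$V1_m3_per_mol
  if (!is.null(cnd$gas_constant)) cond_args$gas_constant <- cnd$gas_constant
  conditions <- do.call(fs_conditions, cond_args)

  b <- cfg$binding
  check_keys(b, config_schema$binding, "binding")
  prep <- if (is.null(cfg$prep)) list() else cfg$prep
  check_keys(prep, config_schema$prep, "prep")

  args <- list(
    protein = protein, salt = salt,
    salt_molarity = if (is.null(prep$salt_M)) 0 else prep$salt_M,
    conditions = conditions, water = water,
    hydration = b$hydration_mol_per_mol,
    hydration_g_per_g = b$hydration_g_per_g,
    sasa = b$sasa_A2,
    ion_binding = if (is.null(b$ion_binding_mol_per_mol)) 0 else
      b$ion_binding_mol_per_mol)
  if (!is.null(b$coverage_per_nm2)) args$coverage <- b$coverage_per_nm2
  if (!is.null(prep$basis_L)) args$basis_volume <- prep$basis_L
  if (!is.null(prep$partial_specific_volume_mL_per_g))
    args$partial_specific_volume <- prep$partial_specific_volume_mL_per_g
  if (!is.null(prep$water_density_g_per_mL))
    args$water_density <- prep$water_density_g_per_mL
  if (!is.null(prep$conc_max_g_per_L)) args$conc_max <- prep$conc_max_g_per_L
  do.call(fs_system, args)
}

#' Parse a concentration grid specification
#'
#' Accepts `"from:to:by"` (e.g. `"0:475:25"`) or a comma-separated list of
#' values (e.g. `"0,100,250,400"`), as used by the command-line interface.
#'
#' @param spec character grid specification.
#' @return Numeric vector of concentrations in g/L.
#' @export
parse_conc_grid <- function(spec) {
  if (grepl(":", spec, fixed = TRUE)) {
    parts <- suppressWarnings(
      as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 3L || any(!is.finite(parts)) || parts[3] <= 0)
      stop("grid must be from:to:by with positive step", call. = FALSE)
    return(seq(parts[1], parts[2], by = parts[3]))
  }
  vals <- suppressWarnings(
    as.numeric(strsplit(spec, ",", fixed = TRUE)[[1]]))
  if (any(!is.finite(vals)))
    stop("grid values must be numeric", call. = FALSE)
  vals
}
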