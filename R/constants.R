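#' Model constants
#'
#' All numeric constants of the footprint model (global-warming potentials,
#' nitrogen-cycle fractions, the soil N2O response coefficients, intake and
#' methane sub-model coefficients, farm-management quantities and herd
#' parameters) are stored in a single YAML file shipped with the package.
#' `model_constants()` reads that file and applies any overrides, so a run
#' can be reproduced from its manifest alone.
#'
#' @param overrides Optional named list (possibly nested) replacing selected
#'   entries, e.g. `list(nitrogen = list(frac_leach = 0.3))`. Names that do
#'   not exist in the constants file are rejected.
#' @param file Path to a YAML constants file; defaults to the file shipped
#'   in `inst/extdata`.
#' @return A nested list of constants with class `"pasture_constants"`.
#' @examples
#' cst <- model_constants()
#' cst$gwp$n2o
#' model_constants(list(nitrogen = list(frac_leach = 0.30)))$nitrogen$frac_leach
#' @export
model_constants <- function(overrides = NULL, file = NULL) {
  file <- file %||% system.file("extdata", "constants.yaml",
                                package = "pastureLCA", mustWork = TRUE)
  if (!file.exists(file)) {
    stop("constants file not found: ", file, call. = FALSE)
  }
  cst <- yaml::read_yaml(file)
  if (!is.null(overrides)) {
    check_override_names(cst, overrides)
    cst <- merge_constants(cst, overrides)
  }
  validate_constants(cst)
  structure(cst, class = "pasture_constants")
}

check_override_names <- function(base, over, path = character()) {
  for (nm in names(over)) {
    here <- c(path, nm)
    if (!nm %in% names(base)) {
      stop("unknown constant override: ", paste(here, collapse = "$"),
           call. = FALSE)
    }
    if (is.list(over[[nm]])) {
      check_override_names(base[[nm]], over[[nm]], here)
    }
  }
  invisible(TRUE)
}

validate_constants <- function(cst) {
  ni <- cst$nitrogen
  assert_fraction(ni$grazing_proportion, "grazing_proportion")
  assert_fraction(ni$excreta_deposition, "excreta_deposition")
  assert_fraction(ni$tan_fraction, "tan_fraction")
  assert_fraction(ni$tan_ef_grazing, "tan_ef_grazing")
  assert_fraction(ni$frac_leach, "frac_leach")
  assert_fraction(ni$ef_volatilization, "ef_volatilization")
  assert_fraction(ni$ef_leaching, "ef_leaching")
  assert_fraction(ni$excretion_fraction, "excretion_fraction")
  if (!ni$leach_basis %in% c("applied", "surplus")) {
    stop("leach_basis must be 'applied' or 'surplus'", call. = FALSE)
  }
  assert_number(cst$gwp$n2o, "gwp$n2o", lower = 0)
  assert_number(cst$gwp$ch4, "gwp$ch4", lower = 0)
  assert_number(ni$milk_n_divisor, "milk_n_divisor", lower = 1)
  assert_number(ni$cp_factor, "cp_factor", lower = 1)
  assert_number(ni$meat_n_export, "meat_n_export", lower = 0)
  for (nm in c("intercept", "scale", "rate")) {
    assert_number(cst$n2o_response[[nm]], paste0("n2o_response$", nm), lower = 0)
  }
  so <- cst$soc
  for (nm in names(so)) assert_fraction(so[[nm]], paste0("soc$", nm))
  hd <- cst$herd
  for (nm in names(hd)) assert_number(hd[[nm]], paste0("herd$", nm), lower = 1e-9)
  if (hd$milk_fat_pct >= 100 || hd$milk_protein_pct >= 100) {
    stop("milk composition percentages must be below 100", call. = FALSE)
  }
  if (hd$replacement_rate >= 1) {
    stop("replacement_rate must be a fraction below 1", call. = FALSE)
  }
  invisible(cst)
}

#' Herd parameters
#'
#' Convenience accessor for the herd block of [model_constants()]: milk fat
#' and protein content, live weight, stocking rate, herd size, farm area and
#' replacement rate.
#'
#' @inheritParams model_constants
#' @return Named list of herd parameters.
#' @export
herd_parameters <- function(overrides = NULL, file = NULL) {
  model_constants(overrides, file)$herd
}

#' Emission-factor table for external resources and farm operations
#'
#' Reads the per-activity emission factors (seed production, mineral N
#' fertilizer, field operations, irrigation water provision, milking, shed
#' operation and slurry storage) shipped as a plain CSV.
#'
#' @param file Optional path to an alternative CSV with columns
#'   `activity`, `factor`, `unit`.
#' @return A data.frame with one row per activity and class
#'   `"emission_factor_table"`.
#' @examples
#' ef <- emission_factors()
#' ef_lookup(ef, "irrigation")
#' @export
emission_factors <- function(file = NULL) {
  file <- file %||% system.file("extdata", "emission_factors.csv",
                                package = "pastureLCA", mustWork = TRUE)
  ef <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("activity", "factor", "unit")
  if (!all(required %in% names(ef))) {
    stop("emission-factor table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ef$activity)) {
    stop("duplicate activity in emission-factor table", call. = FALSE)
  }
  if (any(!is.finite(ef$factor)) || any(ef$factor <= 0)) {
    stop("all emission factors must be positive", call. = FALSE)
  }
  structure(ef, class = c("emission_factor_table", "data.frame"))
}

#' Look up one emission factor
#'
#' @param ef An [emission_factors()] table.
#' @param activity Activity label, e.g. `"fertilizer_n"`.
#' @return The factor value (numeric scalar).
#' @export
ef_lookup <- function(ef, activity) {
  i <- match(activity, ef$activity)
  if (is.na(i)) {
    stop("no emission factor for activity '", activity, "'", call. = FALSE)
  }
  ef$factor[i]
}
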