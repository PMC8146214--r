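#' Model-closure calibrations
#'
#' Four scalar parameters of the pipeline are not measurable at desk scale
#' and are instead solved, once each, from anchors of the base
#' (unfertilized) treatment in a published per-treatment summary; all other
#' treatments are then out-of-sample:
#'
#' * `utilization` - herbage-energy-to-milk closure, solved so the base
#'   treatment's mean potential milk yield equals its reference value;
#' * `supplement_n` - N imported in purchased feed per hectare, solved so
#'   the base treatment's farm-N-balance equals its reference value;
#' * `soc_retention` - SOC retention coefficient, solved so the base
#'   treatment's annual C sequestration equals its reference value;
#' * `methane_scale` - multiplier on the enteric methane yields, solved so
#'   enteric methane is the reference share of the base treatment's gross
#'   GWP.
#'
#' @param scenarios Named list of [treatment_scenario()] objects.
#' @param reference A [reference_summary()] data.frame (or one with the same
#'   columns for synthetic data).
#' @param constants A [model_constants()] list.
#' @param ef An [emission_factors()] table.
#' @return A list of class `"pasture_calibration"` with the four parameters
#'   plus `nel` (MJ/kg ECM) and the id of the anchor treatment.
#' @examples
#' cal <- calibrate_model(load_reference_scenarios(), reference_summary())
#' round(cal$utilization, 3)
#' @export
calibrate_model <- function(scenarios, reference = reference_summary(),
                            constants = model_constants(),
                            ef = emission_factors()) {
  base_id <- base_treatment_id(scenarios)
  cal <- list(
    nel = nel_per_kg_ecm(constants$herd$milk_fat_pct,
                         constants$herd$milk_protein_pct),
    base_treatment = base_id,
    utilization = calibrate_utilization(scenarios, reference, constants),
    supplement_n = calibrate_supplement_n(reference, constants),
    soc_retention = calibrate_soc_retention(scenarios, reference, constants),
    methane_scale = 1
  )
  class(cal) <- "pasture_calibration"
  cal$methane_scale <- calibrate_methane_scale(scenarios, reference,
                                               constants, ef, cal)
  cal
}

base_treatment_id <- function(scenarios) {
  rates <- vapply(scenarios, function(s) s$n_fertilizer_rate, numeric(1))
  names(scenarios)[which.min(rates)]
}

reference_row <- function(reference, id) {
  i <- match(id, reference$treatment)
  if (is.na(i)) stop("treatment '", id, "' not in reference summary",
                     call. = FALSE)
  reference[i, ]
}

#' @rdname calibrate_model
#' @export
calibrate_utilization <- function(scenarios, reference,
                                  constants = model_constants()) {
  id <- base_treatment_id(scenarios)
  ref <- reference_row(reference, id)
  energy <- average_over_years(scenarios[[id]], "energy_yield")
  nel <- nel_per_kg_ecm(constants$herd$milk_fat_pct,
                        constants$herd$milk_protein_pct)
  u <- ref$milk_yield * nel / energy
  if (u <= 0 || u > 1) {
    stop(sprintf("calibrated utilization %.3f outside (0, 1]", u),
         call. = FALSE)
  }
  u
}

#' @rdname calibrate_model
#' @export
calibrate_supplement_n <- function(reference, constants = model_constants()) {
  ref <- reference[which.min(reference$n_rate), ]
  milk_n <- milk_n_export(ref$milk_yield, constants$herd$milk_protein_pct,
                          constants$nitrogen$milk_n_divisor)
  s <- ref$farm_n_balance + milk_n + constants$nitrogen$meat_n_export -
    ref$n_rate
  if (s < 0) stop("calibrated supplement N is negative", call. = FALSE)
  s
}

#' @rdname calibrate_model
#' @export
calibrate_soc_retention <- function(scenarios, reference,
                                    constants = model_constants()) {
  id <- base_treatment_id(scenarios)
  ref <- reference_row(reference, id)
  if (is.null(ref$soc_sequestration) || is.na(ref$soc_sequestration)) {
    return(constants$soc$retention_coefficient)
  }
  dm <- average_over_years(scenarios[[id]], "dm_yield")
  so <- constants$soc
  ret <- ref$soc_sequestration / (dm * so$herbage_c_content *
                                  so$root_c_fraction)
  assert_fraction(ret, "calibrated soc retention")
  ret
}

#' @rdname calibrate_model
#' @export
calibrate_methane_scale <- function(scenarios, reference, constants, ef, cal) {
  id <- cal$base_treatment
  ref <- reference_row(reference, id)
  if (is.null(ref$ch4_share_pct) || is.na(ref$ch4_share_pct)) return(1)
  share <- ref$ch4_share_pct / 100
  assert_fraction(share, "methane share")
  # mean inventory of the base treatment at unit scale; all non-methane
  # items are independent of the scale, so the solution is closed-form
  yearly <- pipeline_treatment(scenarios[[id]], constants, ef, cal)
  ch4_unit <- mean(yearly$enteric_ch4_co2eq)
  other <- mean(yearly$gwp_gross) - ch4_unit
  scale <- share / (1 - share) * other / ch4_unit
  assert_number(scale, "methane_scale", lower = 1e-6)
  scale
}
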