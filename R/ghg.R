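#' Direct soil N2O emission from the field nitrogen balance
#'
#' Exponential response of annual soil N2O emission to the field-N-balance:
#' `intercept + scale * exp(rate * x)`. Strictly increasing and convex, with
#' a background floor at `intercept` for strongly negative balances.
#'
#' @param field_balance Field-N-balance, kg N/ha (vectorized; may be
#'   negative).
#' @param constants A [model_constants()] list; the response coefficients
#'   are read from its `n2o_response` block.
#' @return Direct N2O emission, kg N2O/ha/yr.
#' @examples
#' n2o_direct(0)    # intercept + scale
#' n2o_direct(706)
#' @export
n2o_direct <- function(field_balance, constants = model_constants()) {
  if (!is.numeric(field_balance) || any(!is.finite(field_balance))) {
    stop("`field_balance` must be finite numeric", call. = FALSE)
  }
  rs <- constants$n2o_response
  rs$intercept + rs$scale * exp(rs$rate * field_balance)
}

#' Indirect N2O from volatilized and leached nitrogen
#'
#' Emission factors applied to NH3-N and leached N give indirect N2O-N,
#' converted to N2O mass by the 44/28 stoichiometric ratio.
#'
#' @param nh3_n NH3-N volatilized, kg N/ha (vectorized).
#' @param leached N leached, kg N/ha.
#' @param ef_volat N2O-N per kg NH3-N redeposited.
#' @param ef_leach N2O-N per kg N leached.
#' @return Indirect N2O emission, kg N2O/ha/yr.
#' @export
n2o_indirect <- function(nh3_n, leached, ef_volat = 0.01, ef_leach = 0.011) {
  assert_number(nh3_n, "nh3_n", lower = 0, allow_vector = TRUE)
  assert_number(leached, "leached", lower = 0, allow_vector = TRUE)
  assert_number(ef_volat, "ef_volat", lower = 0, upper = 0.1)
  assert_number(ef_leach, "ef_leach", lower = 0, upper = 0.1)
  (nh3_n * ef_volat + leached * ef_leach) * 44 / 28
}

#' Enteric methane per hectare
#'
#' Feed-specific methane yields (g CH4 per kg DM, separate values for grazed
#' herbage and concentrate) applied to the daily intake profile, scaled to a
#' year and to the hectare through the stocking rate. `scale` is the single
#' calibration factor solved from the methane share of the base treatment
#' (see [calibrate_methane_scale()]).
#'
#' @param intake An `intake_profile` from [estimate_dm_intake()].
#' @param stocking_rate Stocking rate, LU/ha.
#' @param constants A [model_constants()] list (methane yields).
#' @param scale Calibration multiplier on both methane yields.
#' @return Enteric CH4, kg CH4/ha/yr. Errors if the implied per-cow
#'   emission leaves the plausibility band in the constants.
#' @export
enteric_ch4 <- function(intake, stocking_rate, constants = model_constants(),
                        scale = 1) {
  stopifnot(inherits(intake, "intake_profile"))
  assert_number(stocking_rate, "stocking_rate", lower = 0)
  assert_number(scale, "scale", lower = 0)
  me <- constants$methane
  g_day <- scale * (intake$dm_intake_pasture * me$yield_herbage +
                    intake$dm_intake_supplement * me$yield_concentrate)
  percow_yr <- g_day * 365 / 1000  # kg CH4/cow/yr
  if (intake$dm_intake_total > 0 && percow_yr > 0 &&
      (percow_yr < me$percow_min || percow_yr > me$percow_max)) {
    stop(sprintf("per-cow enteric CH4 %.0f kg/yr outside [%g, %g]",
                 percow_yr, me$percow_min, me$percow_max), call. = FALSE)
  }
  percow_yr * stocking_rate
}

#' Embodied emissions of purchased inputs and field operations
#'
#' Mineral fertilizer production, annualized pasture renovation (tillage,
#' sowing and seed at the renovation interval) and the yearly operations
#' (fertilizer spreading per dressing applied, mulching).
#'
#' @param n_rate Fertilizer rate, kg N/ha/yr.
#' @param ef An [emission_factors()] table.
#' @param constants A [model_constants()] list (seed rate, renovation
#'   interval, dressings per year).
#' @return Named list with `fertilizer_embodied`, `seeds_and_renovation`
#'   and `field_operations`, all kg CO2eq/ha/yr.
#' @export
embodied_inputs <- function(n_rate, ef = emission_factors(),
                            constants = model_constants()) {
  assert_number(n_rate, "n_rate", lower = 0)
  fa <- constants$farm
  fertilizer <- n_rate * ef_lookup(ef, "fertilizer_n")
  renovation <- (ef_lookup(ef, "tillage") + ef_lookup(ef, "sowing") +
                 fa$seed_rate * ef_lookup(ef, "grass_seeds")) /
    fa$renovation_interval
  dressings <- if (n_rate > 0) fa$dressings_per_year else 0
  operations <- dressings * ef_lookup(ef, "fertilizing_broadcast") +
    ef_lookup(ef, "mulching")
  list(fertilizer_embodied = fertilizer,
       seeds_and_renovation = renovation,
       field_operations = operations)
}

#' Irrigation energy emissions
#'
#' @param volume Irrigation water applied, m3/ha/yr.
#' @param ef An [emission_factors()] table.
#' @return kg CO2eq/ha/yr.
#' @examples
#' irrigation_emissions(4200)  # 1806
#' @export
irrigation_emissions <- function(volume, ef = emission_factors()) {
  assert_number(volume, "volume", lower = 0)
  volume * ef_lookup(ef, "irrigation")
}

#' Milking, shed and manure-storage emissions
#'
#' Milking energy scales with the milk mass; shed operation with the
#' stocking rate and the housed share of the year (one minus the grazing
#' proportion); manure storage combines the slurry-store factor applied to
#' the slurry volume collected during housed time with a per-LU factor for
#' the stored manure itself.
#'
#' @param milk_yield Milk yield, t ECM/ha/yr.
#' @param stocking_rate Stocking rate, LU/ha.
#' @param ef An [emission_factors()] table.
#' @param constants A [model_constants()] list.
#' @return Named list with `milking_shed` and `manure_storage`,
#'   kg CO2eq/ha/yr.
#' @export
management_emissions <- function(milk_yield, stocking_rate,
                                 ef = emission_factors(),
                                 constants = model_constants()) {
  assert_number(milk_yield, "milk_yield", lower = 0)
  assert_number(stocking_rate, "stocking_rate", lower = 0)
  housed <- 1 - constants$nitrogen$grazing_proportion
  milking <- milk_yield * 1000 * ef_lookup(ef, "milking")
  shed <- stocking_rate * ef_lookup(ef, "shed_operation") * housed
  slurry_m3 <- stocking_rate * 365 * housed * constants$farm$slurry_per_lu_day
  storage <- slurry_m3 * ef_lookup(ef, "slurry_store") +
    stocking_rate * constants$farm$manure_storage_per_lu
  list(milking_shed = milking + shed, manure_storage = storage)
}

#' Soil organic carbon change and its CO2 offset
#'
#' Below-ground carbon input is a fixed fraction of the above-ground biomass
#' carbon; a retention coefficient gives the share persisting as soil
#' organic carbon. The CO2-equivalent offset is the sequestration times
#' -44/12.
#'
#' @param dm_yield Above-ground dry-matter yield, t DM/ha (vectorized).
#' @param constants A [model_constants()] list (`soc` block).
#' @param retention Optional override of the retention coefficient (used by
#'   the calibration).
#' @return List with `sequestration` (t C/ha/yr, positive) and `offset`
#'   (t CO2eq/ha/yr, negative).
#' @export
soc_change <- function(dm_yield, constants = model_constants(),
                       retention = NULL) {
  assert_number(dm_yield, "dm_yield", lower = 0, allow_vector = TRUE)
  so <- constants$soc
  retention <- retention %||% so$retention_coefficient
  assert_fraction(retention, "retention")
  c_input <- dm_yield * so$herbage_c_content * so$root_c_fraction
  seq <- c_input * retention
  list(sequestration = seq, offset = -seq * 44 / 12)
}

#' Aggregate an emission inventory to GWP
#'
#' Converts per-gas masses to CO2 equivalents with the 100-year GWP factors
#' and sums them. The soil-carbon item enters `gwp_net` only.
#'
#' @param items data.frame with columns `item`, `gas` (one of `"co2"`,
#'   `"ch4"`, `"n2o"`, `"co2_soc"`) and `mass` (kg of that gas per ha;
#'   `co2_soc` mass is the signed CO2 offset).
#' @param constants A [model_constants()] list (GWP factors).
#' @return List with `gwp_gross` and `gwp_net` (kg CO2eq/ha) and the items
#'   table with a `co2eq` column added.
#' @examples
#' aggregate_gwp(data.frame(item = c("a", "b"), gas = c("n2o", "ch4"),
#'                          mass = c(1, 1)))$gwp_gross  # 293
#' @export
aggregate_gwp <- function(items, constants = model_constants()) {
  if (nrow(items) == 0L) {
    return(list(gwp_gross = 0, gwp_net = 0, items = items))
  }
  stopifnot(all(c("item", "gas", "mass") %in% names(items)))
  bad <- setdiff(items$gas, c("co2", "ch4", "n2o", "co2_soc"))
  if (length(bad)) stop("unknown gas: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  gwp <- c(co2 = 1, ch4 = constants$gwp$ch4, n2o = constants$gwp$n2o,
           co2_soc = 1)
  items$co2eq <- items$mass * gwp[items$gas]
  soc <- items$gas == "co2_soc"
  if (any(items$co2eq[soc] > 0)) {
    stop("soil-carbon offset must be non-positive", call. = FALSE)
  }
  gross <- sum(items$co2eq[!soc])
  list(gwp_gross = gross, gwp_net = gross + sum(items$co2eq[soc]),
       items = items)
}
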