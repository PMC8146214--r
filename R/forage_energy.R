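#' Net energy requirement per kg of energy-corrected milk
#'
#' Linear function of milk composition: `0.38 * fat + 0.21 * protein + 1.05`
#' MJ NEL per kg ECM, strictly increasing in both fat and protein.
#'
#' @param fat_pct Milk fat content, percent.
#' @param protein_pct Milk protein content, percent.
#' @return MJ NEL per kg ECM.
#' @examples
#' nel_per_kg_ecm(4.9, 3.7)  # 3.689
#' @export
nel_per_kg_ecm <- function(fat_pct, protein_pct) {
  assert_number(fat_pct, "fat_pct", lower = 0, upper = 100)
  assert_number(protein_pct, "protein_pct", lower = 0, upper = 100)
  0.38 * fat_pct + 0.21 * protein_pct + 1.05
}

#' Potential milk yield from herbage energy
#'
#' Converts the herbage net-energy yield of a treatment into potential
#' energy-corrected milk per hectare. `utilization` is the model-closure
#' scalar combining herbage utilization and the share of net energy
#' allocated to milk rather than maintenance and activity; it is calibrated
#' once against the base (unfertilized) treatment and applied to all
#' treatments (see [calibrate_utilization()]).
#'
#' @param energy_yield Herbage energy yield, GJ NEL/ha (vectorized).
#' @param nel_req MJ NEL per kg ECM, from [nel_per_kg_ecm()].
#' @param utilization Fraction of herbage energy realized as milk, in (0, 1].
#' @return Milk yield, t ECM/ha.
#' @examples
#' potential_milk_yield(118, nel_per_kg_ecm(4.9, 3.7), utilization = 1)
#' @export
potential_milk_yield <- function(energy_yield, nel_req, utilization) {
  assert_number(energy_yield, "energy_yield", lower = 0, allow_vector = TRUE)
  assert_number(nel_req, "nel_req", lower = 1.05)
  assert_number(utilization, "utilization")
  if (utilization <= 0 || utilization > 1) {
    stop("`utilization` must be in (0, 1]", call. = FALSE)
  }
  # GJ/ha * 1000 MJ/GJ / (MJ/kg) = kg/ha; /1000 -> t/ha
  energy_yield * utilization / nel_req
}

#' Herbage crude-protein content
#'
#' Crude protein as nitrogen times the conventional 6.25 factor, expressed
#' per kg of dry matter.
#'
#' @param n_yield Nitrogen yield, kg N/ha (vectorized).
#' @param dm_yield Dry-matter yield, t DM/ha.
#' @param cp_factor N-to-CP conversion factor.
#' @return Crude protein content, g CP per kg DM.
#' @examples
#' herbage_cp_content(537, 18.5)  # ~181 g CP/kg DM
#' @export
herbage_cp_content <- function(n_yield, dm_yield, cp_factor = 6.25) {
  assert_number(n_yield, "n_yield", lower = 0, allow_vector = TRUE)
  assert_number(dm_yield, "dm_yield", allow_vector = TRUE)
  if (any(dm_yield <= 0)) stop("`dm_yield` must be positive", call. = FALSE)
  # g N per kg DM = (kg N/ha) / (t DM/ha); times cp_factor -> g CP/kg DM
  cp_factor * n_yield / dm_yield
}

#' Daily dry-matter intake profile of a grazing cow
#'
#' Total daily DM intake as a linear function of live weight and daily milk
#' yield, `DMI = a * LW + b * milk + c`, with coefficient defaults set so
#' that Jersey cows at the reference herd parameters fall in the reported
#' 14-15 kg DM/day range. Pasture intake is the remainder after the fixed
#' parlour supplement.
#'
#' @param milk_yield_per_cow Daily milk yield, kg ECM/cow/day.
#' @param live_weight Cow live weight, kg.
#' @param supplement Parlour concentrate, kg DM/cow/day.
#' @param pasture_cp Crude-protein content of the pasture herbage, g CP/kg DM
#'   (used to form the diet CP concentration).
#' @param constants A [model_constants()] list (intake coefficients and
#'   supplement CP are read from it).
#' @return A list of class `"intake_profile"` with elements
#'   `dm_intake_total`, `dm_intake_pasture`, `dm_intake_supplement` (kg
#'   DM/cow/day), `cp_intake` (g CP/cow/day) and `diet_cp_content`
#'   (g CP/kg DM).
#' @examples
#' estimate_dm_intake(8.6, live_weight = 380, pasture_cp = 181)
#' @export
estimate_dm_intake <- function(milk_yield_per_cow, live_weight,
                               supplement = NULL, pasture_cp = 180,
                               constants = model_constants()) {
  co <- constants$intake
  supplement <- supplement %||% constants$supplement$dm_per_day
  assert_number(milk_yield_per_cow, "milk_yield_per_cow", lower = 0)
  assert_number(live_weight, "live_weight", lower = 1)
  assert_number(supplement, "supplement", lower = 0)
  assert_number(pasture_cp, "pasture_cp", lower = 0)

  total <- co$lw_coef * live_weight + co$milk_coef * milk_yield_per_cow +
    co$intercept
  if (total < 5 || total > 30) {
    stop(sprintf(paste0("implausible DM intake (%.1f kg/day); check intake",
                        " coefficients"), total), call. = FALSE)
  }
  pasture <- max(total - supplement, 0)
  cp_intake <- pasture * pasture_cp + supplement * constants$supplement$cp_content
  structure(list(dm_intake_total = total,
                 dm_intake_pasture = pasture,
                 dm_intake_supplement = supplement,
                 cp_intake = cp_intake,
                 diet_cp_content = cp_intake / total),
            class = "intake_profile")
}
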