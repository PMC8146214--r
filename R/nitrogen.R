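#' Nitrogen exported in milk
#'
#' Milk protein yield divided by the protein-to-N conversion factor.
#'
#' @param milk_yield Milk yield, t ECM/ha (vectorized).
#' @param protein_pct Milk protein content, percent.
#' @param divisor Protein-to-N divisor.
#' @return Milk N export, kg N/ha.
#' @examples
#' milk_n_export(14.8, 3.7)  # ~85.8 kg N/ha
#' @export
milk_n_export <- function(milk_yield, protein_pct, divisor = 6.38) {
  assert_number(milk_yield, "milk_yield", lower = 0, allow_vector = TRUE)
  assert_number(protein_pct, "protein_pct", lower = 0, upper = 100)
  assert_number(divisor, "divisor", lower = 1)
  milk_yield * 1000 * protein_pct / 100 / divisor
}

#' Excreta nitrogen returned to pasture
#'
#' Ingested pasture N not captured in milk is excreted; the stated
#' proportion of it lands back on the grazed sward.
#'
#' @param n_intake Pasture N intake, kg N/ha (vectorized).
#' @param milk_n Milk N export, kg N/ha.
#' @param proportion Fraction of excreted N deposited on pasture.
#' @return Excreta N returned, kg N/ha.
#' @examples
#' excreta_n(537, 85.8, 0.83)
#' @export
excreta_n <- function(n_intake, milk_n, proportion) {
  assert_number(n_intake, "n_intake", lower = 0, allow_vector = TRUE)
  assert_number(milk_n, "milk_n", lower = 0, allow_vector = TRUE)
  assert_fraction(proportion, "proportion")
  if (any(milk_n > n_intake)) {
    stop("infeasible scenario: milk N export exceeds N intake", call. = FALSE)
  }
  (n_intake - milk_n) * proportion
}

#' Daily nitrogen excretion per cow
#'
#' Nitrogen intake (from the diet's DM intake and crude-protein content)
#' times the excretion fraction, plus an optional live-weight maintenance
#' term. The default excretion fraction of 0.84 reflects the low milk-N
#' capture of grazing dairy cows (roughly 16% of ingested N leaves in milk).
#'
#' @param intake An `intake_profile` from [estimate_dm_intake()].
#' @param live_weight Cow live weight, kg.
#' @param excretion_fraction Share of ingested N excreted.
#' @param lw_coef Additional excretion per kg live weight, g N/kg/day.
#' @param cp_factor CP-to-N conversion factor.
#' @return Daily N excretion, g N/cow/day. Values outside the 150-600 g
#'   plausibility band raise an error.
#' @export
nex_per_cow <- function(intake, live_weight,
                        excretion_fraction = 0.84, lw_coef = 0,
                        cp_factor = 6.25) {
  stopifnot(inherits(intake, "intake_profile"))
  assert_number(live_weight, "live_weight", lower = 1)
  assert_fraction(excretion_fraction, "excretion_fraction")
  assert_number(lw_coef, "lw_coef", lower = 0)
  n_intake <- intake$cp_intake / cp_factor  # g N/day
  nex <- excretion_fraction * n_intake + lw_coef * live_weight
  if (n_intake > 0 && (nex < 150 || nex > 600)) {
    stop(sprintf("N excretion %.0f g/day outside the 150-600 g plausibility band",
                 nex), call. = FALSE)
  }
  nex
}

#' Ammonia-N volatilized from excreta deposited at grazing
#'
#' The total-ammoniacal-N (TAN) share of the excreted N times the TAN
#' emission factor for deposition during grazing.
#'
#' @param excreta_n Excreta N on pasture, kg N/ha (vectorized).
#' @param tan_fraction TAN share of excreted N.
#' @param tan_ef NH3-N emitted per unit TAN.
#' @return NH3-N loss, kg N/ha.
#' @examples
#' nh3_loss(374.5, 0.60, 0.65)
#' @export
nh3_loss <- function(excreta_n, tan_fraction, tan_ef) {
  assert_number(excreta_n, "excreta_n", lower = 0, allow_vector = TRUE)
  assert_fraction(tan_fraction, "tan_fraction")
  assert_fraction(tan_ef, "tan_ef")
  excreta_n * tan_fraction * tan_ef
}

#' Leached nitrogen
#'
#' A fixed leaching fraction applied to a nitrogen amount; negative amounts
#' (e.g. a negative field surplus when leaching is computed on the surplus
#' basis) produce zero leaching rather than a negative loss.
#'
#' @param n_basis N amount the leaching fraction applies to, kg N/ha
#'   (vectorized). Under the default pipeline configuration this is the N
#'   applied to the field (fertilizer plus deposited excreta); under the
#'   `"surplus"` configuration it is the field-N-balance.
#' @param frac_leach Leaching fraction.
#' @return Leached N, kg N/ha.
#' @examples
#' leached_n(299, 0.24)
#' leached_n(-119, 0.24)  # 0
#' @export
leached_n <- function(n_basis, frac_leach) {
  assert_number(n_basis, "n_basis", allow_vector = TRUE)
  assert_fraction(frac_leach, "frac_leach")
  pmax(n_basis, 0) * frac_leach
}

#' Field-level nitrogen balance
#'
#' Fertilizer N plus excreta returns (net of ammonia volatilization) minus
#' the N removed in harvested/grazed herbage. May be negative (soil N
#' mining).
#'
#' @param fertilizer_n Fertilizer input, kg N/ha (vectorized).
#' @param excreta_returned Excreta N deposited on pasture, kg N/ha.
#' @param nh3_n NH3-N volatilized from those returns, kg N/ha.
#' @param herbage_n_yield Herbage N removal, kg N/ha.
#' @return Field-N-balance, kg N/ha.
#' @export
field_n_balance <- function(fertilizer_n, excreta_returned, nh3_n,
                            herbage_n_yield) {
  assert_number(fertilizer_n, "fertilizer_n", lower = 0, allow_vector = TRUE)
  assert_number(excreta_returned, "excreta_returned", lower = 0,
                allow_vector = TRUE)
  assert_number(nh3_n, "nh3_n", lower = 0, allow_vector = TRUE)
  assert_number(herbage_n_yield, "herbage_n_yield", lower = 0,
                allow_vector = TRUE)
  fertilizer_n + (excreta_returned - nh3_n) - herbage_n_yield
}

#' Farm-gate nitrogen balance
#'
#' Imports (fertilizer, purchased feed) minus exports (milk, meat) at the
#' farm gate. Gaseous losses are deliberately not deducted.
#'
#' @param fertilizer_n Fertilizer N import, kg N/ha (vectorized).
#' @param supplement_n Feed N import, kg N/ha.
#' @param milk_n Milk N export, kg N/ha.
#' @param meat_n Meat (live-weight) N export, kg N/ha.
#' @return Farm-N-balance, kg N/ha.
#' @examples
#' farm_n_balance(0, 124.8, 85.8, 8)  # ~31 kg N/ha
#' @export
farm_n_balance <- function(fertilizer_n, supplement_n, milk_n, meat_n) {
  assert_number(fertilizer_n, "fertilizer_n", lower = 0, allow_vector = TRUE)
  assert_number(supplement_n, "supplement_n", lower = 0, allow_vector = TRUE)
  assert_number(milk_n, "milk_n", lower = 0, allow_vector = TRUE)
  assert_number(meat_n, "meat_n", lower = 0, allow_vector = TRUE)
  fertilizer_n + supplement_n - milk_n - meat_n
}

#' Nitrogen footprint of milk
#'
#' Predicted N emissions (ammonia, leached N and N2O-N) per kg of
#' energy-corrected milk.
#'
#' @param nh3_n NH3-N loss, kg N/ha (vectorized).
#' @param leached N leached, kg N/ha.
#' @param n2o_n N2O-N emitted (direct plus indirect), kg N/ha.
#' @param milk_yield Milk yield, t ECM/ha.
#' @return N footprint, g N per kg ECM.
#' @export
n_footprint <- function(nh3_n, leached, n2o_n, milk_yield) {
  assert_number(nh3_n, "nh3_n", lower = 0, allow_vector = TRUE)
  assert_number(leached, "leached", lower = 0, allow_vector = TRUE)
  assert_number(n2o_n, "n2o_n", lower = 0, allow_vector = TRUE)
  assert_number(milk_yield, "milk_yield", allow_vector = TRUE)
  if (any(milk_yield <= 0)) stop("`milk_yield` must be positive", call. = FALSE)
  # kg N/ha -> g N per kg milk: *1000 over (t/ha * 1000)
  (nh3_n + leached + n2o_n) / milk_yield
}
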