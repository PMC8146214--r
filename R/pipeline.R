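# Stage orchestration: herbage -> milk -> nitrogen ledger -> GHG inventory
# -> footprints, per treatment-year, then summarized per treatment.

# All per-year arithmetic lives here so every stage sees identical unit
# conventions (kg and kg N per ha per year internally; t and GJ at the I/O
# boundary).
pipeline_year <- function(rec, n_rate, constants, ef, cal) {
  hd <- constants$herd
  ni <- constants$nitrogen

  # --- stage 1: energy to milk ------------------------------------------
  milk <- potential_milk_yield(rec$energy_yield, cal$nel, cal$utilization)
  milk_per_cow_day <- milk * 1000 / hd$stocking_rate / 365
  pasture_cp <- herbage_cp_content(rec$n_yield, rec$dm_yield, ni$cp_factor)
  intake <- estimate_dm_intake(milk_per_cow_day, hd$live_weight,
                               constants$supplement$dm_per_day, pasture_cp,
                               constants)

  # --- stage 2: nitrogen ledger -----------------------------------------
  milk_n <- milk_n_export(milk, hd$milk_protein_pct, ni$milk_n_divisor)
  excreted <- excreta_n(rec$n_yield, milk_n, 1)          # total excreted N
  returned <- excreted * ni$excreta_deposition           # deposited on pasture
  nh3 <- nh3_loss(returned, ni$tan_fraction, ni$tan_ef_grazing)
  field <- field_n_balance(n_rate, returned, nh3, rec$n_yield)
  leach_basis <- switch(ni$leach_basis,
                        applied = n_rate + returned,
                        surplus = field)
  leach <- leached_n(leach_basis, ni$frac_leach)
  farm <- farm_n_balance(n_rate, cal$supplement_n, milk_n, ni$meat_n_export)

  # --- stage 3: GHG inventory -------------------------------------------
  n2o_dir <- n2o_direct(field, constants)
  n2o_ind <- n2o_indirect(nh3, leach, ni$ef_volatilization, ni$ef_leaching)
  ch4 <- enteric_ch4(intake, hd$stocking_rate, constants, cal$methane_scale)
  inputs <- embodied_inputs(n_rate, ef, constants)
  supplement_co2 <- constants$supplement$dm_per_day * 365 * hd$stocking_rate *
    constants$supplement$production_ef
  irr <- irrigation_emissions(constants$farm$irrigation_volume, ef)
  mgmt <- management_emissions(milk, hd$stocking_rate, ef, constants)
  soc <- soc_change(rec$dm_yield, constants, cal$soc_retention)

  items <- data.frame(
    item = c("enteric_ch4", "pasture_n2o_direct", "pasture_n2o_indirect",
             "fertilizer_embodied", "supplement_feed", "seeds_and_renovation",
             "field_operations", "irrigation_energy", "milking_shed",
             "manure_storage", "soc_offset"),
    gas = c("ch4", "n2o", "n2o", "co2", "co2", "co2", "co2", "co2", "co2",
            "co2", "co2_soc"),
    mass = c(ch4, n2o_dir, n2o_ind, inputs$fertilizer_embodied,
             supplement_co2, inputs$seeds_and_renovation,
             inputs$field_operations, irr, mgmt$milking_shed,
             mgmt$manure_storage, soc$offset * 1000),
    stringsAsFactors = FALSE)
  agg <- aggregate_gwp(items, constants)

  n2o_n_total <- (n2o_dir + n2o_ind) * 28 / 44
  list(
    metrics = data.frame(
      treatment = rec$treatment, year = rec$year, n_rate = n_rate,
      dm_yield = rec$dm_yield, n_yield = rec$n_yield,
      energy_yield = rec$energy_yield,
      milk_yield = milk, milk_n = milk_n,
      dm_intake = intake$dm_intake_total,
      excreted_n = excreted, returned_n = returned, nh3_n = nh3,
      leached_n = leach, field_n_balance = field, farm_n_balance = farm,
      supplement_n = cal$supplement_n,
      n2o_direct_kg = n2o_dir, n2o_indirect_kg = n2o_ind,
      n_footprint = n_footprint(nh3, leach, n2o_n_total, milk),
      enteric_ch4_kg = ch4,
      enteric_ch4_co2eq = agg$items$co2eq[agg$items$item == "enteric_ch4"],
      soc_sequestration = soc$sequestration,
      gwp_gross = agg$gwp_gross, gwp_net = agg$gwp_net,
      stringsAsFactors = FALSE),
    items = cbind(treatment = rec$treatment, year = rec$year, agg$items))
}

pipeline_treatment <- function(scenario, constants, ef, cal) {
  rows <- lapply(seq_len(nrow(scenario$years)), function(i) {
    pipeline_year(scenario$years[i, ], scenario$n_fertilizer_rate,
                  constants, ef, cal)$metrics
  })
  do.call(rbind, rows)
}

#' Run the farm-gate footprint pipeline
#'
#' Executes all stages for a set of treatment scenarios: potential milk
#' yield from herbage energy, the field and farm nitrogen ledgers with
#' ammonia, leaching and N2O losses, the per-hectare GHG inventory with its
#' soil-carbon offset, and the per-treatment footprint summary.
#'
#' @param scenarios Named list of [treatment_scenario()] objects.
#' @param constants A [model_constants()] list.
#' @param ef An [emission_factors()] table.
#' @param calibration A `"pasture_calibration"` from [calibrate_model()];
#'   computed from `reference` when omitted.
#' @param reference Reference summary used for calibration anchors when
#'   `calibration` is not supplied.
#' @return A list of class `"footprint_run"`:
#'   \describe{
#'     \item{yearly}{per treatment-year metrics (milk, every N-ledger line,
#'       N2O, CH4, gross/net GWP in kg CO2eq/ha).}
#'     \item{inventory}{long-format emission line items (treatment, year,
#'       item, gas, mass, co2eq).}
#'     \item{summary}{per-treatment three-year summary: milk yield (t
#'       ECM/ha), GWP gross/net (t CO2eq/ha), carbon footprint with the
#'       soil-carbon offset (kg CO2eq/kg ECM; mean of yearly ratios, with
#'       the ratio-of-means alongside), N footprint (g N/kg ECM), farm- and
#'       field-N-balances (kg N/ha), land requirement (m2/kg ECM) and the
#'       enteric-methane share of gross GWP (%).}
#'     \item{calibration}{the calibration actually used.}
#'   }
#' @examples
#' run <- run_footprint_pipeline(load_reference_scenarios())
#' run$summary[, c("treatment", "milk_yield", "cf_net")]
#' @export
run_footprint_pipeline <- function(scenarios, constants = model_constants(),
                                   ef = emission_factors(),
                                   calibration = NULL,
                                   reference = reference_summary()) {
  calibration <- calibration %||%
    calibrate_model(scenarios, reference, constants, ef)
  out <- lapply(scenarios, function(s) {
    res <- lapply(seq_len(nrow(s$years)), function(i) {
      pipeline_year(s$years[i, ], s$n_fertilizer_rate, constants, ef,
                    calibration)
    })
    list(metrics = do.call(rbind, lapply(res, `[[`, "metrics")),
         items = do.call(rbind, lapply(res, `[[`, "items")))
  })
  yearly <- do.call(rbind, lapply(out, `[[`, "metrics"))
  inventory <- do.call(rbind, lapply(out, `[[`, "items"))
  rownames(yearly) <- rownames(inventory) <- NULL

  summary <- do.call(rbind, lapply(out, function(o) {
    m <- o$metrics
    mean_items <- stats::aggregate(co2eq ~ item + gas, data = o$items, FUN = mean)
    shares <- contribution_shares(mean_items)
    data.frame(
      treatment = m$treatment[1], n_rate = m$n_rate[1],
      milk_yield = mean(m$milk_yield),
      gwp_gross = mean(m$gwp_gross) / 1000,
      gwp_net = mean(m$gwp_net) / 1000,
      cf_net = carbon_footprint(m$gwp_net / 1000, m$milk_yield),
      cf_net_ratio_of_means = mean(m$gwp_net) / 1000 / mean(m$milk_yield),
      n_footprint = mean(m$n_footprint),
      farm_n_balance = mean(m$farm_n_balance),
      field_n_balance = mean(m$field_n_balance),
      land_requirement = land_requirement(mean(m$milk_yield)),
      ch4_share_pct = shares$share_pct[shares$item == "enteric_ch4"],
      soc_sequestration = mean(m$soc_sequestration),
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  summary <- summary[order(summary$n_rate), ]

  structure(list(yearly = yearly, inventory = inventory, summary = summary,
                 calibration = calibration),
            class = "footprint_run")
}

#' @export
print.footprint_run <- function(x, ...) {
  cat("<footprint_run:", nrow(x$summary), "treatments,",
      nrow(x$yearly), "treatment-years>\n")
  cols <- c("treatment", "milk_yield", "gwp_net", "cf_net", "n_footprint",
            "farm_n_balance")
  print(cbind(x$summary["treatment"],
              round(x$summary[setdiff(cols, "treatment")], 2)))
  invisible(x)
}

#' File-based pipeline run
#'
#' Thin wrapper around [run_footprint_pipeline()] that reads scenarios from
#' a CSV, applies optional constant overrides, writes the per-stage tables
#' and a JSON manifest of every constant and calibration value actually
#' used, and returns the run invisibly.
#'
#' @param input Path to a scenarios CSV (schema of
#'   `inst/extdata/herbage_yields.csv`); defaults to the shipped table.
#' @param output_dir Directory for the output files (created if needed).
#' @param overrides Optional constants overrides (named nested list).
#' @param use_reference_anchors If `TRUE` (default) the calibration anchors
#'   come from [reference_summary()]; otherwise a `reference` data.frame
#'   must be supplied.
#' @param reference Optional custom reference summary.
#' @return Invisibly, the `"footprint_run"` object; side effect: files
#'   `yearly.csv`, `inventory.csv`, `summary.csv` and `manifest.json` in
#'   `output_dir`.
#' @export
run_pipeline <- function(input = NULL, output_dir = tempfile("footprint_run_"),
                         overrides = NULL, use_reference_anchors = TRUE,
                         reference = NULL) {
  if (!is.null(input) && !file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  scenarios <- if (is.null(input)) load_reference_scenarios() else
    read_scenarios(input)
  constants <- model_constants(overrides)
  ef <- emission_factors()
  reference <- reference %||% if (use_reference_anchors) reference_summary()
  if (is.null(reference)) {
    stop("no calibration anchors: supply `reference` or set ",
         "`use_reference_anchors = TRUE`", call. = FALSE)
  }
  run <- run_footprint_pipeline(scenarios, constants, ef, reference = reference)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$yearly, file.path(output_dir, "yearly.csv"),
                   row.names = FALSE)
  utils::write.csv(run$inventory, file.path(output_dir, "inventory.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(output_dir, "summary.csv"),
                   row.names = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("pastureLCA")),
                   constants = unclass(constants),
                   calibration = unclass(run$calibration),
                   input = if (is.null(input)) "package reference scenarios"
                           else normalizePath(input))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(run)
}

#' Compare a pipeline run against the published per-treatment summary
#'
#' Report-only check of a run produced from the reference scenarios: milk
#' yields, CH4 shares, carbon-footprint ordering, balance monotonicity and
#' field-balance sign pattern, each with its computed value, the reference
#' value and a pass flag.
#'
#' @param run A `"footprint_run"` object.
#' @param reference A [reference_summary()] data.frame.
#' @param tolerances Named list of tolerances: `milk_rel` (relative, milk
#'   yield), `share_pts` (percentage points, CH4 share), `seq_rel`
#'   (relative, C sequestration).
#' @return data.frame with columns `check`, `treatment`, `computed`,
#'   `reference`, `pass`.
#' @export
validate_against_reference <- function(run, reference = reference_summary(),
                                       tolerances = list(milk_rel = 0.05,
                                                         share_pts = 5,
                                                         seq_rel = 0.15)) {
  s <- run$summary[match(reference$treatment, run$summary$treatment), ]
  rows <- list()
  add <- function(check, treatment, computed, ref, pass) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, treatment = treatment, computed = computed,
      reference = ref, pass = pass, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(reference))) {
    add("milk_yield", reference$treatment[i], s$milk_yield[i],
        reference$milk_yield[i],
        abs(s$milk_yield[i] / reference$milk_yield[i] - 1) <=
          tolerances$milk_rel)
    add("ch4_share_pct", reference$treatment[i], s$ch4_share_pct[i],
        reference$ch4_share_pct[i],
        abs(s$ch4_share_pct[i] - reference$ch4_share_pct[i]) <=
          tolerances$share_pts)
    add("soc_sequestration", reference$treatment[i], s$soc_sequestration[i],
        reference$soc_sequestration[i],
        abs(s$soc_sequestration[i] / reference$soc_sequestration[i] - 1) <=
          tolerances$seq_rel)
    add("field_balance_sign", reference$treatment[i],
        sign(s$field_n_balance[i]), sign(reference$field_n_balance[i]),
        sign(s$field_n_balance[i]) == sign(reference$field_n_balance[i]))
  }
  add("gwp_net_increasing", "all", NA, NA, !is.unsorted(s$gwp_net))
  add("farm_balance_increasing", "all", NA, NA, !is.unsorted(s$farm_n_balance))
  add("cf_ordering_n20_to_n80", "all", NA, NA,
      !is.unsorted(s$cf_net[-1], strictly = TRUE))
  do.call(rbind, rows)
}
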