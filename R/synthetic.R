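#' Configuration for the synthetic scenario generator
#'
#' The generator emulates the statistical structure of a multi-year N-rate
#' grazing trial: a linear-plateau dry-matter response to fertilizer N with
#' a weak post-plateau slope, additive year effects shared across
#' treatments, within-treatment noise pooled across cells, herbage N
#' content increasing with the fertilizer rate, and a near-flat energy
#' density. Defaults reproduce the reference trial's magnitudes: a plateau
#' near 220 kg N/ha/yr, base yield 18.5 t DM/ha and three-year treatment
#' means inside the 18.5-21.5 t band.
#'
#' @param fertilizer_rates Annual N rates, kg N/ha/yr.
#' @param n_years Number of trial years.
#' @param base_dm Dry-matter yield at zero N, t DM/ha.
#' @param response_slope DM response below the plateau, t DM per kg N.
#' @param plateau_rate Fertilizer rate at which the main response plateaus,
#'   kg N/ha/yr.
#' @param post_plateau_slope Residual DM response above the plateau.
#' @param year_effect_sd SD of the shared year effect, t DM/ha.
#' @param noise_sd SD of within-treatment noise, t DM/ha (single pooled
#'   value; the reference trial's per-cell SEMs are too erratic to use).
#' @param n_content_base Herbage N content at zero N, g N/kg DM.
#' @param n_content_slope Increase in N content per kg fertilizer N.
#' @param n_content_sd Noise SD on N content, g N/kg DM.
#' @param n_dilution Dilution of N content per t DM of yield deviation
#'   (g N/kg DM per t DM/ha): years with above-curve growth have
#'   proportionally less concentrated herbage, which keeps the spread of
#'   generated N yields at the magnitude of the reference trial's standard
#'   errors instead of inheriting the full DM noise.
#' @param energy_density Mean energy density, MJ NEL/kg DM.
#' @param energy_density_sd Noise SD on energy density.
#' @param seed Integer seed; identical seeds give identical scenarios.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(fertilizer_rates = c(0, 220, 440, 660, 880),
                             n_years = 3,
                             base_dm = 18.5,
                             response_slope = 1.7 / 220,
                             plateau_rate = 220,
                             post_plateau_slope = 0.002,
                             year_effect_sd = 1.1,
                             noise_sd = 1.2,
                             n_content_base = 29,
                             n_content_slope = 0.011,
                             n_content_sd = 0.6,
                             n_dilution = 1.0,
                             energy_density = 6.4,
                             energy_density_sd = 0.15,
                             seed = 1) {
  cfg <- as.list(environment())
  if (is.unsorted(cfg$fertilizer_rates) || any(cfg$fertilizer_rates < 0)) {
    stop("fertilizer_rates must be nonnegative and ascending", call. = FALSE)
  }
  for (nm in c("year_effect_sd", "noise_sd", "n_content_sd",
               "energy_density_sd", "n_dilution")) {
    assert_number(cfg[[nm]], nm, lower = 0)
  }
  if (cfg$plateau_rate > max(cfg$fertilizer_rates)) {
    stop("plateau_rate must lie within the fertilizer-rate range",
         call. = FALSE)
  }
  assert_number(cfg$n_years, "n_years", lower = 1)
  class(cfg) <- "synthetic_config"
  cfg
}

dm_response_curve <- function(rate, cfg) {
  cfg$base_dm + cfg$response_slope * pmin(rate, cfg$plateau_rate) +
    cfg$post_plateau_slope * pmax(rate - cfg$plateau_rate, 0)
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic treatment scenarios
#'
#' Draws a full multi-year, multi-treatment scenario set from a
#' [synthetic_config()]. With all noise SDs at zero the yields lie exactly
#' on the response curves. All scenario invariants (positive yields, N
#' content below 6% of DM, energy density within 4-9 MJ/kg DM) are enforced
#' on the generated records.
#'
#' @param config A [synthetic_config()].
#' @return Named list of [treatment_scenario()] objects (`S0`, `S220`, ...,
#'   named by fertilizer rate).
#' @examples
#' sc <- generate_scenarios(synthetic_config(seed = 42))
#' sapply(sc, function(s) mean(s$years$dm_yield))
#' @export
generate_scenarios <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed, {
    year_eff <- stats::rnorm(config$n_years, 0, config$year_effect_sd)
    out <- lapply(config$fertilizer_rates, function(rate) {
      mu <- dm_response_curve(rate, config)
      dm <- mu + year_eff + stats::rnorm(config$n_years, 0, config$noise_sd)
      dm <- pmax(dm, 0.25 * mu)  # guard against unphysical draws
      ncont <- config$n_content_base + config$n_content_slope * rate -
        config$n_dilution * (dm - mu) +
        stats::rnorm(config$n_years, 0, config$n_content_sd)
      ncont <- pmin(pmax(ncont, 5), 58)
      dens <- config$energy_density +
        stats::rnorm(config$n_years, 0, config$energy_density_sd)
      dens <- pmin(pmax(dens, 4.05), 8.95)
      treatment_scenario(
        paste0("S", rate), rate,
        data.frame(year = seq_len(config$n_years), dm_yield = dm,
                   n_yield = dm * ncont, energy_yield = dm * dens))
    })
    names(out) <- paste0("S", config$fertilizer_rates)
    out
  })
}

#' Parameter-recovery experiment for the calibrated closures
#'
#' Simulation check that the two nitrogen-side calibration parameters -
#' the energy-utilization closure and the supplement-N import - are
#' recoverable from the outputs they are calibrated against. Each
#' replicate generates a synthetic trial, produces the base treatment's
#' "published" outputs (mean milk yield and farm-N-balance) under the true
#' parameters, optionally rounds them to a table-like precision, and
#' re-estimates both parameters from those outputs with the package's
#' calibration routines.
#'
#' @param true_params List with `utilization` and `supplement_n`.
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @param config A [synthetic_config()] (its own seed is ignored; each
#'   replicate derives one from `seed`).
#' @param round_outputs If `TRUE`, milk yield is rounded to 0.1 t and the
#'   balance to 1 kg before recovery, mimicking recovery from a printed
#'   table.
#' @param constants A [model_constants()] list.
#' @return List with `estimates` (one row per replicate), and `report`
#'   (bias, relative bias, RMSE per parameter).
#' @export
parameter_recovery_experiment <- function(true_params = list(utilization = 0.46,
                                                             supplement_n = 125),
                                          n_reps = 100, seed = 1,
                                          config = synthetic_config(),
                                          round_outputs = FALSE,
                                          constants = model_constants()) {
  assert_number(n_reps, "n_reps", lower = 1)
  u_true <- true_params$utilization
  s_true <- true_params$supplement_n
  assert_fraction(u_true, "utilization")
  assert_number(s_true, "supplement_n", lower = 0)
  nel <- nel_per_kg_ecm(constants$herd$milk_fat_pct,
                        constants$herd$milk_protein_pct)

  one_rep <- function(r) {
    cfg <- config
    cfg$seed <- (seed * 10007L + r) %% .Machine$integer.max
    sc <- generate_scenarios(cfg)
    base <- sc[[base_treatment_id(sc)]]
    energy <- average_over_years(base, "energy_yield")
    milk <- potential_milk_yield(energy, nel, u_true)
    milk_n <- milk_n_export(milk, constants$herd$milk_protein_pct,
                            constants$nitrogen$milk_n_divisor)
    balance <- farm_n_balance(base$n_fertilizer_rate, s_true, milk_n,
                              constants$nitrogen$meat_n_export)
    if (round_outputs) {
      milk <- round(milk, 1)
      balance <- round(balance)
    }
    ref <- data.frame(treatment = base$treatment_id,
                      n_rate = base$n_fertilizer_rate,
                      milk_yield = milk, farm_n_balance = balance)
    u_hat <- tryCatch(calibrate_utilization(sc, ref, constants),
                      error = function(e) NA_real_)
    s_hat <- tryCatch(calibrate_supplement_n(ref, constants),
                      error = function(e) NA_real_)
    c(utilization = u_hat, supplement_n = s_hat)
  }

  est <- t(vapply(seq_len(n_reps), one_rep, numeric(2)))
  est <- as.data.frame(est)
  report <- do.call(rbind, lapply(c("utilization", "supplement_n"), function(p) {
    truth <- true_params[[p]]
    x <- est[[p]]
    ok <- is.finite(x)
    data.frame(parameter = p, truth = truth,
               n_converged = sum(ok),
               mean_estimate = mean(x[ok]),
               bias = mean(x[ok]) - truth,
               rel_bias = (mean(x[ok]) - truth) / truth,
               rmse = sqrt(mean((x[ok] - truth)^2)),
               stringsAsFactors = FALSE)
  }))
  list(estimates = est, report = report)
}
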