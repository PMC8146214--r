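#' One pasture-year herbage record
#'
#' Bundles the measured productivity of a single treatment-year: dry-matter
#' yield (t DM/ha), nitrogen yield (kg N/ha) and net-energy-for-lactation
#' yield (GJ NEL/ha), optionally with their standard errors. Validation
#' enforces agronomic plausibility: herbage N content at most 6% of DM and
#' energy density between 4 and 9 MJ NEL per kg DM.
#'
#' @param treatment_id Treatment label, e.g. `"N20"`.
#' @param year_index Integer year of the trial (1-based).
#' @param dm_yield Dry-matter yield, t DM/ha.
#' @param n_yield Nitrogen yield, kg N/ha.
#' @param energy_yield Energy yield, GJ NEL/ha.
#' @param sem_dm,sem_n,sem_energy Optional standard errors in the same units.
#' @return A one-row data.frame of class `"herbage_year_record"`.
#' @examples
#' herbage_year_record("N0", 1, dm_yield = 19.3, n_yield = 519, energy_yield = 123)
#' @export
herbage_year_record <- function(treatment_id, year_index, dm_yield, n_yield,
                                energy_yield, sem_dm = NA_real_,
                                sem_n = NA_real_, sem_energy = NA_real_) {
  rec <- data.frame(treatment = as.character(treatment_id),
                    year = as.integer(year_index),
                    dm_yield = as.numeric(dm_yield),
                    n_yield = as.numeric(n_yield),
                    energy_yield = as.numeric(energy_yield),
                    sem_dm = as.numeric(sem_dm),
                    sem_n = as.numeric(sem_n),
                    sem_energy = as.numeric(sem_energy),
                    stringsAsFactors = FALSE)
  validate_herbage_records(rec)
  class(rec) <- c("herbage_year_record", "data.frame")
  rec
}

validate_herbage_records <- function(rec) {
  for (col in c("dm_yield", "n_yield", "energy_yield")) {
    bad <- !is.finite(rec[[col]]) | rec[[col]] <= 0
    if (any(bad)) {
      stop(sprintf("invalid %s for %s year %s", col,
                   rec$treatment[bad][1], rec$year[bad][1]), call. = FALSE)
    }
  }
  # N content of herbage, g N per kg DM (n_yield kg/ha over dm_yield t/ha)
  n_content <- rec$n_yield / rec$dm_yield
  if (any(n_content > 60)) {
    i <- which(n_content > 60)[1]
    stop(sprintf("herbage N content above 6%% of DM for %s year %s",
                 rec$treatment[i], rec$year[i]), call. = FALSE)
  }
  dens <- rec$energy_yield / rec$dm_yield  # MJ NEL per kg DM
  if (any(dens < 4 | dens > 9)) {
    i <- which(dens < 4 | dens > 9)[1]
    stop(sprintf("energy density outside 4-9 MJ NEL/kg DM for %s year %s",
                 rec$treatment[i], rec$year[i]), call. = FALSE)
  }
  invisible(rec)
}

#' One fertilization treatment scenario
#'
#' A treatment scenario holds the annual N fertilizer rate, the number of
#' split dressings, and exactly one herbage record per trial year.
#'
#' @param treatment_id Treatment label.
#' @param n_rate Annual fertilizer rate, kg N/ha/yr.
#' @param years A data.frame of yearly records (columns `year`, `dm_yield`,
#'   `n_yield`, `energy_yield` and optional SEM columns).
#' @param dressings_per_year Number of split fertilizer applications.
#' @return A list of class `"treatment_scenario"`.
#' @export
treatment_scenario <- function(treatment_id, n_rate, years,
                               dressings_per_year = 12) {
  assert_number(n_rate, "n_rate", lower = 0)
  years <- as.data.frame(years)
  if (!"treatment" %in% names(years)) years$treatment <- treatment_id
  for (col in c("sem_dm", "sem_n", "sem_energy")) {
    if (!col %in% names(years)) years[[col]] <- NA_real_
  }
  validate_herbage_records(years)
  if (anyDuplicated(years$year)) {
    stop("duplicate year index in scenario ", treatment_id, call. = FALSE)
  }
  if (!setequal(years$year, seq_along(years$year))) {
    stop("year indices must be 1..n in scenario ", treatment_id, call. = FALSE)
  }
  years <- years[order(years$year),
                 c("treatment", "year", "dm_yield", "n_yield", "energy_yield",
                   "sem_dm", "sem_n", "sem_energy")]
  rownames(years) <- NULL
  structure(list(treatment_id = as.character(treatment_id),
                 n_fertilizer_rate = as.numeric(n_rate),
                 dressings_per_year = as.integer(dressings_per_year),
                 years = years),
            class = "treatment_scenario")
}

#' @export
print.treatment_scenario <- function(x, ...) {
  cat(sprintf("<treatment_scenario %s: %g kg N/ha/yr, %d years>\n",
              x$treatment_id, x$n_fertilizer_rate, nrow(x$years)))
  print(x$years)
  invisible(x)
}

#' Load the reference field-trial scenarios
#'
#' Reads the three-year, five-treatment herbage dataset shipped with the
#' package (kikuyu-ryegrass pasture under 0/220/440/660/880 kg N/ha/yr) and
#' returns one validated [treatment_scenario()] per fertilizer rate.
#'
#' @param file Optional path to an alternative CSV with the same columns as
#'   `inst/extdata/herbage_yields.csv`.
#' @return Named list of five `treatment_scenario` objects (N0..N80).
#' @examples
#' sc <- load_reference_scenarios()
#' sc$N0$years$dm_yield
#' @export
load_reference_scenarios <- function(file = NULL) {
  file <- file %||% system.file("extdata", "herbage_yields.csv",
                                package = "pastureLCA", mustWork = TRUE)
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  required <- c("treatment", "n_rate", "year", "dm_yield", "n_yield",
                "energy_yield")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("herbage table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in required[-1]) {
    if (any(is.na(raw[[col]]))) {
      i <- which(is.na(raw[[col]]))[1]
      stop(sprintf("missing value in column '%s' (treatment %s, year %s)",
                   col, raw$treatment[i], raw$year[i]), call. = FALSE)
    }
  }
  ids <- unique(raw$treatment)
  out <- lapply(ids, function(id) {
    rows <- raw[raw$treatment == id, ]
    rate <- unique(rows$n_rate)
    if (length(rate) != 1L) {
      stop("inconsistent n_rate for treatment ", id, call. = FALSE)
    }
    treatment_scenario(id, rate, rows[setdiff(names(rows), "n_rate")])
  })
  names(out) <- ids
  out[order(vapply(out, function(s) s$n_fertilizer_rate, numeric(1)))]
}

#' Published per-treatment summary used for calibration and validation
#'
#' Reference three-year means per treatment: potential milk yield (t ECM/ha),
#' gross and net GWP (t CO2eq/ha), carbon footprint including the soil-carbon
#' offset (kg CO2eq/kg ECM), farm- and field-N-balances (kg N/ha), the
#' enteric-methane share of gross GWP (%) and annual soil C sequestration
#' (t C/ha). The milk yield and farm-balance columns provide the anchors for
#' the model's two nitrogen-side calibrations; the remainder is a validation
#' surface.
#'
#' @param file Optional alternative CSV path.
#' @return data.frame with one row per treatment, ordered by N rate.
#' @export
reference_summary <- function(file = NULL) {
  file <- file %||% system.file("extdata", "reference_summary.csv",
                                package = "pastureLCA", mustWork = TRUE)
  ref <- utils::read.csv(file, stringsAsFactors = FALSE)
  ref[order(ref$n_rate), ]
}

#' Average a yearly field over trial years
#'
#' Arithmetic mean of one measured field across the years of a scenario.
#'
#' @param records Yearly records: a `treatment_scenario`, or a data.frame
#'   with the yield columns.
#' @param field One of `"dm_yield"`, `"n_yield"`, `"energy_yield"`.
#' @return Mean value in the units of the field.
#' @examples
#' sc <- load_reference_scenarios()
#' round(average_over_years(sc$N0, "dm_yield"), 1)  # 18.5
#' @export
average_over_years <- function(records, field) {
  if (inherits(records, "treatment_scenario")) records <- records$years
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to average", call. = FALSE)
  if (!field %in% c("dm_yield", "n_yield", "energy_yield")) {
    stop("unknown field '", field, "'", call. = FALSE)
  }
  mean(records[[field]])
}

#' Write and re-read scenarios
#'
#' Scenarios serialize to the same CSV schema as the shipped herbage table;
#' `read_scenarios()` is the inverse of `write_scenarios()` and reproduces
#' every field (full double precision is retained).
#'
#' @param scenarios A list of [treatment_scenario()] objects.
#' @param file Path of the CSV to write or read.
#' @return `write_scenarios()` returns `file` invisibly; `read_scenarios()`
#'   returns a named list of scenarios.
#' @export
write_scenarios <- function(scenarios, file) {
  rows <- do.call(rbind, lapply(scenarios, function(s) {
    cbind(s$years[, "treatment", drop = FALSE],
          n_rate = s$n_fertilizer_rate,
          s$years[, setdiff(names(s$years), "treatment")])
  }))
  rownames(rows) <- NULL
  # format() would round; write full precision so round-trips are exact
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], function(x) sprintf("%.17g", x))
  utils::write.csv(rows, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(file) {
  load_reference_scenarios(file)
}
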