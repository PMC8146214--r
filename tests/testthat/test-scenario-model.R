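test_that("reference scenarios load with the published trial values", {
  expect_named(ref_scenarios, c("N0", "N20", "N40", "N60", "N80"))
  expect_equal(ref_scenarios$N0$years$dm_yield[1], 19.3)
  expect_equal(ref_scenarios$N80$years$n_yield[3], 900)
  expect_equal(ref_scenarios$N60$n_fertilizer_rate, 660)
  expect_equal(vapply(ref_scenarios, function(s) s$n_fertilizer_rate,
                      numeric(1)),
               c(N0 = 0, N20 = 220, N40 = 440, N60 = 660, N80 = 880))
  for (s in ref_scenarios) {
    expect_equal(s$years$year, 1:3)
    expect_true(all(s$years$n_yield / s$years$dm_yield <= 60))
    dens <- s$years$energy_yield / s$years$dm_yield
    expect_true(all(dens >= 4 & dens <= 9))
  }
})

test_that("corrupt herbage tables are rejected with the offending cell named", {
  tmp <- tempfile(fileext = ".csv")
  raw <- read.csv(system.file("extdata", "herbage_yields.csv",
                              package = "pastureLCA"))
  bad <- raw
  bad$n_yield[4] <- NA
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_reference_scenarios(tmp), "n_yield.*N20", ignore.case = TRUE)

  bad <- raw[, setdiff(names(raw), "energy_yield")]
  write.csv(bad, tmp, row.names = FALSE)
  expect_error(load_reference_scenarios(tmp), "energy_yield")
})

test_that("record validation enforces agronomic plausibility bounds", {
  expect_error(herbage_year_record("X", 1, dm_yield = -1, n_yield = 500,
                                   energy_yield = 120), "dm_yield")
  # N content above 6% of DM
  expect_error(herbage_year_record("X", 1, dm_yield = 10, n_yield = 700,
                                   energy_yield = 64), "N content")
  # energy density outside 4-9 MJ/kg DM
  expect_error(herbage_year_record("X", 1, dm_yield = 10, n_yield = 300,
                                   energy_yield = 120), "energy density")
  expect_error(treatment_scenario("X", 220, data.frame(
    year = c(1, 1), dm_yield = c(19, 20), n_yield = c(500, 510),
    energy_yield = c(120, 125))), "duplicate year")
})

test_that("averaging over years matches the published three-year means", {
  expect_equal(round(sapply(ref_scenarios, average_over_years, "dm_yield"), 1),
               c(N0 = 18.5, N20 = 20.2, N40 = 20.1, N60 = 20.9, N80 = 21.5))
  expect_equal(round(sapply(ref_scenarios, average_over_years, "n_yield")),
               c(N0 = 537, N20 = 580, N40 = 640, N60 = 738, N80 = 833))
  expect_equal(average_over_years(data.frame(dm_yield = c(20, 20, 20)),
                                  "dm_yield"), 20)
  expect_error(average_over_years(ref_scenarios$N0, "ph"), "unknown field")
  expect_error(average_over_years(data.frame(dm_yield = numeric(0)),
                                  "dm_yield"), "no records")
})

test_that("scenario serialization round-trips bit-identically", {
  tmp <- tempfile(fileext = ".csv")
  write_scenarios(ref_scenarios, tmp)
  back <- read_scenarios(tmp)
  expect_identical(names(back), names(ref_scenarios))
  for (id in names(back)) {
    expect_identical(back[[id]]$n_fertilizer_rate,
                     ref_scenarios[[id]]$n_fertilizer_rate)
    expect_equal(back[[id]]$years, ref_scenarios[[id]]$years,
                 tolerance = 0)
  }
})

test_that("constants load, validate, and accept only declared overrides", {
  expect_equal(ref_constants$gwp$n2o, 265)
  expect_equal(ref_constants$gwp$ch4, 28)
  expect_equal(ref_constants$nitrogen$milk_n_divisor, 6.38)
  over <- model_constants(list(nitrogen = list(frac_leach = 0.3)))
  expect_equal(over$nitrogen$frac_leach, 0.3)
  expect_equal(over$gwp$n2o, 265)
  expect_error(model_constants(list(nitrogen = list(frac_lech = 0.3))),
               "unknown constant")
  expect_error(model_constants(list(nitrogen = list(frac_leach = 1.5))),
               "frac_leach")
})

test_that("every inventory activity resolves to exactly one emission factor", {
  needed <- c("grass_seeds", "fertilizer_n", "tillage", "sowing",
              "fertilizing_broadcast", "mulching", "irrigation", "milking",
              "shed_operation", "slurry_store")
  for (a in needed) expect_length(ef_lookup(ref_ef, a), 1L)
  expect_error(ef_lookup(ref_ef, "helicopter"), "no emission factor")
})
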