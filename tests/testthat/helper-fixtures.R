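# Shared fixtures: the reference trial, its published summary, and one
# calibrated pipeline run. Built once per test session.

ref_scenarios <- load_reference_scenarios()
ref_summary <- reference_summary()
ref_constants <- model_constants()
ref_ef <- emission_factors()
ref_cal <- calibrate_model(ref_scenarios, ref_summary, ref_constants, ref_ef)
ref_run <- run_footprint_pipeline(ref_scenarios, ref_constants, ref_ef,
                                  calibration = ref_cal)

# independent brute-force N ledger: enumerate every inflow and outflow item
# and sum them, without reusing the package's balance functions
ledger_field_balance <- function(fertilizer_n, excreta_returned, nh3_n,
                                 herbage_n_yield) {
  inflows <- c(fertilizer = fertilizer_n, excreta = excreta_returned)
  outflows <- c(volatilized = nh3_n, herbage = herbage_n_yield)
  sum(inflows) - sum(outflows)
}

ledger_farm_balance <- function(fertilizer_n, supplement_n, milk_n, meat_n) {
  inflows <- c(fertilizer = fertilizer_n, feed = supplement_n)
  outflows <- c(milk = milk_n, meat = meat_n)
  sum(inflows) - sum(outflows)
}
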