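activity,factor,unit
grass_seeds,2.03,kg CO2eq per kg seed
fertilizer_n,8.60,kg CO2eq per kg N
tillage,75.42,kg CO2eq per ha
sowing,22.76,kg CO2eq per ha
fertilizing_broadcast,25.33,kg CO2eq per application per ha
mulching,21.24,kg CO2eq per ha
irrigation,0.43,kg CO2eq per m3
milking,0.02,kg CO2eq per kg milk
shed_operation,436.00,kg CO2eq per LU per yr
slurry_store,0.06,kg CO2eq per m3
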