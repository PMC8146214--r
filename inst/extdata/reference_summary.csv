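treatment,n_rate,milk_yield,gwp_gross,gwp_net,cf_net,farm_n_balance,field_n_balance,ch4_share_pct,soc_sequestration
N0,0,14.8,22.1,18.4,1.3,31,-119,65,0.85
N20,220,16.6,25.3,21.2,1.3,241,86,58,0.85
N40,440,16.5,29.6,25.4,1.6,462,299,50,0.87
N60,660,17.5,36.6,32.2,1.9,677,501,41,0.89
N80,880,18.0,50.7,46.2,2.6,899,706,30,0.91
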