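treatment,n_rate,year,dm_yield,n_yield,energy_yield,sem_dm,sem_n,sem_energy
N0,0,1,19.3,519,123,9.3,26.8,5.7
N0,0,2,17.4,511,112,4.7,24.6,2.7
N0,0,3,18.7,582,119,11.4,38.9,7.5
N20,220,1,21.5,586,140,14.6,51.9,9.3
N20,220,2,18.4,510,120,6.4,18.7,3.6
N20,220,3,20.6,645,133,6.5,17.7,5.0
N40,440,1,21.1,657,137,9.0,34.4,6.5
N40,440,2,18.9,557,123,0.3,16.6,2.1
N40,440,3,20.3,707,132,0.4,13.5,3.0
N60,660,1,22.9,788,151,0.4,11.0,2.5
N60,660,2,19.2,630,126,0.2,33.3,1.3
N60,660,3,20.6,797,134,1.9,13.0,3.2
N80,880,1,22.6,849,148,0.5,29.0,2.9
N80,880,2,20.5,749,135,0.4,9.7,3.1
N80,880,3,21.5,900,141,0.7,35.3,4.9
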