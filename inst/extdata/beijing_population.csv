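year,resident_population,labor_force,mortality_rate,estimated
2013,21150000,11410000,4.52,FALSE
2014,21520000,11570000,4.92,FALSE
2015,21710000,11860000,4.95,FALSE
2016,21730000,12200000,5.20,FALSE
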