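sex,percentile,height_m,weight_kg
male,P05,1.649,66.21
male,P50,1.759,80.50
male,P95,1.869,96.41
female,P05,1.518,49.44
female,P50,1.618,59.85
female,P95,1.724,72.43
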