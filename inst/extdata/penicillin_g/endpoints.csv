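compartment,organism,endpoint_type,value,unit,assessment_factor
water,algae (growth inhibition),NOEC,10,mg/L,10
microorganism,activated sludge (respiration inhibition),EC50,100,mg/L,100
soil,earthworm,NOEC,2000,mg/kg,100
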