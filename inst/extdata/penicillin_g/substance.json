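{
  "format_version": "1.0",
  "name": "penicillin G (benzylpenicillin potassium)",
  "molar_mass": 372.48,
  "solubility": 307,
  "vapor_pressure": 2370,
  "koc": 421,
  "partition_factor_override": 7.69
}
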