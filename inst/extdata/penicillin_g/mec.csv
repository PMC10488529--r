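sample_id,date,analyte,retention_time,area
sample-1,2023-03-15,penicillin G,5.94,239.4
sample-2,2023-03-16,penicillin G,5.94,239.2
sample-3,2023-03-17,penicillin G,5.92,1748
sample-4,2023-03-18,penicillin G,5.94,239.6
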