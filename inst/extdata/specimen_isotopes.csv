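specimen_id,d13C,d15N,carbon_pct,nitrogen_pct
HIRADO_2017_01,-18.87,11.95,15.82,4.85
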