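# Gas phase at 298.15 K: no encounter limit, k_app = k_act exactly.
temperature_K: 298.15
medium: gas
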