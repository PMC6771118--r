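sex,affected_carriers,unaffected_carriers
F,10,4
M,11,4
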