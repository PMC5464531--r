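{"rates_ref":{"k":0.0625,"v":0.529,"a":0.0923,"s":1.48,"d":0.0507},"energies":{"k":335,"v":1057,"a":893,"s":480,"d":322},"T_ref":298,"R":0.0820803068984792}
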