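{"model":"goodwin","rates":{"vs":1.6,"vm":0.505,"ks":0.5,"vd":1.4,"k1":0.5,"k2":0.6},"structural":{"KI":1,"KM":0.5,"KD":0.13,"n":2}}
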