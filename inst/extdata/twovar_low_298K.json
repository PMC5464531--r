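{"model":"twovar","rates":{"k":0.0625,"v":0.529,"a":0.0923,"s":1.48,"d":0.0507},"structural":{"h":0.5,"Kv":0.5,"Ks":0.5,"alpha":4,"gamma":4,"eps":0.02}}
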