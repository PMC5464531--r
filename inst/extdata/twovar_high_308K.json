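{"model":"twovar","rates":{"k":0.0976,"v":2.15,"a":0.302,"s":2.8,"d":0.0778},"structural":{"h":0.5,"Kv":0.5,"Ks":0.5,"alpha":4,"gamma":4,"eps":0.02}}
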