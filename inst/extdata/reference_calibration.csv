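analyte,slope,intercept,r,range_low,range_high,lod,loq
hypoxanthine,33.148,-0.7255,0.9999,0.682,33.5,0.102,0.341
xanthine,34.489,-2.5796,0.9999,0.606,29.8,0.0918,0.303
uridine,22.413,0.3431,0.9999,1.08,54.5,0.164,0.542
inosine,17.695,0.5263,0.9999,1.66,83.2,0.250,0.831
guanosine,21.392,-0.9505,0.9999,1.14,56.8,0.172,0.572
adenosine,31.131,-0.5006,0.9999,0.824,41.3,0.125,0.412
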