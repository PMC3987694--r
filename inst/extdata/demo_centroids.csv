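id,lon,lat
north1,36.8,1.6
north2,37.6,1.4
east1,38.1,0.4
east2,37.9,-0.5
central,36.9,0.2
west1,35.8,0.3
west2,35.1,-0.2
south1,36.4,-1.1
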