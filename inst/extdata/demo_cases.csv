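id,cases,total
north1,62,80
north2,58,75
east1,30,90
east2,22,85
central,18,95
west1,9,70
west2,7,65
south1,25,88
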