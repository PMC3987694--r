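8
north1 3
north2 central west1
north2 3
north1 east1 central
east1 3
north2 east2 central
east2 3
east1 central south1
central 6
north1 north2 east1 east2 west1 south1
west1 3
north1 central west2
west2 2
west1 south1
south1 3
east2 central west2
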