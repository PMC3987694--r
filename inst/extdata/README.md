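# Demo data

Small fully synthetic demonstration inputs (no relation to any real survey
or administrative geography):

- `demo_centroids.csv` — eight fictitious areas with lon/lat centroids
  (`id,lon,lat`, decimal degrees).
- `demo_adjacency.gal` — GAL-dialect neighbour lists for the same areas.
- `demo_cases.csv` — per-area case/control counts (`id,cases,total`) with a
  deliberate high-rate cluster in the two northern areas.
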