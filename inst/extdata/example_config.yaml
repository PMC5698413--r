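# Example pipeline configuration: simulate a two-population star panel and
# run every analysis stage on it.
seed: 11
stages: [simulate, filter, phylo, date, diversity, amova, network]
n_perm: 1000
populations:
  - {name: West, n_samples: 20, longitude: -10, tmrca: 2000, topology: star}
  - {name: East, n_samples: 20, longitude: 8, tmrca: 2000, topology: star}
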