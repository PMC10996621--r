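# Demo pipeline configuration: a small simulated family and two strains.
seed: 7
out_dir: demo_run
simulate:
  nFull: 6
  nSolo: 3
  nTrunc: 1
  nChroms: 2
  chromLen: 150000
  maxDivergence: 0.02
  nStrains: 2
  nEvents: 4
filters:
  min_len: 1000
  max_len: 8750
thresholds:
  recency_threshold: 0.01
  proximity: 10000
  flank: 20000
  min_anchor: 500
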