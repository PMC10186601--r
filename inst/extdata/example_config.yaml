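# Example apoeadmix configuration: fields given here override the package
# defaults (see ?default_config); everything omitted keeps its default.
seed: 7
fdr_q: 0.05
filters:
  min_depth: 3
  qual_min: 50
scan:
  window_len: 15000
  focal_windows: [20, 21, 22]
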