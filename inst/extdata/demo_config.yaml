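seed: 7
outdir: demo_out
n_cpg: 2000
n_perm: 100
k: 6
alpha: 0.01
stages:
  - simulate
  - dmr
  - state
  - de
  - cargo
  - domains
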