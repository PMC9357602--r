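# Example pipeline configuration: dispersion analysis of the
# ligand-internalisation model with a fixed delay.
model:
  kinetics: LI
  a: 0.1
  b: 0.9
  eps2: 0.001
  L2: 4.5
kernel:
  family: dirac
  tau: 0.5
scenario:
  seed: 1
  sigma_IC: 0.01
  m: 200
  t_end: 50
  threshold: 0.1
analysis:
  type: dispersion
  k_max: 50
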