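# 20% of individuals with the lower transmission rate
network: {family: er, n: 1000, mean_degree: 2.6}
outbreak:
  beta: {kind: bimodal, frac_low: 0.2, low_mean: 0.18, low_sd: 0.01, high_mean: 0.22, high_sd: 0.01}
replicates: 10
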