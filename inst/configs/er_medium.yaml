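# ER benchmark, ~30% of nodes observed
network: {family: er, n: 1000, mean_degree: 2.6}
observation: {model: random, q_S: 0.038, q_I: 0.190, q_R: 0.038}
replicates: 10
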