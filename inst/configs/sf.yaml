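# Scale-free configuration-model network, power-law exponent 2.5
network: {family: powerlaw, n: 2044, gamma: 2.5, k_min: 1}
replicates: 10
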