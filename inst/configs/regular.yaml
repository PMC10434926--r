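# Random regular graph: every node has degree 3
network: {family: regular, n: 1000, k: 3}
replicates: 10
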