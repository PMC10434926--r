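# Complete 5-ary tree of depth 4 (781 nodes)
network: {family: tree, branching: 5, depth: 4}
replicates: 10
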