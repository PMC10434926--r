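# Contact-tracing observation model on the ER benchmark; base rate reduced
# so the observed fraction stays in range despite traced tests
network: {family: er, n: 1000, mean_degree: 2.6}
observation: {model: contact, q_S: 0.010, q_I: 0.050, q_R: 0.010}
replicates: 10
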